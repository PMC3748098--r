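# Shared small-scale simulation settings for fast tests.

# compact field: few mid-size nuclei, comfortably inside the size gate
small_field_params <- function(n_cells = 12L, seed = 1L, noise_sigma = 0.02,
                               frac_cd4 = 0.2, frac_nfoxp3 = 0.25,
                               frac_cfoxp3 = 0.1, frac_dual = 0) {
  image_sim_params(width = 256L, height = 256L, n_cells = n_cells,
                   nucleus_diameter_range = c(24, 30),
                   min_separation = 40, cell_margin_range = c(4, 8),
                   axis_ratio_range = c(0.85, 1), frac_cd4 = frac_cd4,
                   frac_nfoxp3 = frac_nfoxp3, frac_cfoxp3 = frac_cfoxp3,
                   frac_dual = frac_dual,
                   noise_sigma = noise_sigma, seed = seed)
}

# dense acceptance-scale field: ~64 CD4+ cells per 512x512 field
dense_field_params <- function(seed, noise_sigma = 0.05, ...) {
  image_sim_params(width = 512L, height = 512L, n_cells = 320L,
                   nucleus_diameter_range = c(21, 24),
                   min_separation = 26, cell_margin_range = c(3, 6),
                   axis_ratio_range = c(0.9, 1), frac_cd4 = 0.2,
                   frac_nfoxp3 = 0.25, frac_cfoxp3 = 0.10,
                   noise_sigma = noise_sigma, seed = seed, ...)
}

# Jaccard overlap of two pixel sets given as label ids in two label maps
jaccard <- function(map_a, id_a, map_b, id_b) {
  a <- map_a == id_a
  b <- map_b == id_b
  sum(a & b) / sum(a | b)
}

# a null cohort: both arms drawn from the same marker distributions
null_cohort_params <- function(seed = NULL, n_cases = 19L, n_controls = 30L) {
  cohort_sim_params(n_cases = n_cases, n_controls = n_controls,
                    case_nfoxp3 = c(2, 14), case_cfoxp3 = c(2, 14),
                    control_nfoxp3 = c(2, 14), control_cfoxp3 = c(2, 14),
                    case_correlation = 0, control_correlation = 0,
                    seed = seed)
}
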