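# foxcyto

Image cytometry of nuclear vs cytoplasmic FOXP3 in CD4+ tumor-infiltrating
T cells, and evaluation of the nFOXP3/cFOXP3 ratio as a case-control
recurrence biomarker.

## The problem

FOXP3 marks regulatory T cells (Treg), but activated effector CD4+ T cells
express it too — mainly in the cytoplasm, whereas Treg express it in the
nucleus.  Counting CD4+FOXP3+ cells without regard to localization mixes
two populations with opposite prognostic meaning, which is one reason
FOXP3-based prognostic studies disagree.  `foxcyto` is for researchers who
want to quantify the two compartments separately from multi-channel
immunofluorescence images (blue = DAPI, green = CD4/autofluorescence,
red = FOXP3) and relate the resulting specimen-level percentages to
clinical outcome.

## The method

1. **Segmentation** — the classical three-tier hierarchy: nuclei (primary
   objects) on the DAPI channel by maximum-entropy (Kapur) thresholding
   (correction 0.5, bounds [0.3, 0.9]), shape-based declumping
   (distance-transform maxima, 20 px suppression, marker-controlled
   watershed) and a 20–50 px equivalent-diameter gate with border discard;
   cells (secondary) grown from the nuclei by seeded propagation over the
   Otsu-thresholded green channel with step cost
   `|ΔI| + λ‖step‖`, λ = 0.05; cytoplasm (tertiary) = cell ∖ nucleus.
2. **Cytometry** — per-cell compartment mean intensities; per-specimen
   empirical positivity threshold
   `median + 1.7 × (2·Q3 − median)` per measurement population (CD4 on the
   whole-cell green mean; FOXP3 on nucleus red and cytoplasm red); strict
   (">") positivity; classification into nuclear-only / cytoplasmic-only /
   dual / negative; specimen percentages **nFOXP3** and **cFOXP3** of CD4+
   cells.
3. **Biomarker statistics** — zeros offset by 0.001, ratio = nFOXP3/cFOXP3,
   log2 transform; Wilcoxon rank-sum case-control comparisons; Pearson /
   Spearman correlation; logistic regression with odds ratio per twofold
   increase (Wald CI/p, separation diagnostics); empirical ROC whose
   trapezoid AUC equals the Mann-Whitney concordance; paired AUC comparison
   by DeLong's method.
4. **Synthetic data** — fluorescence fields with exact per-cell ground
   truth and case-control cohorts (scaled Beta margins, Gaussian copula)
   with planted effect sizes, so the whole pipeline can be validated
   without archival specimens.

See `vignettes/foxcyto-methods.Rmd` for the full model description,
parameter rationale, and limitations.

## Worked example

```r
library(foxcyto)

## one synthetic field with known ground truth
gi  <- generate_image(image_sim_params(seed = 42))
seg <- segment_field(gi$image)
seg
#> <segmentation_result> 45 nuclei | thresholds: DAPI 0.3000 (raw 0.0859), green 0.2383 (raw 0.2383)

rec <- measure_cells(gi$image, seg)
thr <- specimen_thresholds(rec)
thr$foxp3_nuclear
#> <threshold_spec> median 0.05009, Q3 0.0507, 2xQ3-median 0.05131, k 1.7 -> threshold 0.1373 (n = 45)

cls <- classify_cells(rec, thr$cd4, thr$foxp3_nuclear, thr$foxp3_cytoplasmic)
summarize_specimen(cls, "patient-01")
#>   patient_id n_cells n_cd4 pct_cd4foxp3 pct_nfoxp3 pct_cfoxp3 n_dual
#> 1 patient-01      45     9     33.33333   22.22222   11.11111      0
```

The field planted 45 cells, 20% CD4+ (9 cells), with 25% of CD4+ cells
nuclear-FOXP3+ and 10% cytoplasmic: the pipeline segments all 45 nuclei,
finds all 9 CD4+ cells, and recovers 2/9 nuclear-only (22.2%) and 1/9
cytoplasmic-only (11.1%) with no dual positives — the planted rounded
counts exactly.  The logged thresholds show the data-driven Kapur threshold
(raw 0.086, clamped up to the 0.3 lower bound) and the Otsu green threshold.

```r
## a synthetic 19-case / 30-control cohort with planted effect sizes
co <- ratio_transform_cohort(generate_cohort(cohort_sim_params(seed = 1)))
st <- cohort_stats(co)
c(st$roc$nfoxp3$auc, st$roc$cfoxp3$auc, st$roc$log2_ratio$auc)
#> [1] 0.8789474 0.8035088 0.9771930
st$correlation_cases$r_squared
#> [1] 0.724417
st$logistic$log2_ratio
#> <logistic_fit> OR per twofold increase 89.1 (95% CI 3.31-2.39e+03), Wald p = 0.0075, n = 49
st$auc_comparisons$ratio_vs_nuclear$p
#> [1] 0.04703699
```

At the planted effect sizes, the log2 nuclear/cytoplasmic ratio separates
cases from controls better (AUC 0.98) than either component marker (0.88 /
0.80), and the paired DeLong test finds the improvement over nuclear FOXP3
significant at the study size — the qualitative pattern the biomarker is
designed to capture.  Within cases, nuclear and cytoplasmic percentages are
strongly correlated (r² 0.72) as planted.

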