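#!/usr/bin/env Rscript
# Statistics stage: DARC-count>5 SRF-free survival split with the
# signed-rank and slope-difference comparisons, per-interval spot-SRF
# association, and the two desk-recomputable study numbers (baseline
# agreement kappa; segmentation F1). Writes results/statistics.json.

library(darcsrf)

rc <- run_config(cohort = cohort_config(seed = 20260930),
                 use_planted_spots = TRUE)
res <- suppressWarnings(run_pipeline(rc))

surv <- res$survival
cat("SRF-free survival (proportion remaining SRF-free) by DARC-count group:\n")
for (g in c("high", "low")) {
  s <- surv[surv$group == g, ]
  cat(sprintf("  %-4s (n=%2d): %s\n", g, s$n_at_risk[1],
              paste(round(s$proportion, 2), collapse = "  ")))
}
if (!is.null(res$group_tests)) {
  w <- res$group_tests$wilcoxon
  r <- res$group_tests$regression
  cat(sprintf("signed-rank on paired per-interval proportions: W = %.1f, p = %.4g\n",
              w$W, w$p))
  cat(sprintf("slopes: high %.3f (R2 %.2f) vs low %.3f (R2 %.2f); difference p = %.3g\n",
              r$slope1, r$r2_1, r$slope2, r$r2_2, r$p))
}
cat("\nper-interval Spearman r (unique spots vs accumulated SRF):\n")
print(res$association, digits = 2)

kappa <- cohens_kappa(8, 3, 2, 16)
cat(sprintf("\nbaseline clinical-vs-automated agreement kappa: %.3f\n",
            kappa$kappa))
cat(sprintf("segmentation F1 at precision 0.89 / recall 0.72: %.2f\n",
            f1_score(0.89, 0.72)))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(
  survival = surv,
  wilcoxon = res$group_tests$wilcoxon,
  regression = res$group_tests$regression,
  association = res$association,
  kappa_baseline_agreement = kappa$kappa,
  f1_segmentation = f1_score(0.89, 0.72)),
  file.path("results", "statistics.json"), auto_unbox = TRUE, digits = NA,
  na = "null")
cat("wrote results/statistics.json\n")
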