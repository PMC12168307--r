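#!/usr/bin/env Rscript
# Statistical inference: clinical contingency comparisons between the two
# genotype classes (chi-square / Fisher gate), group comparisons of the
# volumetric summaries, fold-wise DeLong comparisons of the three best
# models, and the published worked examples recomputed from their counts.
# Writes results/clinical_tests.csv and results/delong_folds.csv.

library(renalrad)

clinical <- read.csv("results/cohort/clinical.csv")
vol <- read.csv("results/volumetry.csv")
ct <- clinical_comparison(
  clinical, continuous = list(total_volume_cm3 = vol$total_volume_cm3,
                              mean_adc = vol$mean_adc,
                              mean_t2 = vol$mean_t2_intensity))
write.csv(ct, "results/clinical_tests.csv", row.names = FALSE)
cat("Class-comparison tests (synthetic cohort):\n")
print(ct[, c("variable", "p", "method")])

# Worked examples from the published class counts (inputs, not outputs):
omph <- matrix(c(9, 15, 17, 8), 2, byrow = TRUE)
renal <- matrix(c(9, 15, 2, 23), 2, byrow = TRUE)
cat(sprintf("\nWorked examples: omphalocele 9/24 vs 17/25 -> chi2 p = %.3f; ",
            contingency_test(omph)$p))
cat(sprintf("renal anomalies 9/24 vs 2/25 -> chi2 p = %.3f; ",
            contingency_test(renal)$p))
cat(sprintf("pooled benign-renal incidence = %.2f%%\n", 100 * 11 / 49))

# Fold-wise DeLong between the best pipelines (rerun on the selected sets)
sel <- jsonlite::read_json("results/selection_report.json", simplifyVector = TRUE)
read_ft <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df$subject_id
  m
}
ft_t2 <- read_ft("results/features_t2w.csv")
ft_adc <- read_ft("results/features_adc.csv")
colnames(ft_t2) <- paste0("t2w_", colnames(ft_t2))
colnames(ft_adc) <- paste0("adc_", colnames(ft_adc))
pooled <- cbind(ft_t2, ft_adc)
sets <- list(t2w = sel$t2w$final, adc = sel$adc$final,
             combined = sel$combined$final)
sets <- Filter(length, sets)
if (length(sets) >= 2) {
  grids <- lapply(sets, function(f) {
    fit_evaluate_grid(pooled[, f, drop = FALSE], clinical$class_label,
                      grid_config(seed = 11L))
  })
  bests <- lapply(grids, select_best)
  rows <- list()
  for (pr in combn(names(sets), 2, simplify = FALSE)) {
    fa <- renalrad:::pipeline_fold_scores(grids[[pr[1]]], bests[[pr[1]]]$index)
    fb <- renalrad:::pipeline_fold_scores(grids[[pr[2]]], bests[[pr[2]]]$index)
    for (k in seq_along(fa)) {
      p <- tryCatch(delong_test(fa[[k]]$labels, fa[[k]]$scores, fb[[k]]$scores)$p,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(pr, collapse = " vs "), fold = k, p = p)
    }
  }
  dl <- do.call(rbind, rows)
  write.csv(dl, "results/delong_folds.csv", row.names = FALSE)
  cat("\nFold-wise DeLong p-values between best models:\n")
  print(reshape(dl, idvar = "comparison", timevar = "fold", direction = "wide"))
} else {
  cat("\nfewer than two fitted models; skipping DeLong comparisons\n")
}
cat("Wrote results/clinical_tests.csv and results/delong_folds.csv\n")
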