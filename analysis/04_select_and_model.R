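#!/usr/bin/env Rscript
# Feature selection (correlation screen -> univariate/multivariate logistic ->
# LASSO, voted over 5 stratified folds) and the 8x13 model grid for the T2WI,
# ADC and combined models. Writes results/selection_report.json,
# results/grid_{model}.csv and results/best_models.json.

library(renalrad)

read_ft <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df$subject_id
  m
}
ft_t2 <- read_ft("results/features_t2w.csv")
ft_adc <- read_ft("results/features_adc.csv")
colnames(ft_t2) <- paste0("t2w_", colnames(ft_t2))
colnames(ft_adc) <- paste0("adc_", colnames(ft_adc))
clinical <- read.csv("results/cohort/clinical.csv")
labels <- clinical$class_label

sel <- combined_model_selection(ft_t2, ft_adc, labels,
                                selection_config(fold_seed = 7L))
cat("Final feature sets: T2WI =", length(sel$t2w$final),
    "| ADC =", length(sel$adc$final),
    "| combined =", length(sel$combined$final), "\n")
if (length(sel$combined$final)) {
  cat("Combined-model features and voting counts:\n")
  print(data.frame(feature = sel$combined$final,
                   votes = unname(sel$combined$votes)))
}
jsonlite::write_json(
  list(t2w = list(final = sel$t2w$final,
                  votes = as.list(sel$t2w$votes[sel$t2w$votes > 0])),
       adc = list(final = sel$adc$final,
                  votes = as.list(sel$adc$votes[sel$adc$votes > 0])),
       combined = list(final = sel$combined$final,
                       votes = as.list(sel$combined$votes))),
  "results/selection_report.json", auto_unbox = TRUE, pretty = TRUE)

pooled <- cbind(ft_t2, ft_adc)
sets <- list(t2w = sel$t2w$final, adc = sel$adc$final,
             combined = sel$combined$final)
best <- list()
for (model in names(sets)) {
  if (!length(sets[[model]])) {
    cat("no features survived voting for the", model, "model; skipping grid\n")
    next
  }
  g <- fit_evaluate_grid(pooled[, sets[[model]], drop = FALSE], labels,
                         grid_config(seed = 11L))
  write.csv(g$summary, sprintf("results/grid_%s.csv", model), row.names = FALSE)
  best[[model]] <- select_best(g)
  b <- best[[model]]
  cat(sprintf("%s model: best pipeline %s, mean test AUC %.3f (95%% CI %.3f-%.3f), acc %.2f\n",
              model, b$pipeline, b$mean_auc, b$auc_ci[1], b$auc_ci[2],
              b$mean_accuracy))
}
jsonlite::write_json(lapply(best, function(b) b[setdiff(names(b), "index")]),
                     "results/best_models.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/grid_*.csv and results/best_models.json\n")
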