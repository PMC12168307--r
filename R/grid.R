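# The 8-preprocessor x 13-classifier model grid: every pipeline is fitted on
# each of 5 shared stratified training folds (preprocessor fitted on the
# training split only) and scored on the held-out fold; pipelines are ranked
# by mean test AUC.

PREPROCESSOR_NAMES <- c("identity", "zscore", "minmax", "robust",
                        "identity+pca95", "zscore+pca95", "minmax+pca95",
                        "robust+pca95")

#' Grid configuration
#'
#' The default grid is 8 preprocessors (identity, z-score, min-max and
#' robust-quantile scaling, each with and without a PCA retaining 95% of
#' variance) crossed with 13 classifiers, i.e. 104 pipelines.
#'
#' @param preprocessors character vector of preprocessor names.
#' @param classifiers character vector of classifier names.
#' @param n_folds stratified folds (default 5).
#' @param seed seed controlling folds, stochastic learners and the bootstrap CI.
#' @return object of class `grid_config`.
#' @export
grid_config <- function(preprocessors = PREPROCESSOR_NAMES,
                        classifiers = CLASSIFIER_NAMES,
                        n_folds = 5L, seed = 11L) {
  if (anyDuplicated(preprocessors) || anyDuplicated(classifiers)) {
    stop("preprocessor and classifier names must be unique")
  }
  structure(list(preprocessors = preprocessors, classifiers = classifiers,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "grid_config")
}

#' Enumerate the pipeline grid
#'
#' Cartesian product in deterministic preprocessor-major order.
#'
#' @param cfg a [grid_config()].
#' @return data.frame(pipeline, preprocessor, classifier).
#' @export
enumerate_pipelines <- function(cfg = grid_config()) {
  g <- expand.grid(classifier = cfg$classifiers, preprocessor = cfg$preprocessors,
                   stringsAsFactors = FALSE)[, 2:1]
  g$pipeline <- paste(g$preprocessor, g$classifier, sep = "|")
  g[, c("pipeline", "preprocessor", "classifier")]
}

## ---- preprocessors ---------------------------------------------------------

fit_preprocessor <- function(name, x) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  use_pca <- length(parts) > 1L && parts[2] == "pca95"
  st <- switch(base,
    identity = list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))),
    zscore = list(center = colMeans(x),
                  scale = pmax(apply(x, 2, stats::sd), 1e-12)),
    minmax = list(center = apply(x, 2, min),
                  scale = pmax(apply(x, 2, max) - apply(x, 2, min), 1e-12)),
    robust = list(center = apply(x, 2, stats::median),
                  scale = pmax(apply(x, 2, stats::IQR), 1e-12)),
    stop("unknown preprocessor: ", base))
  xt <- sweep(sweep(x, 2, st$center), 2, st$scale, "/")
  pca <- NULL
  if (use_pca) {
    pc <- stats::prcomp(xt, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    k <- max(1L, which(cumsum(v) / sum(v) >= 0.95)[1])
    pca <- list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE])
  }
  list(name = name, st = st, pca = pca)
}

apply_preprocessor <- function(pp, x) {
  xt <- sweep(sweep(x, 2, pp$st$center), 2, pp$st$scale, "/")
  if (!is.null(pp$pca)) {
    xt <- sweep(xt, 2, pp$pca$center) %*% pp$pca$rotation
  }
  xt
}

## ---- ROC -------------------------------------------------------------------

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney U statistic normalized by n+ * n-, with ties
#' counted 1/2 (so all-equal scores give 0.5). ROC points are monotone
#' nondecreasing in both coordinates.
#'
#' @param scores numeric scores (finite), larger = more class-positive.
#' @param labels binary labels.
#' @return list(points = data.frame(threshold, fpr, tpr), auc).
#' @export
roc_auc <- function(scores, labels) {
  y <- check_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(all(is.finite(scores)), length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # collapse tied thresholds
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(threshold = c(Inf, ss[last]),
                    fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(points = pts, auc = auc)
}

# sensitivity/specificity/accuracy at the Youden-optimal ROC point
youden_metrics <- function(roc, labels) {
  y <- check_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  j <- roc$points$tpr - roc$points$fpr
  i <- which.max(j)
  sens <- roc$points$tpr[i]; spec <- 1 - roc$points$fpr[i]
  acc <- (sens * n1 + spec * n0) / (n1 + n0)
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

## ---- grid evaluation -------------------------------------------------------

#' Fit and evaluate the full pipeline grid
#'
#' All pipelines share one stratified fold partition (so later DeLong
#' comparisons are paired). Preprocessors are fitted on each training split
#' only. Per fold, each pipeline reports test AUC plus accuracy, sensitivity
#' and specificity at the Youden-optimal threshold; pipelines whose classifier
#' fails on any fold are flagged failed and excluded from best-model
#' selection. The mean-AUC 95% CI is a percentile bootstrap over fold AUCs.
#'
#' @param table numeric feature matrix (subjects x selected features).
#' @param labels binary labels.
#' @param cfg a [grid_config()].
#' @return object of class `grid_result`: list(summary = data.frame,
#'   fold_metrics, fold_scores, folds, config).
#' @export
fit_evaluate_grid <- function(table, labels, cfg = grid_config()) {
  y <- check_binary_labels(labels)
  pipes <- enumerate_pipelines(cfg)
  folds <- make_stratified_folds(labels, cfg$n_folds, cfg$seed)
  pps <- unique(pipes$preprocessor)
  # preprocess once per (preprocessor, fold)
  prep <- list()
  for (pp in pps) {
    for (k in seq_len(cfg$n_folds)) {
      tr <- folds != k
      f <- fit_preprocessor(pp, table[tr, , drop = FALSE])
      prep[[paste(pp, k)]] <- list(
        train = apply_preprocessor(f, table[tr, , drop = FALSE]),
        test = apply_preprocessor(f, table[!tr, , drop = FALSE]))
    }
  }
  n_pipe <- nrow(pipes)
  fold_metrics <- vector("list", n_pipe)
  fold_scores <- vector("list", n_pipe)
  summary_rows <- vector("list", n_pipe)
  for (i in seq_len(n_pipe)) {
    met <- matrix(NA_real_, cfg$n_folds, 4,
                  dimnames = list(NULL, c("auc", "accuracy", "sensitivity",
                                          "specificity")))
    scores_i <- vector("list", cfg$n_folds)
    failed <- FALSE
    for (k in seq_len(cfg$n_folds)) {
      pk <- prep[[paste(pipes$preprocessor[i], k)]]
      tr <- folds != k
      res <- tryCatch({
        clf <- fit_classifier(pipes$classifier[i], pk$train, y[tr],
                              seed = derive_seed(cfg$seed, i * 100L + k))
        sc <- score_classifier(clf, pk$test)
        if (any(!is.finite(sc))) stop("non-finite scores")
        roc <- roc_auc(sc, y[!tr])
        list(sc = sc, auc = roc$auc, ym = youden_metrics(roc, y[!tr]))
      }, error = function(e) e)
      if (inherits(res, "error")) { failed <- TRUE; break }
      met[k, ] <- c(res$auc, res$ym["accuracy"], res$ym["sensitivity"],
                    res$ym["specificity"])
      scores_i[[k]] <- res$sc
    }
    fold_metrics[[i]] <- met
    fold_scores[[i]] <- scores_i
    ci <- c(NA_real_, NA_real_)
    if (!failed) {
      ci <- with_seed(derive_seed(cfg$seed, 90000L + i), {
        bm <- replicate(2000, mean(sample(met[, "auc"], replace = TRUE)))
        stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      })
    }
    summary_rows[[i]] <- data.frame(
      pipeline = pipes$pipeline[i], preprocessor = pipes$preprocessor[i],
      classifier = pipes$classifier[i], failed = failed,
      mean_auc = if (failed) NA_real_ else mean(met[, "auc"]),
      auc_ci_lo = ci[1], auc_ci_hi = ci[2],
      mean_accuracy = if (failed) NA_real_ else mean(met[, "accuracy"]),
      mean_sensitivity = if (failed) NA_real_ else mean(met[, "sensitivity"]),
      mean_specificity = if (failed) NA_real_ else mean(met[, "specificity"]))
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 fold_metrics = fold_metrics, fold_scores = fold_scores,
                 folds = folds, labels = y, config = cfg),
            class = "grid_result")
}

#' Select the best pipeline from a grid result
#'
#' Argmax of mean test AUC among non-failed pipelines; ties broken by higher
#' mean accuracy, then enumeration order.
#'
#' @param result a `grid_result`.
#' @return list(pipeline, preprocessor, classifier, mean_auc, auc_ci,
#'   mean_accuracy, mean_sensitivity, mean_specificity, index).
#' @export
select_best <- function(result) {
  s <- result$summary
  ok <- which(!s$failed)
  if (length(ok) == 0L) stop("all pipelines failed")
  ord <- ok[order(-s$mean_auc[ok], -s$mean_accuracy[ok], ok)]
  i <- ord[1]
  list(pipeline = s$pipeline[i], preprocessor = s$preprocessor[i],
       classifier = s$classifier[i], mean_auc = s$mean_auc[i],
       auc_ci = c(s$auc_ci_lo[i], s$auc_ci_hi[i]),
       mean_accuracy = s$mean_accuracy[i],
       mean_sensitivity = s$mean_sensitivity[i],
       mean_specificity = s$mean_specificity[i], index = i)
}

# Per-fold test scores of one pipeline, assembled subject-by-subject (for
# paired DeLong comparisons between models evaluated on the same folds).
pipeline_fold_scores <- function(result, index) {
  lapply(seq_len(result$config$n_folds), function(k) {
    idx <- which(result$folds == k)
    list(idx = idx, labels = result$labels[idx],
         scores = result$fold_scores[[index]][[k]])
  })
}
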