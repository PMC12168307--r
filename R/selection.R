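# Staged feature-selection cascade inside stratified k-fold cross-validation:
# z-normalization -> label-correlation screen (p < 0.05) -> univariate
# logistic (Wald p < 0.10) -> multivariate logistic (Wald p < 0.05) -> LASSO
# (L1 penalty strength 0.05). Features surviving the cascade in at least
# `vote_threshold` of `n_folds` training splits form the final set.

#' Selection configuration
#'
#' @param corr_p correlation-screen p threshold (default 0.05).
#' @param uni_p univariate logistic Wald p threshold (default 0.10).
#' @param multi_p multivariate logistic Wald p threshold (default 0.05).
#' @param lasso_alpha L1 penalty strength for the LASSO stage (default 0.05;
#'   this is the penalty magnitude, not a significance level).
#' @param n_folds cross-validation folds (default 5).
#' @param vote_threshold folds a feature must survive in (default 4).
#' @param fold_seed RNG seed for the stratified fold assignment.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(corr_p = 0.05, uni_p = 0.10, multi_p = 0.05,
                             lasso_alpha = 0.05, n_folds = 5L,
                             vote_threshold = 4L, fold_seed = 7L) {
  stopifnot(corr_p > 0, corr_p < 1, uni_p > 0, uni_p < 1, multi_p > 0,
            multi_p < 1, n_folds >= 2L, vote_threshold <= n_folds)
  structure(list(corr_p = corr_p, uni_p = uni_p, multi_p = multi_p,
                 lasso_alpha = lasso_alpha, n_folds = as.integer(n_folds),
                 vote_threshold = as.integer(vote_threshold),
                 fold_seed = as.integer(fold_seed)),
            class = "selection_config")
}

#' Z-normalize a feature table
#'
#' Centres each column to mean 0 and scales to sample (n-1) SD 1.
#' Zero-variance columns are dropped with a warning.
#'
#' @param table numeric matrix (subjects x features) with column names.
#' @return normalized matrix (possibly fewer columns), with attributes
#'   `center` and `scale`.
#' @export
znormalize <- function(table) {
  stopifnot(is.matrix(table), all(is.finite(table)))
  sds <- apply(table, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance column(s): ",
            paste(utils::head(colnames(table)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    table <- table[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  mus <- colMeans(table)
  out <- sweep(sweep(table, 2, mus, "-"), 2, sds, "/")
  attr(out, "center") <- mus
  attr(out, "scale") <- sds
  out
}

check_binary_labels <- function(labels) {
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("labels must contain exactly two classes")
  as.integer(labels == u[2])
}

#' Label-correlation screen
#'
#' Retains features whose point-biserial correlation with the 0/1 label has a
#' two-sided p below the threshold (t transform on Pearson r).
#'
#' @param table numeric matrix with column names.
#' @param labels binary labels (two classes present).
#' @param p threshold (default 0.05).
#' @return character vector of surviving feature names.
#' @export
correlation_filter <- function(table, labels, p = 0.05) {
  y <- check_binary_labels(labels)
  n <- nrow(table)
  r <- suppressWarnings(as.vector(stats::cor(table, y)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  pv[abs(r) == 1] <- 0
  colnames(table)[pv < p]
}

# Wald p for the slope of a single-feature logistic fit; falls back to the
# likelihood-ratio p under (near-)separation, where the Wald SE blows up.
uni_logistic_p <- function(x, y) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- suppressWarnings(summary(fit)$coefficients)
  wald <- if (nrow(sm) >= 2) sm[2, 4] else 1
  separated <- !fit$converged || abs(stats::coef(fit)[2] %||% 0) > 12
  if (is.na(wald) || separated) {
    lrt <- fit$null.deviance - fit$deviance
    wald <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  }
  wald
}

#' Univariate logistic filter
#'
#' Keeps features whose single-feature logistic slope has Wald p below the
#' threshold; perfectly separating features are scored by the likelihood-ratio
#' test instead (the Wald statistic degenerates under separation).
#'
#' @param table numeric matrix with column names.
#' @param labels binary labels.
#' @param p threshold (default 0.10).
#' @return surviving feature names.
#' @export
univariate_logistic_filter <- function(table, labels, p = 0.10) {
  y <- check_binary_labels(labels)
  pv <- vapply(seq_len(ncol(table)), function(j) uni_logistic_p(table[, j], y),
               numeric(1))
  colnames(table)[pv < p]
}

#' Multivariate logistic filter
#'
#' Joint logistic model reduced by backward stepwise elimination: the feature
#' with the largest drop-one likelihood-ratio p is removed until every
#' remaining feature is significant at the threshold (possibly leaving none).
#' The LR statistic is asymptotically equivalent to the Wald test but stays
#' defined under the (near-)separation that strong radiomic feature sets
#' routinely produce, where every Wald p degenerates to 1.
#'
#' If more candidates than floor(n/5) enter, they are first reduced to a
#' greedily decorrelated (|r| < 0.9) set of the floor(n/5) best by univariate
#' p (ties by name), keeping the initial joint fit identifiable.
#'
#' @param table numeric matrix with column names.
#' @param labels binary labels.
#' @param p threshold (default 0.05).
#' @return surviving feature names.
#' @export
multivariate_logistic_filter <- function(table, labels, p = 0.05) {
  y <- check_binary_labels(labels)
  if (ncol(table) == 0L) return(character())
  cap <- max(1L, floor(nrow(table) / 5))
  if (ncol(table) > cap) {
    upv <- vapply(seq_len(ncol(table)), function(j) uni_logistic_p(table[, j], y),
                  numeric(1))
    ord <- order(upv, colnames(table))
    keep <- integer()
    for (j in ord) {
      if (length(keep) == 0L ||
          max(abs(suppressWarnings(stats::cor(table[, j], table[, keep])))) < 0.9) {
        keep <- c(keep, j)
      }
      if (length(keep) >= cap) break
    }
    table <- table[, keep, drop = FALSE]
  }
  deviance_of <- function(cols) {
    if (length(cols) == 0L) {
      return(suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))$deviance)
    }
    x <- table[, cols, drop = FALSE]
    suppressWarnings(stats::glm.fit(cbind(1, x), y, family = stats::binomial()))$deviance
  }
  cur <- colnames(table)
  dev_full <- deviance_of(cur)
  while (length(cur) > 0L) {
    pv <- vapply(cur, function(f) {
      d <- deviance_of(setdiff(cur, f)) - dev_full
      stats::pchisq(max(d, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    if (max(pv) < p) break
    worst <- cur[order(-pv, cur)[1]]
    cur <- setdiff(cur, worst)
    dev_full <- deviance_of(cur)
  }
  cur
}

#' LASSO selection
#'
#' L1-penalized logistic regression at fixed penalty strength; features with
#' nonzero coefficients are retained. Inputs are expected standardized (the
#' cascade z-normalizes first), so glmnet's internal standardization is off.
#'
#' @param table numeric matrix with column names (standardized).
#' @param labels binary labels.
#' @param alpha penalty strength lambda (default 0.05).
#' @return surviving feature names.
#' @export
lasso_select <- function(table, labels, alpha = 0.05) {
  y <- check_binary_labels(labels)
  if (ncol(table) == 0L) return(character())
  if (ncol(table) == 1L) return(colnames(table))  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(table, y, family = "binomial", alpha = 1,
                        lambda = sort(unique(c(0.4, 0.2, 0.1, alpha)),
                                      decreasing = TRUE),
                        standardize = FALSE)
  if (!fit$jerr == 0 && fit$jerr > 0) stop("glmnet failed to converge (jerr=", fit$jerr, ")")
  co <- as.matrix(stats::coef(fit, s = alpha, exact = FALSE))[-1, 1]
  names(co)[co != 0]
}

# One pass of the full cascade on a training table; returns per-stage sets.
selection_cascade <- function(table, labels, cfg = selection_config()) {
  zn <- suppressWarnings(znormalize(table))
  s1 <- colnames(zn)
  s2 <- correlation_filter(zn, labels, cfg$corr_p)
  s3 <- if (length(s2)) {
    univariate_logistic_filter(zn[, s2, drop = FALSE], labels, cfg$uni_p)
  } else character()
  s4 <- if (length(s3)) {
    multivariate_logistic_filter(zn[, s3, drop = FALSE], labels, cfg$multi_p)
  } else character()
  s5 <- if (length(s4)) {
    lasso_select(zn[, s4, drop = FALSE], labels, cfg$lasso_alpha)
  } else character()
  list(znorm = s1, correlation = s2, univariate = s3, multivariate = s4,
       lasso = s5)
}

# Stratified fold assignment (deterministic under seed).
make_stratified_folds <- function(labels, n_folds, seed) {
  y <- check_binary_labels(labels)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in 0:1) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  if (min(table(fold, y)) < 1) stop("stratification failed: a fold lost a class")
  fold
}

#' Cross-validated feature voting
#'
#' Runs the cascade independently on each of `n_folds` stratified training
#' splits; a feature's voting count is the number of folds in which it
#' survives the full cascade, and the final set is the features with count at
#' least `vote_threshold`.
#'
#' @param table numeric matrix (subjects x features) with column names.
#' @param labels binary class labels (one per row).
#' @param cfg a [selection_config()].
#' @return object of class `selection_report`: list(votes = named integer
#'   vector, final = character, per_fold = list of per-stage sets, folds =
#'   fold assignment).
#' @export
cv_feature_voting <- function(table, labels, cfg = selection_config()) {
  stopifnot(nrow(table) == length(labels))
  if (min(table(labels)) < cfg$n_folds) {
    stop("need at least n_folds subjects per class for stratified folds")
  }
  folds <- make_stratified_folds(labels, cfg$n_folds, cfg$fold_seed)
  per_fold <- vector("list", cfg$n_folds)
  votes <- stats::setNames(integer(ncol(table)), colnames(table))
  for (k in seq_len(cfg$n_folds)) {
    tr <- folds != k
    per_fold[[k]] <- selection_cascade(table[tr, , drop = FALSE], labels[tr], cfg)
    sel <- per_fold[[k]]$lasso
    votes[sel] <- votes[sel] + 1L
  }
  final <- names(votes)[votes >= cfg$vote_threshold]
  structure(list(votes = votes, final = sort(final), per_fold = per_fold,
                 folds = folds, config = cfg),
            class = "selection_report")
}

#' Single-sequence and combined model selection
#'
#' Runs [cv_feature_voting()] on the two single-sequence tables; the combined
#' model's feature set is the union of the two final sets, and its voting
#' counts are recomputed by rerunning the cascade voting on the pooled
#' (column-bound) table.
#'
#' @param table_t2w,table_adc feature matrices with distinct column names
#'   (prefix them by sequence).
#' @param labels binary labels.
#' @param cfg a [selection_config()].
#' @return list(t2w = report, adc = report, combined = list(final, votes,
#'   pooled_report)).
#' @export
combined_model_selection <- function(table_t2w, table_adc, labels,
                                     cfg = selection_config()) {
  rep_t2 <- cv_feature_voting(table_t2w, labels, cfg)
  rep_adc <- cv_feature_voting(table_adc, labels, cfg)
  pooled <- cbind(table_t2w, table_adc)
  if (anyDuplicated(colnames(pooled))) {
    stop("t2w and adc feature names must be distinct (prefix by sequence)")
  }
  rep_pool <- cv_feature_voting(pooled, labels, cfg)
  final_comb <- sort(union(rep_t2$final, rep_adc$final))
  list(t2w = rep_t2, adc = rep_adc,
       combined = list(final = final_comb,
                       votes = rep_pool$votes[final_comb],
                       pooled_report = rep_pool))
}

#' Selection report as a Table-4-style data frame
#'
#' @param reports output of [combined_model_selection()].
#' @param manifest bank manifest for provenance (image type, family).
#' @return data.frame(feature, sequence, combined_votes, single_votes,
#'   image_type, family).
#' @export
selection_table <- function(reports, manifest = default_bank_manifest()) {
  rows <- lapply(reports$combined$final, function(f) {
    seqn <- if (f %in% colnames_or(reports$t2w$votes)) "T2WI" else "ADC"
    single <- if (seqn == "T2WI") reports$t2w$votes else reports$adc$votes
    bare <- sub("^(t2w|adc)_", "", f)
    prov <- manifest[manifest$name == bare, ]
    data.frame(feature = f, sequence = seqn,
               combined_votes = unname(reports$combined$votes[f]),
               single_votes = unname(single[f]),
               image_type = if (nrow(prov)) prov$image_type else NA,
               family = if (nrow(prov)) prov$family else NA)
  })
  do.call(rbind, rows)
}

colnames_or <- function(v) names(v)
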