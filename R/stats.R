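# Inference: from-scratch DeLong paired AUC comparison, contingency-table
# tests with the chi-square/Fisher gate, and normality-gated group comparison.

# Midrank placement values: for each positive score, the fraction of negatives
# it beats (ties = 1/2), and vice versa. Computed via midranks for speed.
placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg))           # midranks in the combined sample
  rp <- rank(pos); rn <- rank(neg)
  v10 <- (all_r[seq_len(m)] - rp) / n              # per-positive placements
  v01 <- 1 - (all_r[m + seq_len(n)] - rn) / m      # per-negative placements
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC AUCs
#'
#' Both score vectors must be computed on the same subjects. AUCs are the
#' Mann-Whitney statistics (ties 1/2); the variance of the AUC difference uses
#' the placement-value (structural components) estimator; the p-value is
#' two-sided normal. When the variance of the difference is zero the p-value
#' is 1 if the AUCs are equal, otherwise 0 with a warning (a deterministic
#' difference).
#'
#' @param labels binary labels.
#' @param scores_a,scores_b per-subject scores from the two models.
#' @return list(auc_a, auc_b, z, p).
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  y <- check_binary_labels(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  if (min(sum(y == 1), sum(y == 0)) < 1) stop("both classes must be present")
  pa <- placements(scores_a[y == 1], scores_a[y == 0])
  pb <- placements(scores_b[y == 1], scores_b[y == 0])
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
    }
    warning("zero estimated variance with unequal AUCs: deterministic difference")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = sign(d) * Inf, p = 0))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' DeLong variance of a single AUC
#'
#' @param labels binary labels.
#' @param scores model scores.
#' @return list(auc, var).
#' @export
delong_auc_variance <- function(labels, scores) {
  y <- check_binary_labels(labels)
  p <- placements(scores[y == 1], scores[y == 0])
  list(auc = p$auc,
       var = stats::var(p$v10) / sum(y == 1) + stats::var(p$v01) / sum(y == 0))
}

#' Chi-square / Fisher contingency test for a 2x2 table
#'
#' Pearson chi-square without continuity correction when every expected count
#' is at least 5, otherwise the two-sided Fisher exact test. The method used
#' is reported.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (group x outcome).
#' @param correct apply the Yates continuity correction to the chi-square
#'   branch (default FALSE).
#' @return list(statistic (NA for Fisher), p, method).
#' @export
contingency_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("undefined test: contingency table has an empty margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = correct)
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = if (correct) "chi-square (Yates)" else "chi-square")
  } else {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher")
  }
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk at 0.05 per group decides the branch: both normal leads to
#' Welch's unpaired t-test, otherwise the Mann-Whitney U test (normal
#' approximation with tie correction). Constant groups route to the
#' nonparametric branch; fully tied data return p = 1 with a warning.
#'
#' @param values numeric vector.
#' @param group_labels two-level grouping of the same length.
#' @return list(p, method).
#' @export
group_compare <- function(values, group_labels) {
  g <- check_binary_labels(group_labels)
  x0 <- values[g == 0]; x1 <- values[g == 1]
  if (length(x0) < 2 || length(x1) < 2) stop("need >= 2 observations per group")
  if (stats::sd(values) == 0) {
    warning("all observations tied in both groups; p = 1")
    return(list(p = 1, method = "degenerate"))
  }
  normal <- function(x) {
    length(x) >= 3 && stats::sd(x) > 0 &&
      tryCatch(stats::shapiro.test(x)$p.value > 0.05, error = function(e) FALSE)
  }
  if (normal(x0) && normal(x1)) {
    list(p = stats::t.test(x0, x1)$p.value, method = "welch-t")
  } else {
    list(p = mwu_p(x0, x1), method = "mann-whitney")
  }
}

# Mann-Whitney U two-sided p: normal approximation with midranks, tie
# correction and continuity correction.
mwu_p <- function(x0, x1) {
  wt <- suppressWarnings(stats::wilcox.test(x0, x1, exact = FALSE,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all observations tied
  p
}

#' Table-2-style clinical comparison report
#'
#' For every 0/1 phenotype flag, builds the 2x2 class-by-flag table and runs
#' [contingency_test()]; continuous columns go through [group_compare()].
#'
#' @param clinical clinical data.frame with class_label and flag columns.
#' @param flags flag column names (default all declared phantom flags present).
#' @param continuous named list of continuous vectors to compare (optional).
#' @return data.frame(variable, type, p, method, rate_or_mean per class).
#' @export
clinical_comparison <- function(clinical,
                                flags = intersect(CLINICAL_FLAGS, names(clinical)),
                                continuous = list()) {
  cls <- sort(unique(clinical$class_label))
  stopifnot(length(cls) == 2L)
  rows <- list()
  for (f in flags) {
    tab <- matrix(0L, 2, 2)
    for (i in 1:2) {
      v <- clinical[[f]][clinical$class_label == cls[i]]
      tab[i, ] <- c(sum(v == 1), sum(v == 0))
    }
    res <- tryCatch(contingency_test(tab), error = function(e) list(p = NA, method = "undefined"))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = f, type = "flag", p = res$p, method = res$method,
      class1 = mean(clinical[[f]][clinical$class_label == cls[1]]),
      class2 = mean(clinical[[f]][clinical$class_label == cls[2]]))
  }
  for (nm in names(continuous)) {
    v <- continuous[[nm]]
    res <- group_compare(v, clinical$class_label)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, type = "continuous", p = res$p, method = res$method,
      class1 = stats::median(v[clinical$class_label == cls[1]]),
      class2 = stats::median(v[clinical$class_label == cls[2]]))
  }
  out <- do.call(rbind, rows)
  names(out)[5:6] <- paste0(c("class_", "class_"), cls)
  out
}
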