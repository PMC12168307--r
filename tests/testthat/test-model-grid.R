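test_that("pipeline enumeration is the ordered Cartesian product", {
  g <- enumerate_pipelines(grid_config())
  expect_equal(nrow(g), 104L)
  expect_equal(anyDuplicated(g$pipeline), 0L)
  g1 <- enumerate_pipelines(grid_config(preprocessors = "identity",
                                        classifiers = "logistic"))
  expect_equal(nrow(g1), 1L)
  g6 <- enumerate_pipelines(grid_config(preprocessors = c("identity", "zscore"),
                                        classifiers = c("logistic", "lda", "qda")))
  expect_equal(nrow(g6), 6L)
  expect_equal(g6$preprocessor, rep(c("identity", "zscore"), each = 3))
  expect_error(grid_config(classifiers = c("lda", "lda")), "unique")
})

test_that("ROC/AUC equals pair counting with ties at one half", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)   # 3 of 4 concordant pairs
  expect_equal(roc_auc(1:10, rep(c(0, 1), each = 5))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # exhaustive pair-counting oracle on random instances
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(rnorm(n), 1)
    pairs <- 0; tot <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      tot <- tot + 1
      pairs <- pairs + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    }
    expect_equal(roc_auc(sc, y)$auc, pairs / tot)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "two classes")
})

test_that("every classifier family fits and scores sensibly on separable data", {
  set.seed(30)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(rnorm(n) + 3 * y, rnorm(n) - 2 * y)
  colnames(x) <- c("u", "v")
  for (clf in renalrad:::CLASSIFIER_NAMES) {
    fit <- fit_classifier(clf, x, y, seed = 4L)
    sc <- score_classifier(fit, x)
    expect_true(all(is.finite(sc)), label = clf)
    expect_gt(roc_auc(sc, y)$auc, 0.9)
  }
})

test_that("grid evaluation: separable case, determinism, failure handling", {
  set.seed(31)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = rnorm(n) + 4 * y, f2 = rnorm(n))
  cfg <- grid_config(seed = 19L)
  res <- fit_evaluate_grid(x, y, cfg)
  expect_equal(nrow(res$summary), 104L)
  expect_true(all(res$summary$mean_auc[!res$summary$failed] >= 0 &
                    res$summary$mean_auc[!res$summary$failed] <= 1))
  expect_gt(sum(res$summary$mean_auc == 1, na.rm = TRUE), 3L)
  res2 <- fit_evaluate_grid(x, y, cfg)
  expect_identical(res$summary, res2$summary)
  best <- select_best(res)
  expect_equal(best$mean_auc, max(res$summary$mean_auc, na.rm = TRUE))
})

test_that("best-model selection applies the documented tie rule", {
  mk <- function(auc, acc, pipeline) data.frame(
    pipeline = pipeline, preprocessor = "p", classifier = "c", failed = FALSE,
    mean_auc = auc, auc_ci_lo = NA, auc_ci_hi = NA, mean_accuracy = acc,
    mean_sensitivity = NA, mean_specificity = NA)
  fake <- structure(list(summary = rbind(mk(0.9, 0.8, "a"), mk(0.8, 0.9, "b"))),
                    class = "grid_result")
  expect_equal(select_best(fake)$pipeline, "a")
  # tie on AUC -> higher accuracy wins
  fake2 <- structure(list(summary = rbind(mk(0.9, 0.7, "a"), mk(0.9, 0.8, "b"))),
                     class = "grid_result")
  expect_equal(select_best(fake2)$pipeline, "b")
  # full tie (duplicated pipeline under two names) -> enumeration order
  fake3 <- structure(list(summary = rbind(mk(0.9, 0.8, "dup1"), mk(0.9, 0.8, "dup2"))),
                     class = "grid_result")
  expect_equal(select_best(fake3)$pipeline, "dup1")
  fake4 <- structure(list(summary = mk(0.5, 0.5, "only")), class = "grid_result")
  expect_equal(select_best(fake4)$pipeline, "only")
  fake5 <- fake4; fake5$summary$failed <- TRUE
  expect_error(select_best(fake5), "failed")
})

test_that("null features give chance-level best AUC (grid-max optimism bounded)", {
  aucs <- vapply(1:6, function(s) {
    set.seed(400 + s)
    y <- rep(c(0, 1), each = 30)
    x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
    cfg <- grid_config(preprocessors = c("identity", "zscore"),
                       classifiers = c("logistic", "lda", "naive_bayes", "knn"),
                       seed = 400 + s)
    select_best(fit_evaluate_grid(x, y, cfg))$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})
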