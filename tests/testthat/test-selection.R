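sim_table <- function(n, p, seed, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  colnames(m) <- paste0(prefix, seq_len(p))
  m
}

test_that("z-normalization: hand example, idempotence, constant columns dropped", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(0, 1, 0))
  expect_warning(z <- znormalize(m), "zero-variance")
  expect_equal(colnames(z), c("a", "c"))
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))           # sample (n-1) SD
  z2 <- znormalize(z)
  expect_lt(max(abs(z2 - z)), 1e-10)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
})

test_that("correlation filter keeps label-aligned features at the right rate", {
  y <- rep(c(0, 1), each = 50)
  x <- sim_table(100, 1000, 42)
  x <- cbind(x, label_copy = y)
  kept <- correlation_filter(x, y, 0.05)
  expect_true("label_copy" %in% kept)
  null_rate <- (length(setdiff(kept, "label_copy"))) / 1000
  expect_lt(abs(null_rate - 0.05), 0.02)
  # n = 3: only |r| = 1 can pass
  x3 <- cbind(f1 = c(1, 2, 3.01), f2 = c(5, -2, 4))
  y3 <- c(0, 0, 1)
  expect_false("f2" %in% correlation_filter(x3, y3, 0.05))
  expect_error(correlation_filter(x, rep(1, 100), 0.05), "two classes")
})

test_that("logistic filters: survivors, separation handling, collinearity", {
  y <- rep(c(0, 1), each = 30)
  set.seed(9)
  strong <- y * 3 + rnorm(60, 0, 0.5)
  x <- cbind(sim_table(60, 5, 10), strong = strong, sep = y * 2 - 1)
  expect_true(all(c("strong", "sep") %in% univariate_logistic_filter(x, y, 0.1)))
  # duplicated informative features: at most one survives the joint fit
  xd <- cbind(strong1 = strong, strong2 = strong, sim_table(60, 2, 11))
  surv <- multivariate_logistic_filter(xd, y, 0.05)
  expect_lte(sum(c("strong1", "strong2") %in% surv), 1L)
  # null multivariate calibration (~5% on average)
  rates <- vapply(1:60, function(s) {
    xn <- sim_table(100, 20, 500 + s)
    yn <- rep(c(0, 1), 50)
    length(multivariate_logistic_filter(xn, yn, 0.05)) / 20
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.025)
})

test_that("lasso selection: shrinkage limits and recovery of a planted effect", {
  y <- rep(c(0, 1), each = 100)
  set.seed(13)
  x <- sim_table(200, 20, 14)
  x[, 1] <- x[, 1] + y * 2   # 2-SD separation on feature 1
  x <- znormalize(x)
  expect_length(lasso_select(x, y, alpha = 5), 0L)   # full shrinkage
  hits <- vapply(1:50, function(s) {
    xs <- sim_table(200, 20, 900 + s)
    xs[, 1] <- xs[, 1] + y * 2
    "f1" %in% lasso_select(znormalize(xs), y, 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # alpha -> 0 approaches the unpenalized support (everything nonzero)
  sel0 <- lasso_select(x, y, alpha = 1e-4)
  expect_gt(length(sel0), 15L)
})

test_that("cv voting: determinism, label-copy votes, threshold containment", {
  y <- rep(c(0, 1), each = 25)
  x <- cbind(sim_table(50, 30, 15), label_copy = y + rnorm(50, 0, 0.05))
  cfg <- selection_config(fold_seed = 3L)
  r1 <- cv_feature_voting(x, y, cfg)
  r2 <- cv_feature_voting(x, y, cfg)
  expect_identical(r1$votes, r2$votes)
  expect_equal(unname(r1$votes["label_copy"]), 5L)
  expect_true(all(r1$votes >= 0 & r1$votes <= 5))
  expect_true(all(r1$votes[r1$final] >= cfg$vote_threshold))
  # stage monotonicity within each fold
  for (k in seq_along(r1$per_fold)) {
    st <- r1$per_fold[[k]]
    expect_true(all(st$correlation %in% st$znorm))
    expect_true(all(st$univariate %in% st$correlation))
    expect_true(all(st$multivariate %in% st$univariate))
    expect_true(all(st$lasso %in% st$multivariate))
  }
  expect_error(cv_feature_voting(x[23:28, ], y[23:28], cfg), "n_folds")
})

test_that("planted informative features reach the voting threshold", {
  # 3 informative features at 1.5 SD separation among 200 nulls, n = 150
  reps <- 12
  ok <- vapply(1:reps, function(s) {
    set.seed(2000 + s)
    y <- rep(c(0, 1), 75)
    x <- matrix(rnorm(150 * 203), 150, 203)
    colnames(x) <- c(paste0("inf", 1:3), paste0("null", 1:200))
    x[, 1:3] <- x[, 1:3] + outer(y, rep(1.5, 3))
    rep <- cv_feature_voting(x, y, selection_config(fold_seed = s))
    all(rep$votes[paste0("inf", 1:3)] >= 4)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("combined selection is the union with pooled-table votes", {
  set.seed(77)
  y <- rep(c(0, 1), each = 30)
  xt <- sim_table(60, 15, 21, prefix = "t2w_f")
  xa <- sim_table(60, 15, 22, prefix = "adc_f")
  xt[, 1] <- xt[, 1] + y * 3
  xa[, 2] <- xa[, 2] + y * 3
  sel <- combined_model_selection(xt, xa, y, selection_config(fold_seed = 5L))
  expect_setequal(sel$combined$final, union(sel$t2w$final, sel$adc$final))
  expect_true(all(names(sel$combined$votes) %in% colnames(cbind(xt, xa))))
  expect_true("t2w_f1" %in% sel$t2w$final)
  expect_true("adc_f2" %in% sel$adc$final)
})
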