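test_that("DeLong: self-comparison, symmetry, monotone-transform invariance", {
  set.seed(50)
  y <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  expect_equal(delong_test(y, a, a)$p, 1)
  ab <- delong_test(y, a, b); ba <- delong_test(y, b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
  tr <- delong_test(y, exp(a), b)   # strictly monotone transform of scores_a
  expect_equal(ab$p, tr$p)
  expect_equal(ab$auc_a, tr$auc_a)
})

test_that("DeLong variance agrees with a resampling oracle", {
  set.seed(51)
  y <- rep(c(0, 1), each = 15)
  sc <- rnorm(30) + 0.8 * y
  est <- delong_auc_variance(y, sc)
  # oracle: resample positives/negatives with replacement and recompute AUC
  boot <- replicate(20000, {
    pos <- sample(sc[y == 1], replace = TRUE)
    neg <- sample(sc[y == 0], replace = TRUE)
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  })
  expect_lt(abs(est$var - var(boot)) / var(boot), 0.10)
})

test_that("DeLong type-I error is calibrated under the null", {
  set.seed(52)
  rej <- mean(replicate(2000, {
    y <- rep(c(0, 1), each = 20)
    delong_test(y, rnorm(40), rnorm(40))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("contingency tests reproduce the published worked examples", {
  omph <- matrix(c(9, 15, 17, 8), 2, byrow = TRUE)   # flagged/not by class
  r1 <- contingency_test(omph)
  expect_equal(r1$method, "chi-square")
  expect_equal(r1$statistic, 4.574, tolerance = 1e-3)
  expect_equal(r1$p, 0.032, tolerance = 0.02)
  renal <- matrix(c(9, 15, 2, 23), 2, byrow = TRUE)
  r2 <- contingency_test(renal)
  expect_equal(r2$statistic, 6.121, tolerance = 1e-3)
  expect_equal(r2$p, 0.013, tolerance = 0.03)
  expect_equal(contingency_test(matrix(5, 2, 2))$p, 1)
  # expected counts below 5 route to Fisher
  small <- matrix(c(1, 9, 5, 5), 2, byrow = TRUE)
  expect_equal(contingency_test(small)$method, "fisher")
  # invariance under simultaneous row and column swaps
  sw <- omph[2:1, 2:1]
  expect_equal(contingency_test(sw)$p, r1$p)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margin")
  # identical group proportions give Fisher p = 1
  prop <- matrix(c(2, 8, 1, 4), 2, byrow = TRUE)
  expect_equal(contingency_test(prop)$p, 1)
})

test_that("group comparison gates on normality and handles degenerate data", {
  x <- c(rep(1, 10), rep(1, 10))
  g <- rep(c(0, 1), each = 10)
  expect_warning(r <- group_compare(x, g), "tied")
  expect_equal(r$p, 1)
  set.seed(53)
  xn <- c(rnorm(30), rnorm(30) + 2)
  gn <- rep(c("a", "b"), each = 30)
  rn <- group_compare(xn, gn)
  expect_equal(rn$method, "welch-t")
  expect_lt(rn$p, 1e-4)
  # heavy-tailed data routes to Mann-Whitney
  xe <- c(rexp(30), rexp(30) * 3)
  re <- group_compare(xe, gn)
  expect_equal(re$method, "mann-whitney")
  # identical distributions (same values in both groups) -> p = 1
  xi <- rep(c(1, 2, 3, 7, 9), 2)  # group pattern irrelevant, values mirrored
  ri <- group_compare(xi, rep(c(0, 1), each = 5))
  expect_equal(ri$p, 1, tolerance = 1e-12)
})

test_that("power: shifted normals are detected nearly always", {
  set.seed(54)
  ps <- replicate(300, {
    x <- c(rnorm(30), rnorm(30) + 2)
    group_compare(x, rep(c(0, 1), each = 30))$p
  })
  expect_lt(median(ps), 1e-3)
})

test_that("Mann-Whitney approximation tracks the exact permutation oracle", {
  set.seed(55)
  for (i in 1:15) {
    n0 <- sample(5:8, 1); n1 <- sample(5:8, 1)
    x <- rnorm(n0 + n1)   # continuous, so the permutation distribution is exact
    g <- rep(c(0, 1), c(n0, n1))
    approx_p <- renalrad:::mwu_p(x[g == 0], x[g == 1])
    # exhaustive two-sided permutation p (doubled smaller tail, capped at 1)
    r <- rank(x)
    obs <- sum(r[g == 0])
    perm <- apply(combn(length(x), n0), 2, function(idx) sum(r[idx]))
    exact_p <- min(1, 2 * min(mean(perm <= obs), mean(perm >= obs)))
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})
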