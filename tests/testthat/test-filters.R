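test_that("LoG annihilates constants and peaks at the matching scale", {
  v <- array(7.5, c(12, 12, 12))
  expect_lt(max(abs(log_filter(v, c(1, 1, 1), 2))), 1e-6 * 7.5)
  # centred Gaussian blob of scale s: response extremal near sigma = s
  s <- 2; co <- (1:24) - 12.5
  blob <- exp(-outer(outer(co^2, co^2, "+"), co^2, "+") / (2 * s^2))
  resp <- vapply(c(0.5 * s, s, 2 * s), function(sig) {
    max(abs(log_filter(blob, c(1, 1, 1), sig)))
  }, numeric(1))
  expect_equal(which.max(resp), 2L)
  # sigma in physical units: doubling sigma and spacing together is the
  # identity in the voxel domain
  set.seed(4)
  x <- array(rnorm(10^3), c(10, 10, 10))
  expect_equal(log_filter(x, c(2, 2, 2), 3), log_filter(x, c(1, 1, 1), 1.5))
  expect_warning(log_filter(x, c(1, 1, 5), 0.3), "degenerate")
})

test_that("wavelet bank: names, constants, Parseval, exact reconstruction", {
  b <- wavelet_decompose(array(3, c(8, 8, 8)))
  expect_named(b, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_lt(max(abs(b$HHH)), 1e-6 * 3)
  expect_lt(max(abs(b$LLL - 3)), 1e-6 * 3)
  imp <- array(0, c(8, 8, 8)); imp[4, 4, 4] <- 1
  bi <- wavelet_decompose(imp)
  expect_lt(abs(sum(vapply(bi, function(v) sum(v^2), numeric(1))) - 1), 1e-6)
  set.seed(8)
  x <- array(rnorm(7 * 9 * 8), c(7, 9, 8))
  r <- wavelet_reconstruct(wavelet_decompose(x))
  expect_lt(max(abs(r - x)) / max(abs(x)), 1e-5)
  expect_error(wavelet_decompose(array(0, c(4, 8, 8))), "filter length")
})

test_that("binomial blur: impulse kernel, mean preservation, variance decay", {
  # 1D impulse embedded in 3D: a single plane along x
  v <- array(0, c(9, 6, 6)); v[5, , ] <- 1
  b <- binomial_blur(v, 1)
  expect_equal(b[4:6, 3, 3], c(0.25, 0.5, 0.25))
  expect_equal(binomial_blur(array(2.5, c(6, 6, 6)), 3), array(2.5, c(6, 6, 6)))
  set.seed(10)
  for (i in 1:10) {
    x <- array(rnorm(6^3), c(6, 6, 6))
    expect_lt(abs(mean(binomial_blur(x, 2)) - mean(x)), 1e-6 * max(1, abs(mean(x))))
    v1 <- var(as.vector(binomial_blur(x, 1)))
    v2 <- var(as.vector(binomial_blur(x, 2)))
    expect_lt(v2, v1)
    expect_lt(v1, var(as.vector(x)))
  }
})

test_that("shot noise is seed-deterministic, unbiased, and scale-sensitive", {
  x <- array(runif(5^3, 10, 50), c(5, 5, 5))
  expect_identical(shot_noise(x, 3, 1), shot_noise(x, 3, 1))
  means <- vapply(1:100, function(s) mean(shot_noise(x, s, 1)), numeric(1))
  se <- sqrt(mean(x) / length(x)) / sqrt(100)
  expect_lt(abs(mean(means) - mean(x)), 3 * se)
  # relative variance grows as the quantum scale grows (fewer counts per voxel)
  relvar <- function(scale) {
    v <- vapply(1:30, function(s) {
      y <- shot_noise(x, s + 1000, scale)
      var(as.vector(y - x))
    }, numeric(1))
    mean(v) / mean(x)^2
  }
  expect_lt(relvar(0.5), relvar(4))
  expect_error(shot_noise(x - 100, 1, 1), "nonnegative")
  y <- shot_noise(x - 100, 1, 1, shift = TRUE)
  expect_equal(dim(y), dim(x))
})

test_that("derive_image_types yields the configured bank", {
  set.seed(11)
  x <- array(rnorm(8^3, 100, 10), c(8, 8, 8))
  bank <- derive_image_types(x, c(1, 1, 1))
  expect_length(bank, 15L)
  expect_true(all(vapply(bank, function(v) identical(dim(v), dim(x)), logical(1))))
  expect_identical(names(bank)[1:3],
                   c("original", "log-sigma-1-0-mm-3D", "log-sigma-2-0-mm-3D"))
  bank2 <- derive_image_types(x, c(1, 1, 1),
                              filter_bank_config(include_noise = FALSE))
  expect_length(bank2, 11L)
  # noise filters are pure functions of (volume, seed, params)
  bank3 <- derive_image_types(x, c(1, 1, 1))
  expect_identical(bank$shotnoise, bank3$shotnoise)
  expect_identical(bank$specklenoise, bank3$specklenoise)
})
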