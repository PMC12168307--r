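test_that("discretization maps the masked range onto 1..Ng", {
  v <- array(0, c(4, 4, 2)); v[1:32] <- 0:31
  mask <- array(FALSE, c(4, 4, 2)); mask[1:32] <- TRUE
  d <- discretize(v, mask, 32)
  expect_identical(d$levels[mask], 0:31 + 1L)
  # constant region collapses to a single level
  dc <- discretize(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 32)
  expect_identical(unique(dc$levels[dc$mask]), 1L)
  expect_equal(dc$Ng, 1L)
  # histogram independent of voxel order by construction
  set.seed(1)
  v2 <- array(rnorm(27), c(3, 3, 3))
  d2 <- discretize(v2, array(TRUE, c(3, 3, 3)), 8)
  expect_equal(sort(tabulate(d2$levels[d2$mask], 8)),
               sort(tabulate(discretize(aperm(v2, c(2, 1, 3)),
                                        array(TRUE, c(3, 3, 3)), 8)$levels, 8)))
})

test_that("texture matrices satisfy their conservation invariants", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    d <- inst$d
    Np <- sum(d$mask)
    g <- build_glcm(d)
    if (sum(g$M) > 0) expect_equal(sum(g$M), 1)
    gd <- build_gldm(d)
    expect_equal(sum(gd$M), Np)
    gz <- build_glszm(d)
    expect_equal(sum(gz$M %*% seq_len(ncol(gz$M))), Np)
    gn <- build_ngtdm(d)
    if (gn$Nvp > 0) expect_equal(sum(gn$M[, "p"]), 1)
    gr <- build_glrlm(d)
    expect_equal(sum(gr$M %*% seq_len(ncol(gr$M))), 13 * Np)
  }
})

test_that("matrix builders match brute-force enumeration on small instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    d <- inst$d; Ng <- inst$Ng
    expect_equal(build_glcm(d)$M, oracle_glcm(d$levels, Ng), tolerance = 1e-12)
    expect_equal(unname(build_gldm(d)$M), unname(oracle_gldm(d$levels, Ng)))
    expect_equal(unname(build_glszm(d)$M), unname(oracle_glszm(d$levels, Ng)))
    expect_equal(unname(build_glrlm(d)$M), unname(oracle_glrlm(d$levels, Ng)))
    on <- oracle_ngtdm(d$levels, Ng)
    bn <- build_ngtdm(d)
    expect_equal(unname(bn$M[, "n"]), on$n)
    expect_equal(unname(bn$M[, "s"]), on$s, tolerance = 1e-12)
  }
})

test_that("degenerate regions take the documented feature conventions", {
  # constant 2x2x1 region: all GLCM mass at (1,1)
  v <- array(3, c(2, 2, 1)); mask <- array(TRUE, c(2, 2, 1))
  d <- discretize(v, mask, 32)
  g <- build_glcm(d)
  expect_equal(g$M[1, 1], 1)
  expect_equal(compute_feature(g, "Idmn"), 1)
  nt <- build_ngtdm(d)
  expect_equal(compute_feature(nt, "Busyness"), 0)
  expect_equal(compute_feature(v[mask], "InterquartileRange"), 0)
  # single masked voxel: empty pair set, defined values
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  d1 <- discretize(array(rnorm(27), c(3, 3, 3)), m1, 32)
  g1 <- build_glcm(d1)
  expect_equal(sum(g1$M), 0)
  expect_equal(compute_feature(g1, "Idmn"), 1)
  expect_equal(compute_feature(g1, "Contrast"), 0)
  # constant 3x3x3 cube, alpha 0: centre voxel has dependence 26
  dc <- discretize(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 32)
  gd <- build_gldm(dc)
  expect_equal(gd$M[1, 27], 1)   # column j+1 = 27 is dependence j = 26
  expect_equal(sum(gd$M), 27)
  # two disjoint equal-level islands -> 2 zones
  lv <- array(0L, c(5, 3, 3)); lv[1, 1, 1] <- 1L; lv[5, 3, 3] <- 1L
  mz <- lv > 0
  vz <- array(0, c(5, 3, 3)); dz <- discretize(vz, mz, 2)
  expect_equal(build_glszm(dz)$Nz, 2)
})

test_that("selected-feature formulas match direct-summation oracles", {
  for (seed in 41:80) {
    inst <- random_instance(seed)
    d <- inst$d; Ng <- inst$Ng
    oracle <- oracle_named_features(d$levels, Ng, inst$values)
    expect_equal(compute_feature(inst$values, "Maximum"), unname(oracle["Maximum"]))
    expect_equal(compute_feature(inst$values, "InterquartileRange"),
                 unname(oracle["InterquartileRange"]))
    expect_equal(compute_feature(build_glcm(d), "Idmn"), unname(oracle["Idmn"]),
                 tolerance = 1e-12)
    gd <- build_gldm(d)
    expect_equal(compute_feature(gd, "LargeDependenceLowGrayLevelEmphasis"),
                 unname(oracle["LargeDependenceLowGrayLevelEmphasis"]), tolerance = 1e-12)
    expect_equal(compute_feature(gd, "SmallDependenceLowGrayLevelEmphasis"),
                 unname(oracle["SmallDependenceLowGrayLevelEmphasis"]), tolerance = 1e-12)
    expect_equal(compute_feature(gd, "DependenceVariance"),
                 unname(oracle["DependenceVariance"]), tolerance = 1e-12)
    expect_equal(compute_feature(build_glszm(d), "ZonePercentage"),
                 unname(oracle["ZonePercentage"]), tolerance = 1e-12)
    expect_equal(compute_feature(build_ngtdm(d), "Busyness"),
                 unname(oracle["Busyness"]), tolerance = 1e-12)
  }
})

test_that("feature vectors: width, restriction arithmetic, purity, translation", {
  s <- small_phantom()
  mask <- s$mask_left | s$mask_right
  # the fixture grid is coarse (2.5 mm), so the 1 mm LoG scale warns by design
  v <- suppressWarnings(compute_feature_vector(s$t2w, mask, s$spacing))
  expect_length(v, 1246L)
  expect_true(all(is.finite(v)))
  # original-only manifest: 16 shape + 82 intensity
  cfg1 <- filter_bank_config(log_sigmas_mm = numeric(), wavelet = FALSE,
                             include_noise = FALSE)
  m1 <- default_bank_manifest(cfg1)
  expect_equal(nrow(m1), 98L)
  v1 <- compute_feature_vector(s$t2w, mask, s$spacing, m1, cfg = cfg1)
  expect_length(v1, 98L)
  # purity: identical inputs give identical vectors
  v2 <- compute_feature_vector(s$t2w, mask, s$spacing, m1, cfg = cfg1)
  expect_identical(v1, v2)
  # translation invariance: shift image + mask within the array (margins kept)
  set.seed(12)
  dims <- c(16, 14, 10)
  img <- array(rnorm(prod(dims), 50, 8), dims)
  msk <- array(FALSE, dims); msk[5:9, 4:8, 4:6] <- TRUE
  sh <- function(a, k) { b <- array(0, dim(a)); b[(1+k):dim(a)[1], , ] <- a[1:(dim(a)[1]-k), , ]; b }
  img2 <- sh(img, 2); msk2 <- sh(msk * 1, 2) > 0
  cfgq <- filter_bank_config(include_noise = FALSE)
  mq <- default_bank_manifest(cfgq)
  mq <- mq[mq$family != "shape", ]
  f1 <- compute_feature_vector(img, msk, c(1, 1, 2), mq, cfg = cfgq)
  f2 <- compute_feature_vector(img2, msk2, c(1, 1, 2), mq, cfg = cfgq)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("busyness rises monotonically as texture correlation length falls", {
  spec <- small_spec()
  corr_lengths <- c(10, 7.5, 5, 3.5, 2.5)
  busy <- vapply(seq_along(corr_lengths), function(i) {
    sp <- spec
    sp$texture_model[["UPD+IC1"]]$corr_mm <- corr_lengths[i]
    vals <- vapply(1:4, function(k) {
      s <- generate_kidney_phantom(sp, "UPD+IC1", 20, 5000 + k, "B")
      mask <- s$mask_left | s$mask_right
      d <- discretize(s$t2w, mask, 32)
      compute_feature(build_ngtdm(d), "Busyness")
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(cor(seq_along(corr_lengths), busy, method = "spearman"), 0.8)
})
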