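# Radiomic feature formulas and the default 1246-feature bank:
# 16 shape features on the original-geometry mask plus 82 intensity features
# (18 first-order + 64 texture) on each of the 15 derived image types.
#
# Degenerate inputs (single gray level, single voxel, empty pair/zone sets)
# map to fixed documented values (0, or 1 for the diagonal-concentration GLCM
# measures and Correlation) rather than NaN, so downstream selection never
# sees missing values.

log2p <- function(p) ifelse(p > 0, log2(p), 0)
fin <- function(x, default = 0) ifelse(is.finite(x), x, default)

## ---- first order ----------------------------------------------------------

FIRSTORDER_FEATURES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10", "Percentile90",
  "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "Kurtosis", "Variance", "Uniformity")

firstorder_features <- function(x, voxel_volume_mm3, n_bins = 32L) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rx <- x[x >= q[1] & x <= q[5]]
  # histogram probabilities at the same fixed bin count as the texture stage
  if (max(x) > min(x)) {
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)
    lv <- pmin(findInterval(x, edges), n_bins)
    ph <- tabulate(lv, n_bins) / n
  } else ph <- 1
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(ph * log2p(ph)),
    Minimum = min(x),
    Percentile10 = q[1], Percentile90 = q[5],
    Maximum = max(x), Mean = mu, Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rx - mean(rx))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = fin(mean((x - mu)^3) / m2^1.5, 0),
    Kurtosis = fin(mean((x - mu)^4) / m2^2, 0),
    Variance = m2,
    Uniformity = sum(ph^2))
}

## ---- GLCM -----------------------------------------------------------------

GLCM_FEATURES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "InverseVariance",
  "JointAverage", "JointEnergy", "JointEntropy", "MaximumProbability",
  "SumEntropy", "SumSquares")

glcm_features <- function(tm) {
  P <- tm$M; Ng <- tm$Ng
  i <- row(P); j <- col(P)
  if (sum(P) == 0) {  # single masked voxel: no pairs
    out <- stats::setNames(rep(0, length(GLCM_FEATURES)), GLCM_FEATURES)
    out[c("Correlation", "Id", "Idm", "Idmn", "Idn")] <- 1
    return(out)
  }
  px <- rowSums(P)
  mu <- sum(seq_len(Ng) * px)                      # symmetric: mu_x == mu_y
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  k_diff <- abs(i - j)
  pdiff <- vapply(0:(Ng - 1), function(k) sum(P[k_diff == k]), numeric(1))
  k_sum <- i + j
  psum <- vapply(2:(2 * Ng), function(k) sum(P[k_sum == k]), numeric(1))
  da <- sum((0:(Ng - 1)) * pdiff)
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * log2p(pdiff)),
    DifferenceVariance = sum(((0:(Ng - 1)) - da)^2 * pdiff),
    Id = sum(P / (1 + k_diff)),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + k_diff / Ng)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = -sum(P * log2p(P)),
    MaximumProbability = max(P),
    SumEntropy = -sum(psum * log2p(psum)),
    SumSquares = sig2)
}

## ---- GLRLM ----------------------------------------------------------------

GLRLM_FEATURES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "HighGrayLevelRunEmphasis",
  "LowGrayLevelRunEmphasis", "LongRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis")

glrlm_features <- function(tm) {
  R <- tm$M; Nr <- tm$Nr; Np <- tm$Np
  if (Nr == 0) return(stats::setNames(rep(0, length(GLRLM_FEATURES)), GLRLM_FEATURES))
  i <- row(R); j <- col(R)
  p <- R / Nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(ShortRunEmphasis = sum(R / j^2) / Nr,
    LongRunEmphasis = sum(R * j^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / Nr^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / Nr^2,
    RunPercentage = Nr / (Np * tm$n_directions),
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((j - mu_j)^2 * p),
    RunEntropy = -sum(p * log2p(p)),
    HighGrayLevelRunEmphasis = sum(R * i^2) / Nr,
    LowGrayLevelRunEmphasis = sum(R / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * j^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(R * j^2 / i^2) / Nr)
}

## ---- GLSZM ----------------------------------------------------------------

GLSZM_FEATURES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "HighGrayLevelZoneEmphasis",
  "LowGrayLevelZoneEmphasis", "LargeAreaHighGrayLevelEmphasis")

glszm_features <- function(tm) {
  S <- tm$M; Nz <- tm$Nz; Np <- tm$Np
  if (Nz == 0) return(stats::setNames(rep(0, length(GLSZM_FEATURES)), GLSZM_FEATURES))
  i <- row(S); s <- col(S)
  p <- S / Nz
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  c(SmallAreaEmphasis = sum(S / s^2) / Nz,
    LargeAreaEmphasis = sum(S * s^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(S)^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(S)^2) / Nz^2,
    SizeZoneNonUniformity = sum(colSums(S)^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(colSums(S)^2) / Nz^2,
    ZonePercentage = Nz / Np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    ZoneVariance = sum((s - mu_s)^2 * p),
    ZoneEntropy = -sum(p * log2p(p)),
    HighGrayLevelZoneEmphasis = sum(S * i^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(S / i^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(S * s^2 * i^2) / Nz)
}

## ---- GLDM -----------------------------------------------------------------

GLDM_FEATURES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "HighGrayLevelEmphasis",
  "LowGrayLevelEmphasis", "LargeDependenceLowGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

gldm_features <- function(tm) {
  P <- tm$M; Np <- tm$Np
  if (Np == 0) return(stats::setNames(rep(0, length(GLDM_FEATURES)), GLDM_FEATURES))
  i <- row(P); j <- col(P) - 1L          # dependence value j in 0..26
  p <- P / Np
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  jpos <- j >= 1L                        # j-in-denominator sums skip j = 0
  c(SmallDependenceEmphasis = sum(P[jpos] / j[jpos]^2) / Np,
    LargeDependenceEmphasis = sum(P * j^2) / Np,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Np,
    DependenceNonUniformity = sum(colSums(P)^2) / Np,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Np^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(p * log2p(p)),
    HighGrayLevelEmphasis = sum(P * i^2) / Np,
    LowGrayLevelEmphasis = sum(P / i^2) / Np,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Np,
    SmallDependenceLowGrayLevelEmphasis = sum(P[jpos] / (i[jpos]^2 * j[jpos]^2)) / Np)
}

## ---- NGTDM ----------------------------------------------------------------

NGTDM_FEATURES <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

ngtdm_features <- function(tm) {
  n_i <- tm$M[, "n"]; p_i <- tm$M[, "p"]; s_i <- tm$M[, "s"]
  Ng <- tm$Ng; Nvp <- tm$Nvp
  act <- which(p_i > 0)
  Ngp <- length(act)
  ps <- sum(p_i * s_i)
  if (Nvp == 0) return(stats::setNames(rep(0, length(NGTDM_FEATURES)), NGTDM_FEATURES))
  iv <- seq_len(Ng)
  # pairwise terms over active levels
  busy_den <- 0; contrast1 <- 0; complexity <- 0; strength_num <- 0
  for (a in act) for (b in act) {
    if (a == b) next
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    contrast1 <- contrast1 + p_i[a] * p_i[b] * (a - b)^2
    complexity <- complexity + abs(a - b) *
      (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
    strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
  }
  c(Coarseness = if (ps > 0) 1 / ps else 1e6,
    Contrast = if (Ngp > 1) (contrast1 / (Ngp * (Ngp - 1))) * (sum(s_i) / Nvp) else 0,
    Busyness = if (busy_den > 0) ps / busy_den else 0,
    Complexity = complexity / Nvp,
    Strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0)
}

## ---- shape ----------------------------------------------------------------

SHAPE_FEATURES <- c(
  "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity",
  "Compactness1", "Compactness2", "SphericalDisproportion",
  "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
  "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness")

# max pairwise distance among 2D points (exact, via convex hull)
max_diam_2d <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) > 2L) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  max(stats::dist(pts))
}

# convex-hull candidate points per slice along `axis` (list of mm coordinates)
slice_hull_points <- function(coord_mm, axis) {
  planes <- split.data.frame(coord_mm, coord_mm[, axis])
  do.call(rbind, lapply(planes, function(p) {
    q <- p[, -axis, drop = FALSE]
    if (nrow(q) > 2L) p[grDevices::chull(q), , drop = FALSE] else p
  }))
}

shape_features <- function(mask, spacing) {
  n <- sum(mask)
  stopifnot(n > 0)
  vv <- prod(spacing)
  V <- n * vv
  dims <- dim(mask)
  # surface area by exposed-face counting
  SA <- 0
  for (a in 1:3) {
    face_area <- prod(spacing[-a])
    off <- c(0L, 0L, 0L); off[a] <- 1L
    sr <- shift_ranges(dims, off)
    m1 <- mask[sr$from[[1]], sr$from[[2]], sr$from[[3]], drop = FALSE]
    m2 <- mask[sr$to[[1]], sr$to[[2]], sr$to[[3]], drop = FALSE]
    internal_faces <- sum(m1 & m2)
    SA <- SA + (2 * n - 2 * internal_faces) * face_area
  }
  idx <- which(mask, arr.ind = TRUE)
  coord <- sweep(idx - 0.5, 2, spacing, "*")
  # max diameters: every 3D hull vertex lies on its slice's 2D hull
  cand3 <- unique(rbind(slice_hull_points(coord, 3)))
  d3 <- if (nrow(cand3) > 1L) max(stats::dist(cand3)) else 0
  d2s <- max_diam_by_plane(coord, 3)
  d2c <- max_diam_by_plane(coord, 2)
  d2r <- max_diam_by_plane(coord, 1)
  ev <- if (n > 1) {
    e <- eigen(stats::cov(coord), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  sph <- (36 * pi * V^2)^(1 / 3) / SA
  c(VoxelVolume = V,
    SurfaceArea = SA,
    SurfaceVolumeRatio = SA / V,
    Sphericity = sph,
    Compactness1 = V / (sqrt(pi) * SA^1.5),
    Compactness2 = 36 * pi * V^2 / SA^3,
    SphericalDisproportion = 1 / sph,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2s,
    Maximum2DDiameterColumn = d2c,
    Maximum2DDiameterRow = d2r,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = fin(sqrt(ev[2] / ev[1]), 0),
    Flatness = fin(sqrt(ev[3] / ev[1]), 0))
}

max_diam_by_plane <- function(coord, axis) {
  planes <- split.data.frame(coord[, -axis, drop = FALSE], coord[, axis])
  max(vapply(planes, max_diam_2d, numeric(1)))
}

## ---- bank manifest and feature vectors ------------------------------------

FAMILY_FEATURES <- list(firstorder = FIRSTORDER_FEATURES, glcm = GLCM_FEATURES,
                        glrlm = GLRLM_FEATURES, glszm = GLSZM_FEATURES,
                        gldm = GLDM_FEATURES, ngtdm = NGTDM_FEATURES)

default_image_types <- function(cfg = filter_bank_config()) {
  nm <- character()
  if (cfg$include_original) nm <- c(nm, "original")
  nm <- c(nm, vapply(cfg$log_sigmas_mm, log_sigma_name, character(1)))
  if (cfg$wavelet) nm <- c(nm, paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                                    "HLL", "HLH", "HHL", "HHH")))
  if (cfg$include_noise) nm <- c(nm, "shotnoise", "binomialblur", "specklenoise",
                                 "additivegaussiannoise")
  nm
}

#' Default feature-bank manifest
#'
#' 16 shape features on the original-geometry mask plus, for each derived
#' image type, 18 first-order and 64 texture features (20 GLCM + 14 GLRLM +
#' 13 GLSZM + 12 GLDM + 5 NGTDM). Under the default 15-type filter bank the
#' manifest is exactly 1246 named features. Names follow the
#' `<imagetype>_<family>_<feature>` convention.
#'
#' @param cfg a [filter_bank_config()] controlling the image types.
#' @return data.frame(name, image_type, family, feature).
#' @export
default_bank_manifest <- function(cfg = filter_bank_config()) {
  types <- default_image_types(cfg)
  rows <- list(data.frame(image_type = "original", family = "shape",
                          feature = SHAPE_FEATURES))
  for (ty in types) {
    for (fam in names(FAMILY_FEATURES)) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_type = ty, family = fam, feature = FAMILY_FEATURES[[fam]])
    }
  }
  m <- do.call(rbind, rows)
  m$name <- paste(m$image_type, m$family, m$feature, sep = "_")
  if (anyDuplicated(m$name)) stop("duplicate feature names in bank manifest")
  m[, c("name", "image_type", "family", "feature")]
}

#' Compute a single named feature from a texture matrix or value vector
#'
#' @param x a `texture_matrix`, or a numeric vector of masked intensities for
#'   first-order features.
#' @param feature_name feature name within the family (e.g. `"Idmn"`,
#'   `"Busyness"`, `"Maximum"`).
#' @param voxel_volume_mm3 voxel volume, used only by first-order
#'   Energy/TotalEnergy.
#' @return numeric value.
#' @export
compute_feature <- function(x, feature_name, voxel_volume_mm3 = 1) {
  if (inherits(x, "texture_matrix")) {
    fam <- tolower(x$family)
    vals <- switch(fam,
                   glcm = glcm_features(x), glrlm = glrlm_features(x),
                   glszm = glszm_features(x), gldm = gldm_features(x),
                   ngtdm = ngtdm_features(x),
                   stop("unknown texture family: ", x$family))
  } else if (is.numeric(x)) {
    vals <- firstorder_features(x, voxel_volume_mm3)
  } else stop("x must be a texture_matrix or a numeric vector")
  if (!feature_name %in% names(vals)) {
    stop("unknown feature '", feature_name, "' for this input family")
  }
  unname(vals[feature_name])
}

# Crop arrays to the mask bounding box plus a margin, so features are
# translation invariant and filtering cost scales with the VOI, not the grid.
crop_to_mask <- function(volume, mask, margin = 4L, min_dim = 8L) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, min(idx[, a]) - margin)
    hi <- min(dims[a], max(idx[, a]) + margin)
    while (hi - lo + 1L < min_dim) {   # wavelet needs every dim >= filter length
      if (lo > 1L) lo <- lo - 1L else if (hi < dims[a]) hi <- hi + 1L else break
    }
    lo:hi
  })
  list(volume = volume[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       mask = mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
}

# All 82 intensity features for one derived image type, kept per family
# (several families share feature names, e.g. GLCM and NGTDM "Contrast").
intensity_features_for_type <- function(img, mask, spacing, n_bins) {
  x <- img[mask]
  d <- discretize(img, mask, n_bins)
  list(firstorder = firstorder_features(x, prod(spacing), n_bins),
       glcm = glcm_features(build_glcm(d)),
       glrlm = glrlm_features(build_glrlm(d)),
       glszm = glszm_features(build_glszm(d)),
       gldm = gldm_features(build_gldm(d)),
       ngtdm = ngtdm_features(build_ngtdm(d)))
}

#' Compute the full named feature vector for one volume + mask
#'
#' Applies the filter bank, then evaluates every feature in the manifest.
#' Shape features are computed once on the original-geometry mask. Any
#' non-finite feature value raises an error naming the feature.
#'
#' @param volume 3D intensity array (one MRI sequence).
#' @param mask logical 3D parenchyma mask.
#' @param spacing voxel spacing (mm).
#' @param manifest bank manifest (default [default_bank_manifest()]).
#' @param n_bins discretization bin count (default 32).
#' @param cfg filter bank config; must be consistent with the manifest's image
#'   types.
#' @return named numeric vector, one entry per manifest row (1246 by default).
#' @export
compute_feature_vector <- function(volume, mask, spacing,
                                   manifest = default_bank_manifest(),
                                   n_bins = 32L,
                                   cfg = filter_bank_config()) {
  stopifnot(identical(dim(volume), dim(mask)))
  cr <- crop_to_mask(volume, mask)
  types_needed <- unique(manifest$image_type[manifest$family != "shape"])
  bank <- derive_image_types(cr$volume, spacing, cfg)
  missing_types <- setdiff(types_needed, names(bank))
  if (length(missing_types)) {
    stop("manifest requires image types absent from the filter bank: ",
         paste(missing_types, collapse = ", "))
  }
  vals <- list()
  if (any(manifest$family == "shape")) {
    vals[["original_shape"]] <- shape_features(mask, spacing)
  }
  for (ty in types_needed) {
    f <- intensity_features_for_type(bank[[ty]], cr$mask, spacing, n_bins)
    for (fam in names(FAMILY_FEATURES)) {
      vals[[paste0(ty, "_", fam)]] <- f[[fam]]
    }
  }
  out <- numeric(nrow(manifest))
  names(out) <- manifest$name
  for (r in seq_len(nrow(manifest))) {
    block <- paste0(manifest$image_type[r], "_", manifest$family[r])
    out[r] <- vals[[block]][[manifest$feature[r]]]
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad)) stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  out
}

#' Feature table for a list of subjects
#'
#' @param subjects list of `subject_volumes`.
#' @param sequence `"t2w"` or `"adc"`.
#' @param manifest,n_bins,cfg passed to [compute_feature_vector()].
#' @return matrix subjects x features with subject IDs as row names.
#' @export
compute_feature_table <- function(subjects, sequence = c("t2w", "adc"),
                                  manifest = default_bank_manifest(),
                                  n_bins = 32L, cfg = filter_bank_config()) {
  sequence <- match.arg(sequence)
  rows <- lapply(subjects, function(s) {
    mask <- s$mask_left | s$mask_right
    compute_feature_vector(s[[sequence]], mask, s$spacing, manifest, n_bins, cfg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(subjects, function(s) s$subject_id, character(1))
  out
}
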