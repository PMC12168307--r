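# Derived-image ("filter") bank: the 15 image types on which intensity
# features are computed. Defaults: original, Laplacian-of-Gaussian at 1 and
# 2 mm, the 8 subbands of a single-level undecimated coiflet-1 wavelet
# decomposition, shot (Poisson) noise, binomial blur, speckle noise and
# additive Gaussian noise.

# coiflet-1 analysis lowpass; highpass via the quadrature mirror relation.
COIF1_H <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
             0.852572020212255, 0.337897662457809, -0.072732619512854)
coif1_g <- function() {
  h <- COIF1_H
  (-1)^(seq_along(h) - 1) * rev(h)
}

#' Laplacian-of-Gaussian filter with physical-units sigma
#'
#' Gaussian smoothing (sigma in mm, converted to voxels per axis through the
#' spacing; reflect boundary) followed by the discrete Laplacian in physical
#' units, scaled by sigma^2 (scale-normalized response). The response to a
#' constant volume is identically zero; halving/doubling sigma and spacing
#' together leaves the voxel-domain output unchanged.
#'
#' @param volume 3D array.
#' @param spacing voxel spacing (mm).
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @return filtered 3D array, same shape.
#' @export
log_filter <- function(volume, spacing, sigma_mm) {
  stopifnot(sigma_mm > 0)
  if (sigma_mm < min(spacing) / 2) {
    warning("LoG sigma ", sigma_mm, " mm is below half the smallest spacing; ",
            "the scale is degenerate on this grid")
  }
  g <- volume
  for (a in 1:3) {
    k <- gaussian_kernel(sigma_mm / spacing[a])
    if (length(k) > 1L) g <- conv_axis(g, k, a, "reflect")
  }
  lap <- array(0, dim(volume))
  for (a in 1:3) {
    d2 <- conv_axis(g, c(1, -2, 1), a, "reflect") / spacing[a]^2
    lap <- lap + d2
  }
  sigma_mm^2 * lap
}

# Forward wavelet step: circular correlation with the analysis filter.
wavelet_axis <- function(a, f, axis) {
  conv_axis(a, f, axis, "periodic")
}

# Adjoint of wavelet_axis (exact for the periodic boundary).
wavelet_axis_adjoint <- function(a, f, axis) {
  conv_axis(a, rev(f), axis, "periodic",
            anchor = length(f) + 1L - (length(f) + 1L) %/% 2L)
}

#' Single-level 3D wavelet decomposition (8 subbands)
#'
#' Undecimated (shape-preserving) separable coiflet-1 decomposition with
#' periodic boundary. Filters are scaled by 1/sqrt(2) per axis so the 8-band
#' transform is a tight frame: subband energies sum to the input energy and
#' [wavelet_reconstruct()] inverts it exactly. Subband names are the
#' axis-ordered L/H strings LLL, LLH, ..., HHH; the LLL band of a constant
#' volume is that constant and every H-containing band is ~0.
#'
#' @param volume 3D array; each dimension must be at least the filter length (6).
#' @return named list of 8 subband arrays.
#' @export
wavelet_decompose <- function(volume) {
  dims <- dim(volume)
  if (any(dims < length(COIF1_H))) {
    stop("every dimension must be >= the wavelet filter length (",
         length(COIF1_H), ")")
  }
  h <- COIF1_H / sqrt(2)
  g <- coif1_g() / sqrt(2)
  bands <- stats::setNames(list(volume), "root")
  for (axis in 1:3) {
    nb <- list()
    for (i in seq_along(bands)) {
      b <- if (names(bands)[i] == "root") "" else names(bands)[i]
      nb[[paste0(b, "L")]] <- wavelet_axis(bands[[i]], h, axis)
      nb[[paste0(b, "H")]] <- wavelet_axis(bands[[i]], g, axis)
    }
    bands <- nb
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Invert [wavelet_decompose()]
#'
#' Applies the adjoint filters and sums over subbands; exact up to the
#' numerical precision of the filter coefficients.
#'
#' @param bands named list from [wavelet_decompose()].
#' @return reconstructed 3D array.
#' @export
wavelet_reconstruct <- function(bands) {
  h <- COIF1_H / sqrt(2)
  g <- coif1_g() / sqrt(2)
  out <- array(0, dim(bands[[1]]))
  for (b in names(bands)) {
    x <- bands[[b]]
    code <- strsplit(b, "")[[1]]
    for (axis in 3:1) {
      f <- if (code[axis] == "L") h else g
      x <- wavelet_axis_adjoint(x, f, axis)
    }
    out <- out + x
  }
  out
}

#' Binomial blur
#'
#' The separable kernel (1,2,1)/4 applied `iterations` times along each axis
#' under a periodic boundary, so the mean intensity is preserved exactly.
#'
#' @param volume 3D array.
#' @param iterations number of passes (>= 1).
#' @return blurred array.
#' @export
binomial_blur <- function(volume, iterations = 1L) {
  stopifnot(iterations >= 1L)
  out <- volume
  k <- c(1, 2, 1) / 4
  for (i in seq_len(iterations)) {
    for (a in 1:3) out <- conv_axis(out, k, a, "periodic")
  }
  out
}

#' Shot (Poisson) noise
#'
#' Voxelwise Poisson resampling: `y = scale * Poisson(x / scale)`. Smaller
#' `scale` means finer quanta and lower relative noise. Deterministic under
#' `seed`.
#'
#' @param volume nonnegative 3D array (or set `shift = TRUE` to shift an
#'   affine-negative volume into range and back).
#' @param seed RNG seed.
#' @param scale quantum size (> 0).
#' @param shift allow negative input by shifting by its minimum.
#' @return noisy array.
#' @export
shot_noise <- function(volume, seed, scale = 1, shift = FALSE) {
  stopifnot(scale > 0)
  m <- min(volume)
  if (m < 0) {
    if (!shift) stop("shot noise requires nonnegative intensities; ",
                     "set shift = TRUE to shift the volume into range")
    volume <- volume - m
  }
  out <- with_seed(seed, {
    array(stats::rpois(length(volume), volume / scale) * scale, dim(volume))
  })
  if (m < 0) out <- out + m
  out
}

#' Speckle (multiplicative) noise
#'
#' `y = x * (1 + sd * Z)`, `Z ~ N(0,1)`; deterministic under `seed`.
#' @param volume 3D array.
#' @param seed RNG seed.
#' @param sd relative noise SD.
#' @return noisy array.
#' @export
speckle_noise <- function(volume, seed, sd = 0.05) {
  with_seed(seed, volume * (1 + sd * array(stats::rnorm(length(volume)), dim(volume))))
}

#' Additive Gaussian noise
#'
#' `y = x + N(0, sd)` with `sd` given as a fraction of the volume's intensity
#' SD (absolute if `absolute = TRUE`); deterministic under `seed`.
#' @param volume 3D array.
#' @param seed RNG seed.
#' @param sd noise SD (relative by default).
#' @param absolute interpret `sd` as absolute.
#' @return noisy array.
#' @export
additive_gaussian_noise <- function(volume, seed, sd = 0.05, absolute = FALSE) {
  s <- if (absolute) sd else sd * stats::sd(volume)
  with_seed(seed, volume + array(stats::rnorm(length(volume), 0, max(s, .Machine$double.eps)),
                                 dim(volume)))
}

#' Filter bank configuration
#'
#' The default yields exactly 15 image types: original, LoG at 1 and 2 mm,
#' 8 wavelet subbands, and 4 noise-type images (shot noise, binomial blur,
#' speckle, additive Gaussian). `include_noise = FALSE` drops the 4 noise
#' types (11 image types).
#'
#' @param include_original keep the unfiltered image.
#' @param log_sigmas_mm LoG scales in mm.
#' @param wavelet include the 8 subbands.
#' @param include_noise include the 4 noise-type images.
#' @param shot_scale,binomial_iterations,speckle_sd,gauss_sd noise parameters.
#' @param noise_seed seed for the stochastic noise filters.
#' @return object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(include_original = TRUE,
                               log_sigmas_mm = c(1, 2),
                               wavelet = TRUE,
                               include_noise = TRUE,
                               shot_scale = 1,
                               binomial_iterations = 1L,
                               speckle_sd = 0.05,
                               gauss_sd = 0.05,
                               noise_seed = 42L) {
  structure(list(include_original = include_original,
                 log_sigmas_mm = log_sigmas_mm, wavelet = wavelet,
                 include_noise = include_noise, shot_scale = shot_scale,
                 binomial_iterations = binomial_iterations,
                 speckle_sd = speckle_sd, gauss_sd = gauss_sd,
                 noise_seed = as.integer(noise_seed)),
            class = "filter_bank_config")
}

log_sigma_name <- function(s) {
  sprintf("log-sigma-%s-mm-3D", gsub("\\.", "-", format(s, nsmall = 1)))
}

#' Derive the named image-type bank from one volume
#'
#' @param volume 3D array (the raw image).
#' @param spacing voxel spacing in mm.
#' @param cfg a [filter_bank_config()].
#' @return named list of derived volumes (15 under the default config), all
#'   sharing the input shape.
#' @export
derive_image_types <- function(volume, spacing, cfg = filter_bank_config()) {
  out <- list()
  if (cfg$include_original) out[["original"]] <- volume
  for (s in cfg$log_sigmas_mm) {
    out[[log_sigma_name(s)]] <- log_filter(volume, spacing, s)
  }
  if (cfg$wavelet) {
    wb <- wavelet_decompose(volume)
    names(wb) <- paste0("wavelet-", names(wb))
    out <- c(out, wb)
  }
  if (cfg$include_noise) {
    vmin <- min(volume)
    out[["shotnoise"]] <- shot_noise(volume, derive_seed(cfg$noise_seed, 1L),
                                     cfg$shot_scale, shift = vmin < 0)
    out[["binomialblur"]] <- binomial_blur(volume, cfg$binomial_iterations)
    out[["specklenoise"]] <- speckle_noise(volume, derive_seed(cfg$noise_seed, 2L),
                                           cfg$speckle_sd)
    out[["additivegaussiannoise"]] <- additive_gaussian_noise(
      volume, derive_seed(cfg$noise_seed, 3L), cfg$gauss_sd)
  }
  if (anyDuplicated(names(out))) stop("duplicate image-type names in filter bank")
  out
}
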