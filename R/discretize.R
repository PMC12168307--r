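# Fixed-bin-count discretization of masked intensities. The per-image-type
# quantization makes filtered (negative-valued) images well-defined.

#' Discretize a masked volume to integer gray levels
#'
#' Fixed-bin-count quantization over the masked intensity range: the minimum
#' maps to level 1 and the maximum to level `n_bins`. A constant masked region
#' collapses to a single level (Ng = 1) - a documented degenerate path, not an
#' error. Unmasked voxels carry level 0 as the excluded sentinel.
#'
#' @param volume 3D array.
#' @param mask logical 3D array (nonempty).
#' @param n_bins number of gray levels (>= 2).
#' @return object of class `discretized_voi`: list(levels = integer 3D array
#'   with 0 outside the mask, Ng, bin_edges, mask, spacing is carried by the
#'   caller).
#' @export
discretize <- function(volume, mask, n_bins = 32L) {
  stopifnot(n_bins >= 2L, any(mask))
  x <- volume[mask]
  lo <- min(x); hi <- max(x)
  levels <- array(0L, dim(volume))
  if (hi == lo) {
    levels[mask] <- 1L
    return(structure(list(levels = levels, Ng = 1L, bin_edges = c(lo, hi),
                          mask = mask), class = "discretized_voi"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  lv <- findInterval(x, edges)
  lv[lv > n_bins] <- n_bins    # the maximum lands in the last closed bin
  levels[mask] <- as.integer(lv)
  structure(list(levels = levels, Ng = as.integer(n_bins), bin_edges = edges,
                 mask = mask), class = "discretized_voi")
}
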