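#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic substream seed under a master seed
#'
#' Integer hash of (master seed, stream index), kept below 2^31 - 1 so it is
#' always a valid R RNG seed. All per-subject, per-fold and per-noise-filter
#' streams in the package derive from the master seed through this function.
#'
#' @param master_seed integer master seed.
#' @param idx integer stream index.
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, idx) {
  as.integer((as.numeric(master_seed) %% 1000003L) * 2047 +
               (as.numeric(idx) %% 1000003L) * 8191 + 17) %% 2147483647L
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one per +/- pair).
.offsets13 <- local({
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  keep <- o$dz > 0 | (o$dz == 0 & o$dy > 0) | (o$dz == 0 & o$dy == 0 & o$dx > 0)
  m <- as.matrix(o[keep, , drop = FALSE])
  rownames(m) <- NULL
  m
})
offsets13 <- function() .offsets13

# All 26 neighbour offsets.
.offsets26 <- rbind(.offsets13, -.offsets13)
offsets26 <- function() .offsets26

# Index vectors describing the overlap of an array with itself shifted by
# `off` (in-bounds region only). Returns list(from = list(i,j,k), to = ...).
shift_ranges <- function(dims, off) {
  f <- vector("list", 3L)
  t2 <- vector("list", 3L)
  for (a in 1:3) {
    d <- dims[a]; o <- off[a]
    if (o >= 0) { f[[a]] <- seq_len(d - o); t2[[a]] <- seq_len(d - o) + o }
    else        { f[[a]] <- seq_len(d + o) - o; t2[[a]] <- seq_len(d + o) }
  }
  list(from = f, to = t2)
}

# Boundary-extended index lookup along one axis.
reflect_index <- function(i, n) {
  # whole-sample symmetric reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  # repeat in case the kernel overshoots twice on tiny axes
  while (any(i < 1L | i > n)) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
  }
  i
}

periodic_index <- function(i, n) ((i - 1L) %% n) + 1L

# Separable 1D correlation of a 3D array along `axis` with kernel `k`:
# out[i] = sum_j k[j] * a[i + j - anchor], under "reflect" or "periodic"
# boundary. The default anchor centres odd kernels.
conv_axis <- function(a, k, axis, boundary = c("reflect", "periodic"),
                      anchor = (length(k) + 1L) %/% 2L) {
  boundary <- match.arg(boundary)
  dims <- dim(a)
  n <- dims[axis]
  out <- array(0, dims)
  idx <- function(shifted) {
    ii <- lapply(seq_len(3L), function(ax) seq_len(dims[ax]))
    ii[[axis]] <- shifted
    a[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  }
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    src <- seq_len(n) + (j - anchor)
    src <- if (boundary == "reflect") reflect_index(src, n) else periodic_index(src, n)
    out <- out + k[j] * idx(src)
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox < 0.25) return(1)  # degenerate scale: identity
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
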