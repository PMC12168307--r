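# The five gray-level texture-matrix families, built from a discretized VOI.
#
# All builders operate on the level array (0 = outside mask) with fully
# vectorized neighbour arithmetic over the 13 unique 3D offsets at Chebyshev
# distance 1 (26-neighbourhood). Results are `texture_matrix` objects holding
# the matrix and its normalization constants.

texture_matrix <- function(family, M, Ng, Np, extras = list()) {
  structure(c(list(family = family, M = M, Ng = Ng, Np = Np), extras),
            class = "texture_matrix")
}

# Zero-padded vector view of a level array: `lv` is the padded level vector,
# `idx` the padded linear indices of masked voxels, and `deltas(off)` maps a
# voxel offset to a linear-index shift, so neighbour levels are single gathers
# lv[idx + delta] with the pad absorbing out-of-bounds reads.
padded_levels <- function(levels) {
  dims <- dim(levels)
  pd <- dims + 2L
  p <- array(0L, pd)
  p[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- levels
  lv <- as.integer(p)
  list(lv = lv, idx = which(lv > 0L),
       delta = function(off) off[1] + off[2] * pd[1] + off[3] * pd[1] * pd[2])
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Counts of co-occurring level pairs over the 13 unique direction offsets at
#' Chebyshev distance 1, pooled over directions, symmetrized and normalized to
#' sum 1. Neighbours outside the mask are excluded. A single masked voxel has
#' no pairs and yields the defined zero matrix.
#'
#' @param d a `discretized_voi`.
#' @return `texture_matrix` with family "GLCM"; `M` is the Ng x Ng probability
#'   matrix (sum 1, or all zero when no pairs exist).
#' @export
build_glcm <- function(d) {
  Ng <- d$Ng
  pl <- padded_levels(d$levels)
  a <- pl$lv[pl$idx]
  counts <- matrix(0, Ng, Ng)
  o13 <- offsets13()
  for (r in seq_len(nrow(o13))) {
    b <- pl$lv[pl$idx + pl$delta(o13[r, ])]
    keep <- b > 0L
    if (!any(keep)) next
    tab <- tabulate((a[keep] - 1L) * Ng + b[keep], nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng, byrow = TRUE)
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  M <- if (tot > 0) counts / tot else counts
  texture_matrix("GLCM", M, Ng, sum(d$mask))
}

#' Gray-level dependence matrix (GLDM)
#'
#' `P(i, j)` counts masked voxels of level `i` having exactly `j` neighbours
#' (26-neighbourhood, restricted to the mask) within `|level difference| <=
#' alpha`. The dependence index `j` ranges 0..26 and is stored in column
#' `j + 1`; the matrix total equals the number of masked voxels.
#'
#' @param d a `discretized_voi`.
#' @param alpha dependence tolerance (>= 0).
#' @return `texture_matrix` with family "GLDM"; `M` is Ng x 27.
#' @export
build_gldm <- function(d, alpha = 0) {
  stopifnot(alpha >= 0)
  pl <- padded_levels(d$levels)
  a <- pl$lv[pl$idx]
  dep <- integer(length(a))
  o26 <- offsets26()
  for (r in seq_len(nrow(o26))) {
    b <- pl$lv[pl$idx + pl$delta(o26[r, ])]
    dep <- dep + (b > 0L & abs(a - b) <= alpha)
  }
  M <- matrix(tabulate((a - 1L) * 27L + dep + 1L, nbins = d$Ng * 27L),
              d$Ng, 27L, byrow = TRUE)
  texture_matrix("GLDM", M, d$Ng, sum(d$mask))
}

#' Gray-level run length matrix (GLRLM)
#'
#' Maximal runs of equal level along each of the 13 unique directions,
#' restricted to the mask, aggregated by summation over directions.
#' `M[i, l]` is the number of runs of level `i` and length `l`.
#'
#' @param d a `discretized_voi`.
#' @return `texture_matrix` with family "GLRLM"; extras carry `Nr` (total
#'   runs) and `n_directions` (13).
#' @export
build_glrlm <- function(d) {
  lv <- d$levels
  dims <- dim(lv)
  maxlen <- max(dims)
  counts <- matrix(0, d$Ng, maxlen)
  trav <- glrlm_traversals(dims)
  for (tr in trav) {
    lvo <- as.integer(lv)[tr$o]
    n <- length(lvo)
    # break runs at line changes / position gaps (precomputed) or level changes
    newrun <- c(TRUE, tr$linebreak | lvo[-1] != lvo[-n])
    rl <- tabulate(cumsum(newrun))
    rlev <- lvo[newrun]
    keep <- rlev > 0L
    if (!any(keep)) next
    tab <- tabulate((rlev[keep] - 1L) * maxlen + pmin(rl[keep], maxlen),
                    nbins = d$Ng * maxlen)
    counts <- counts + matrix(tab, d$Ng, maxlen, byrow = TRUE)
  }
  # trim trailing all-zero run lengths (keep at least one column)
  last <- max(1L, max(which(colSums(counts) > 0), 1L))
  counts <- counts[, seq_len(last), drop = FALSE]
  texture_matrix("GLRLM", counts, d$Ng, sum(d$mask),
                 extras = list(Nr = sum(counts), n_directions = 13L))
}

# Per-direction traversal orders for GLRLM depend only on the array shape, so
# they are memoized (one shape at a time): `o` orders voxels line-by-line along
# the direction and `linebreak[i]` marks where consecutive ordered voxels do
# not continue the same line.
.glrlm_cache <- new.env(parent = emptyenv())
glrlm_traversals <- function(dims) {
  key <- paste(dims, collapse = "x")
  if (identical(.glrlm_cache$key, key)) return(.glrlm_cache$trav)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  maxlen <- max(dims)
  o13 <- offsets13()
  trav <- vector("list", nrow(o13))
  for (r in seq_len(nrow(o13))) {
    off <- o13[r, ]
    step <- sum(off^2)  # t advances by |d|^2 between consecutive line voxels
    t_pos <- as.vector(coords %*% off)
    # line id: the projection coords*|d|^2 - t*d is constant exactly along the
    # line through a voxel in direction d (integer arithmetic, no fractions)
    base <- coords * step - outer(t_pos, off)
    M <- 13 * maxlen + 7
    key_l <- (base[, 1] + 6 * maxlen) + (base[, 2] + 6 * maxlen) * M +
      (base[, 3] + 6 * maxlen) * M^2
    o <- order(key_l, t_pos)
    keyo <- key_l[o]; to <- t_pos[o]
    n <- length(o)
    trav[[r]] <- list(o = o,
                      linebreak = keyo[-1] != keyo[-n] | to[-1] != to[-n] + step)
  }
  .glrlm_cache$key <- key
  .glrlm_cache$trav <- trav
  trav
}

#' Gray-level size zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal level within the mask.
#' `M[i, s]` counts zones of level `i` and size `s` voxels.
#'
#' @param d a `discretized_voi`.
#' @return `texture_matrix` with family "GLSZM"; extras carry `Nz` (zone
#'   count) and `zone_sizes`.
#' @export
build_glszm <- function(d) {
  pl <- padded_levels(d$levels)
  vox <- pl$idx
  if (length(vox) == 0L) {
    return(texture_matrix("GLSZM", matrix(0, d$Ng, 1), d$Ng, 0,
                          extras = list(Nz = 0, zone_sizes = integer())))
  }
  node <- integer(length(pl$lv))
  node[vox] <- seq_along(vox)
  a <- pl$lv[vox]
  edges <- list(); ei <- 0L
  o13 <- offsets13()
  for (r in seq_len(nrow(o13))) {
    nbi <- vox + pl$delta(o13[r, ])
    b <- pl$lv[nbi]
    ok <- b > 0L & a == b
    if (any(ok)) {
      ei <- ei + 1L
      edges[[ei]] <- rbind(node[vox[ok]], node[nbi[ok]])
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (ei > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)
  zl <- a
  zone_level <- integer(comp$no)
  first <- !duplicated(comp$membership)
  zone_level[comp$membership[first]] <- zl[first]
  zone_size <- as.integer(comp$csize)
  maxs <- max(zone_size)
  M <- matrix(tabulate((zone_level - 1L) * maxs + zone_size, nbins = d$Ng * maxs),
              d$Ng, maxs, byrow = TRUE)
  texture_matrix("GLSZM", M, d$Ng, sum(d$mask),
                 extras = list(Nz = comp$no, zone_sizes = zone_size))
}

#' Neighbouring gray tone difference matrix (NGTDM)
#'
#' For each level `i`: `n_i` counts masked voxels of level `i` having at least
#' one masked 26-neighbour, `p_i = n_i / sum(n)`, and `s_i` is the sum over
#' those voxels of `|i - mean(neighbour levels)|`.
#'
#' @param d a `discretized_voi`.
#' @return `texture_matrix` with family "NGTDM"; `M` is the 3-column matrix
#'   cbind(n_i, p_i, s_i); extras carry `Nvp` (voxels with neighbours).
#' @export
build_ngtdm <- function(d) {
  pl <- padded_levels(d$levels)
  a <- pl$lv[pl$idx]
  nb_sum <- numeric(length(a))
  nb_cnt <- integer(length(a))
  o26 <- offsets26()
  for (r in seq_len(nrow(o26))) {
    b <- pl$lv[pl$idx + pl$delta(o26[r, ])]
    inb <- b > 0L
    nb_sum <- nb_sum + b * inb
    nb_cnt <- nb_cnt + inb
  }
  sel <- nb_cnt > 0L
  lvs <- a[sel]
  diffs <- abs(lvs - nb_sum[sel] / nb_cnt[sel])
  n_i <- tabulate(lvs, nbins = d$Ng)
  s_i <- as.vector(tapply(diffs, factor(lvs, levels = seq_len(d$Ng)), sum))
  s_i[is.na(s_i)] <- 0
  Nvp <- sum(n_i)
  p_i <- if (Nvp > 0) n_i / Nvp else rep(0, d$Ng)
  texture_matrix("NGTDM", cbind(n = n_i, p = p_i, s = s_i), d$Ng, sum(d$mask),
                 extras = list(Nvp = Nvp))
}
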