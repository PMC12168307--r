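# Brute-force enumeration oracles for the texture-matrix families and the
# named features. Deliberately naive (explicit voxel loops, recursive flood
# fill, direct summation) and independent of the package implementation.

oracle_offsets26 <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

oracle_neighbors <- function(dims, v) {
  out <- list()
  for (r in seq_len(nrow(oracle_offsets26))) {
    u <- v + oracle_offsets26[r, ]
    if (all(u >= 1) && all(u <= dims)) out[[length(out) + 1L]] <- u
  }
  out
}

# levels: integer array with 0 outside the mask
oracle_glcm <- function(levels, Ng) {
  dims <- dim(levels)
  C <- matrix(0, Ng, Ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    i <- levels[x, y, z]
    if (i == 0) next
    for (nb in oracle_neighbors(dims, c(x, y, z))) {
      j <- levels[nb[1], nb[2], nb[3]]
      if (j > 0) C[i, j] <- C[i, j] + 1
    }
  }
  if (sum(C) > 0) C / sum(C) else C
}

oracle_gldm <- function(levels, Ng, alpha = 0) {
  dims <- dim(levels)
  P <- matrix(0, Ng, 27)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    i <- levels[x, y, z]
    if (i == 0) next
    dep <- 0
    for (nb in oracle_neighbors(dims, c(x, y, z))) {
      j <- levels[nb[1], nb[2], nb[3]]
      if (j > 0 && abs(i - j) <= alpha) dep <- dep + 1
    }
    P[i, dep + 1] <- P[i, dep + 1] + 1
  }
  P
}

# recursive flood fill over 26-connected equal-level components
oracle_glszm <- function(levels, Ng) {
  dims <- dim(levels)
  seen <- array(FALSE, dims)
  zones <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (levels[x, y, z] == 0 || seen[x, y, z]) next
    lv <- levels[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (nb in oracle_neighbors(dims, v)) {
        if (!seen[nb[1], nb[2], nb[3]] && levels[nb[1], nb[2], nb[3]] == lv) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  if (!length(zones)) return(matrix(0, Ng, 1))
  zs <- do.call(rbind, zones)
  S <- matrix(0, Ng, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) S[zs[r, 1], zs[r, 2]] <- S[zs[r, 1], zs[r, 2]] + 1
  S
}

# explicit line walks along the 13 canonical directions
oracle_glrlm <- function(levels, Ng) {
  dims <- dim(levels)
  dirs <- renalrad:::offsets13()
  counts <- matrix(0, Ng, max(dims))
  inb <- function(v) all(v >= 1) && all(v <= dims)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
      v <- c(x, y, z)
      prev <- v - d
      if (inb(prev)) next  # only start walking at the first voxel of each line
      while (inb(v)) {
        lv <- levels[v[1], v[2], v[3]]
        if (lv > 0) {
          len <- 0
          u <- v
          while (inb(u) && levels[u[1], u[2], u[3]] == lv) {
            len <- len + 1
            u <- u + d
          }
          counts[lv, len] <- counts[lv, len] + 1
          v <- u
        } else {
          v <- v + d
        }
      }
    }
  }
  last <- max(1, max(which(colSums(counts) > 0), 1))
  counts[, seq_len(last), drop = FALSE]
}

oracle_ngtdm <- function(levels, Ng) {
  dims <- dim(levels)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    i <- levels[x, y, z]
    if (i == 0) next
    nbs <- c()
    for (nb in oracle_neighbors(dims, c(x, y, z))) {
      j <- levels[nb[1], nb[2], nb[3]]
      if (j > 0) nbs <- c(nbs, j)
    }
    if (length(nbs) == 0) next
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nbs))
  }
  Nvp <- sum(n_i)
  p_i <- if (Nvp > 0) n_i / Nvp else n_i
  list(n = n_i, p = p_i, s = s_i, Nvp = Nvp)
}

# Direct-summation oracles for the named features of the worked-example set
# (the distinct features of the selected-feature table), evaluated from the
# brute-force matrices above.
oracle_named_features <- function(levels, Ng, values) {
  Np <- sum(levels > 0)
  P <- oracle_glcm(levels, Ng)
  D <- oracle_gldm(levels, Ng)
  S <- oracle_glszm(levels, Ng)
  Ntg <- oracle_ngtdm(levels, Ng)
  idmn <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    idmn <- idmn + P[i, j] / (1 + (i - j)^2 / Ng^2)
  }
  if (sum(P) == 0) idmn <- 1
  ldlgle <- 0; sdlgle <- 0; mu_j <- 0
  for (i in seq_len(Ng)) for (jc in 1:27) {
    j <- jc - 1
    ldlgle <- ldlgle + D[i, jc] * j^2 / i^2
    if (j >= 1) sdlgle <- sdlgle + D[i, jc] / (i^2 * j^2)
    mu_j <- mu_j + D[i, jc] / Np * j
  }
  depvar <- 0
  for (i in seq_len(Ng)) for (jc in 1:27) {
    depvar <- depvar + D[i, jc] / Np * ((jc - 1) - mu_j)^2
  }
  busy_num <- sum(Ntg$p * Ntg$s)
  busy_den <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    if (i != j && Ntg$p[i] > 0 && Ntg$p[j] > 0) {
      busy_den <- busy_den + abs(i * Ntg$p[i] - j * Ntg$p[j])
    }
  }
  c(Maximum = max(values),
    InterquartileRange = unname(diff(quantile(values, c(0.25, 0.75)))),
    Idmn = idmn,
    LargeDependenceLowGrayLevelEmphasis = ldlgle / Np,
    SmallDependenceLowGrayLevelEmphasis = sdlgle / Np,
    DependenceVariance = depvar,
    ZonePercentage = sum(S) / Np,
    Busyness = if (busy_den > 0) busy_num / busy_den else 0)
}

# random small discretized instance (<= 6^3 voxels, Ng <= 4)
random_instance <- function(seed) {
  set.seed(seed)
  dims <- sample(2:6, 3, replace = TRUE)
  Ng <- sample(2:4, 1)
  mask <- array(runif(prod(dims)) > 0.3, dims)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  vals <- array(rnorm(prod(dims)), dims)
  d <- discretize(vals, mask, Ng)
  list(d = d, values = vals[mask], Ng = d$Ng, dims = dims)
}
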