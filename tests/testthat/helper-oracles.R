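# Independent brute-force oracles for the texture matrices: plain nested
# loops over voxels, kept deliberately naive and separate from the package's
# vectorized implementations.

oracle_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

oracle_offsets_13 <- function() {
  offs <- oracle_offsets_26()
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  offs[keep, , drop = FALSE]
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# Symmetric co-occurrence counts for one direction offset.
oracle_glcm <- function(lev, d, ng) {
  dims <- dim(lev)
  m <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + d
    if (!in_grid(q, dims)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# Run-length counts for one direction: walk every line, breaking runs at ROI
# gaps and level changes.
oracle_glrlm <- function(lev, d, ng) {
  dims <- dim(lev)
  maxlen <- max(dims)
  m <- matrix(0, ng, maxlen)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    p <- c(x, y, z)
    v <- lev[x, y, z]
    if (is.na(v)) next
    # run starts here iff the previous voxel along -d is not part of a run
    prev <- p - d
    if (in_grid(prev, dims)) {
      pv <- lev[prev[1], prev[2], prev[3]]
      if (!is.na(pv) && pv == v) next
    }
    len <- 1
    q <- p + d
    while (in_grid(q, dims)) {
      qv <- lev[q[1], q[2], q[3]]
      if (is.na(qv) || qv != v) break
      len <- len + 1
      q <- q + d
    }
    m[v, len] <- m[v, len] + 1
  }
  m
}

# 26-connected zones by flood fill.
oracle_glszm <- function(lev, ng) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  offs <- oracle_offsets_26()
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    v <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (!in_grid(q, dims)) next
        if (seen[q[1], q[2], q[3]]) next
        qv <- lev[q[1], q[2], q[3]]
        if (is.na(qv) || qv != v) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue <- c(queue, list(q))
      }
    }
    zones[[length(zones) + 1]] <- c(level = v, size = size)
  }
  maxsz <- max(vapply(zones, function(z) z[["size"]], numeric(1)))
  m <- matrix(0, ng, maxsz)
  for (z in zones) m[z[["level"]], z[["size"]]] <- m[z[["level"]], z[["size"]]] + 1
  m
}

# Dependence counts: D(i, d) with d = number of similar 26-neighbors.
oracle_gldm <- function(lev, ng, alpha = 0) {
  dims <- dim(lev)
  offs <- oracle_offsets_26()
  dep <- list()
  maxdep <- 0
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    cnt <- 0
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (!in_grid(q, dims)) next
      qv <- lev[q[1], q[2], q[3]]
      if (!is.na(qv) && abs(qv - v) <= alpha) cnt <- cnt + 1
    }
    dep[[length(dep) + 1]] <- c(level = v, dep = cnt)
    maxdep <- max(maxdep, cnt)
  }
  m <- matrix(0, ng, maxdep + 1)
  for (d in dep) m[d[["level"]], d[["dep"]] + 1] <- m[d[["level"]], d[["dep"]] + 1] + 1
  m
}

# NGTDM n_i / s_i vectors over voxels with at least one valid neighbor.
oracle_ngtdm <- function(lev, ng) {
  dims <- dim(lev)
  offs <- oracle_offsets_26()
  n_i <- numeric(ng)
  s_i <- numeric(ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (!in_grid(q, dims)) next
      qv <- lev[q[1], q[2], q[3]]
      if (!is.na(qv)) nb <- c(nb, qv)
    }
    if (!length(nb)) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  list(n_i = n_i, s_i = s_i)
}

# Build a discretized_roi directly from an integer level array (NA outside
# the ROI), bypassing the preprocessing path.
droi_from_levels <- function(lev, spacing = c(1, 1, 1), bin_width = 25) {
  vals <- (lev[!is.na(lev)] - 1) * bin_width
  img <- array(0, dim(lev))
  img[!is.na(lev)] <- vals
  msk <- array(as.integer(!is.na(lev)), dim(lev))
  discretize_roi(image_volume(img, spacing), roi_mask(msk, spacing), bin_width)
}

# Random small ROI with controlled level count; NA-holes make the ROI
# non-convex so boundary truncation paths are exercised.
random_levels <- function(dims, ng, p_hole = 0.2) {
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  holes <- array(runif(prod(dims)) < p_hole, dims)
  if (all(holes)) holes[1] <- FALSE
  lev[holes] <- NA_integer_
  lev
}

# Mann-Whitney AUC by exhaustive pair counting.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
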