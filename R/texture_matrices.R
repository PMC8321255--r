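# Construction of the five texture matrices from a discretized ROI.
# All scans use the 26-neighborhood: the 13 unique direction offsets (one per
# antipodal pair) for pairwise scans, applied in both orders where needed.

new_texture_matrix <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> kind=%s\n", x$kind))
  invisible(x)
}

#' Gray level co-occurrence matrix (GLCM)
#'
#' Counts co-occurring gray-level pairs at Chebyshev distance 1 along each of
#' the 13 unique 3D directions, restricted to voxel pairs that both lie inside
#' the ROI. Each direction's matrix is symmetric (pairs counted in both
#' orders); features are later computed per direction on the normalized matrix
#' and averaged with equal weights.
#'
#' @param droi a [discretize_roi()] result.
#' @return A `texture_matrix` with `kind = "GLCM"`, the per-direction count
#'   matrices in `$directions`, and the offsets in `$offsets`.
#' @export
glcm_matrix <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  ng <- droi$ng
  offs <- direction_offsets_13()
  dirs <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(droi$levels, offs[k, ])
    m <- matrix(0, ng, ng)
    if (length(pr$a)) {
      tab <- table(factor(c(pr$a, pr$b), levels = 1:ng),
                   factor(c(pr$b, pr$a), levels = 1:ng))
      m <- m + unclass(tab)
    }
    dimnames(m) <- NULL
    dirs[[k]] <- m
  }
  new_texture_matrix("GLCM", ng = ng, directions = dirs, offsets = offs)
}

#' Gray level run length matrix (GLRLM)
#'
#' Counts maximal runs of consecutive equal gray levels along each of the 13
#' unique 3D directions; runs are truncated at the ROI boundary. Features are
#' computed per direction and averaged with equal weights.
#'
#' @inheritParams glcm_matrix
#' @return A `texture_matrix` with `kind = "GLRLM"`, per-direction count
#'   matrices (gray level x run length) in `$directions`, and `$n_voxels`.
#' @export
glrlm_matrix <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- droi$levels
  ng <- droi$ng
  dims <- dim(lev)
  maxlen <- max(dims)
  offs <- direction_offsets_13()
  inroi <- which(!is.na(lev))
  coords <- arrayInd(inroi, dims)
  vals <- lev[inroi]
  dirs <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    ax <- which(d != 0)[1]            # first nonzero component is +1
    t <- coords[, ax]
    lid <- coords - outer(t, d)       # line identifier: start point of the line
    key <- (lid[, 1] + dims[1]) +
      (lid[, 2] + dims[2]) * (2 * dims[1] + 1) +
      (lid[, 3] + dims[3]) * (2 * dims[1] + 1) * (2 * dims[2] + 1)
    ord <- order(key, t)
    kv <- key[ord]; tv <- t[ord]; lv <- vals[ord]
    n <- length(lv)
    # a new run starts at a new line, a gap along the line, or a level change
    newrun <- c(TRUE, kv[-1] != kv[-n] | tv[-1] != tv[-n] + 1 | lv[-1] != lv[-n])
    runid <- cumsum(newrun)
    runlen <- tabulate(runid)
    runlev <- lv[newrun]
    m <- matrix(0, ng, maxlen)
    tab <- table(factor(runlev, levels = 1:ng), factor(runlen, levels = 1:maxlen))
    m <- m + unclass(tab)
    dimnames(m) <- NULL
    dirs[[k]] <- m
  }
  new_texture_matrix("GLRLM", ng = ng, directions = dirs, offsets = offs,
                     n_voxels = droi$n_voxels)
}

#' Gray level size zone matrix (GLSZM)
#'
#' `P(i, j)` counts the 26-connected zones of gray level `i` comprising
#' exactly `j` voxels. A single matrix is produced (the zone decomposition has
#' no directionality). `SizeZoneNonUniformityNormalized`, the zone-size
#' homogeneity measure used in the final radiomic signature, is
#' `sum_j (sum_i P(i,j))^2 / Nz^2`.
#'
#' @inheritParams glcm_matrix
#' @return A `texture_matrix` with `kind = "GLSZM"`, the count matrix in
#'   `$matrix`, `$n_zones` and `$n_voxels`.
#' @export
glszm_matrix <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- droi$levels
  ng <- droi$ng
  inroi <- which(!is.na(lev))
  vid <- match(seq_along(lev), inroi)   # voxel linear index -> vertex id
  offs <- direction_offsets_13()
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(lev, offs[k, ])
    same <- pr$a == pr$b
    if (any(same)) {
      edges[[length(edges) + 1]] <- cbind(vid[pr$ia[same]], vid[pr$ib[same]])
    }
  }
  nv <- length(inroi)
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_len(nv)
  }
  zone_size <- tabulate(comp)
  zone_level <- lev[inroi][match(seq_along(zone_size), comp)]
  maxsz <- max(zone_size)
  m <- unclass(table(factor(zone_level, levels = 1:ng),
                     factor(zone_size, levels = 1:maxsz)))
  dimnames(m) <- NULL
  new_texture_matrix("GLSZM", ng = ng, matrix = m,
                     n_zones = length(zone_size), n_voxels = droi$n_voxels)
}

#' Gray level dependence matrix (GLDM)
#'
#' For each ROI voxel, its dependence is the number of 26-neighbors within
#' Chebyshev distance `delta` (that are also in the ROI) whose gray level
#' differs by at most `alpha`. `D(i, d)` counts ROI voxels of level `i`
#' having dependence `d` (d = 0..26 for delta 1); feature formulas use the
#' conventional shifted index `j = d + 1`.
#'
#' @inheritParams glcm_matrix
#' @param alpha level-difference tolerance (default 0).
#' @param delta neighborhood Chebyshev distance (default 1; only 1 supported).
#' @return A `texture_matrix` with `kind = "GLDM"` and the count matrix in
#'   `$matrix` (rows = levels, columns = dependence 0..max).
#' @export
gldm_matrix <- function(droi, alpha = 0, delta = 1) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (alpha < 0) stopf("alpha must be >= 0")
  if (delta != 1) stopf("only delta = 1 neighborhoods are supported")
  lev <- droi$levels
  ng <- droi$ng
  dep <- array(0L, dim(lev))
  offs <- direction_offsets_13()
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(lev, offs[k, ])
    ok <- abs(pr$a - pr$b) <= alpha
    if (any(ok)) {
      inc <- tabulate(c(pr$ia[ok], pr$ib[ok]), nbins = length(lev))
      dep <- dep + array(inc, dim(lev))
    }
  }
  inroi <- !is.na(lev)
  m <- unclass(table(factor(lev[inroi], levels = 1:ng),
                     factor(dep[inroi], levels = 0:max(dep[inroi]))))
  dimnames(m) <- NULL
  new_texture_matrix("GLDM", ng = ng, matrix = m, n_voxels = droi$n_voxels)
}

#' Neighboring gray tone difference matrix (NGTDM)
#'
#' For each gray level `i`, `s_i` sums `|i - mean level of the valid
#' 26-neighbors|` over ROI voxels of level `i` that have at least one valid
#' neighbor, and `n_i` counts those voxels.
#'
#' @inheritParams gldm_matrix
#' @return A `texture_matrix` with `kind = "NGTDM"` and vectors `$n_i`,
#'   `$s_i`, `$levels` (1..Ng) plus `$n_valid` (total contributing voxels).
#' @export
ngtdm_vector <- function(droi, delta = 1) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (delta != 1) stopf("only delta = 1 neighborhoods are supported")
  lev <- droi$levels
  ng <- droi$ng
  nsum <- array(0, dim(lev))
  ncnt <- array(0L, dim(lev))
  offs <- direction_offsets_13()
  for (k in seq_len(nrow(offs))) {
    pr <- offset_pairs(lev, offs[k, ])
    if (length(pr$a)) {
      # accumulate neighbor level sums and counts in both pair orders
      nsum <- nsum + array(tapply_sum(pr$ia, pr$b, length(lev)) +
                             tapply_sum(pr$ib, pr$a, length(lev)), dim(lev))
      ncnt <- ncnt + array(tabulate(c(pr$ia, pr$ib), nbins = length(lev)),
                           dim(lev))
    }
  }
  inroi <- !is.na(lev)
  valid <- inroi & ncnt > 0L
  diffs <- abs(lev[valid] - nsum[valid] / ncnt[valid])
  lv <- lev[valid]
  s_i <- vapply(1:ng, function(i) sum(diffs[lv == i]), numeric(1))
  n_i <- vapply(1:ng, function(i) sum(lv == i), numeric(1))
  new_texture_matrix("NGTDM", ng = ng, n_i = n_i, s_i = s_i, levels = 1:ng,
                     n_valid = sum(n_i))
}

# Sum `values` into bins given by `index` over a vector of length n.
tapply_sum <- function(index, values, n) {
  out <- numeric(n)
  if (length(index)) {
    agg <- rowsum(as.numeric(values), group = index)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}
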