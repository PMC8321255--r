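# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a master seed and a stream index, staying within
# the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one per
# antipodal pair of the 26-neighborhood), first nonzero component positive.
direction_offsets_13 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  m <- as.matrix(offs[keep, ])
  dimnames(m) <- NULL
  m
}

# Extract the aligned voxel pairs (values and linear indices) for one offset
# applied to a 3D array; NA marks voxels outside the ROI.
offset_pairs <- function(lev, d) {
  dims <- dim(lev)
  idx1 <- vector("list", 3)
  for (k in 1:3) {
    s <- d[k]
    idx1[[k]] <- if (s >= 0) {
      seq_len(max(dims[k] - s, 0L))
    } else if (dims[k] + s < 1L) {
      integer(0)   # offset longer than the axis: no pairs
    } else {
      seq(1L - s, dims[k])
    }
  }
  if (any(lengths(idx1) == 0L)) {
    return(list(a = numeric(0), b = numeric(0), ia = integer(0), ib = integer(0)))
  }
  lin <- array(seq_along(lev), dims)
  ia <- lin[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
  ib <- lin[idx1[[1]] + d[1], idx1[[2]] + d[2], idx1[[3]] + d[3], drop = FALSE]
  a <- lev[ia]
  b <- lev[ib]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok], ia = ia[ok], ib = ib[ok])
}

# log2 with 0*log(0) treated as 0, plus the small-epsilon guard customary in
# texture-feature entropies.
xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}
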