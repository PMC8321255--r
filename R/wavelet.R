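# Single-level undecimated (stationary) separable 3D wavelet filter bank.
#
# Decomposition filters. Coiflet-1 is the default family; its analysis
# low-pass sums to sqrt(2) and the quadrature-mirror high-pass sums to 0,
# so any band with at least one H letter annihilates constant images.
wavelet_filter_bank <- function(family = "coif1") {
  lo <- switch(family,
    coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    stopf("unknown wavelet family: %s", family)
  )
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi, length = n)
}

# Circular (periodic) convolution of a 3D array along one axis with a short
# filter, implemented as a sum of wrapped axis rolls. Zero-phase alignment:
# tap j (1-based) reads the plane offset by j - 1 - floor((L-1)/2).
conv_axis_periodic <- function(a, h, axis) {
  dims <- dim(a)
  n <- dims[axis]
  L <- length(h)
  center <- floor((L - 1) / 2)
  out <- array(0, dims)
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (j in seq_len(L)) {
    off <- j - 1 - center
    src <- idx
    src[[axis]] <- ((idx[[axis]] - 1 + off) %% n) + 1
    out <- out + h[j] * a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  out
}

#' Compute the 8 stationary-wavelet sub-band images
#'
#' Applies a single-level undecimated separable 3D wavelet transform with
#' periodic boundary handling, producing one derived image per combination of
#' low-pass (L) / high-pass (H) filtering along each axis. Band labels follow
#' the x, y, z filter order: the first letter is the filter applied along the
#' x axis, so e.g. `HHL` is high-pass along x and y, low-pass along z.
#'
#' @param image an [image_volume()]; every dimension must be at least the
#'   filter length (6 for `coif1`).
#' @param family wavelet family: `"coif1"` (default), `"haar"` or `"db2"`.
#' @return A named list of 8 `image_volume` objects with names
#'   `LLL, HLL, LHL, HHL, LLH, HLH, LHH, HHH`.
#' @export
wavelet_bands <- function(image, family = "coif1") {
  stopifnot(inherits(image, "image_volume"))
  fb <- wavelet_filter_bank(family)
  if (any(dim(image$data) < fb$length)) {
    stopf("image dimensions %s are smaller than the %s filter length (%d)",
          paste(dim(image$data), collapse = "x"), family, fb$length)
  }
  # filter axes incrementally so each partial convolution is computed once
  x <- list(L = conv_axis_periodic(image$data, fb$lo, 1),
            H = conv_axis_periodic(image$data, fb$hi, 1))
  xy <- list()
  for (fx in c("L", "H")) for (fy in c("L", "H")) {
    xy[[paste0(fx, fy)]] <-
      conv_axis_periodic(x[[fx]], if (fy == "L") fb$lo else fb$hi, 2)
  }
  bands <- list()
  for (fx in c("L", "H")) for (fy in c("L", "H")) for (fz in c("L", "H")) {
    lab <- paste0(fx, fy, fz)
    dat <- conv_axis_periodic(xy[[paste0(fx, fy)]],
                              if (fz == "L") fb$lo else fb$hi, 3)
    bands[[lab]] <- image_volume(dat, image$spacing_mm, image$origin_mm)
  }
  bands[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}
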