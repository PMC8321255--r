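#' Histogram-match an image to a reference
#'
#' Monotone quantile mapping: each intensity is mapped through the input
#' image's empirical quantile function onto the reference image's, so the
#' output intensity distribution approximates the reference's while the
#' ordering of voxel intensities is preserved. This is the normalization
#' applied cohort-wide before feature extraction to remove scanner-session
#' intensity-scale differences.
#'
#' @param image an [image_volume()] to normalize.
#' @param reference an `image_volume` providing the target distribution; must
#'   contain at least 2 distinct values.
#' @param n_quantiles number of quantile knots for the piecewise-linear map.
#' @return An `image_volume` on the same grid as `image`.
#' @export
histogram_match <- function(image, reference, n_quantiles = 256) {
  stopifnot(inherits(image, "image_volume"), inherits(reference, "image_volume"))
  refv <- as.numeric(reference$data)
  if (length(unique(refv)) < 2L) stopf("constant reference image: cannot histogram-match")
  probs <- seq(0, 1, length.out = n_quantiles)
  qin <- quantile(as.numeric(image$data), probs, names = FALSE, type = 7)
  qref <- quantile(refv, probs, names = FALSE, type = 7)
  # collapse duplicated input knots (flat stretches of the input CDF)
  keep <- !duplicated(qin)
  qin_u <- qin[keep]
  qref_u <- vapply(split(qref, cumsum(keep)), mean, numeric(1))
  if (length(qin_u) == 1L) {
    out <- array(qref_u, dim(image$data))
  } else {
    out <- array(approx(qin_u, qref_u, xout = as.numeric(image$data),
                        rule = 2, ties = "ordered")$y,
                 dim(image$data))
  }
  image_volume(out, image$spacing_mm, image$origin_mm)
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates, clamped to the grid.
trilinear_at <- function(a, xi, yi, zi) {
  dims <- dim(a)
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  xi <- cl(xi, dims[1]); yi <- cl(yi, dims[2]); zi <- cl(zi, dims[3])
  x0 <- pmin(floor(xi), dims[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(yi), dims[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(zi), dims[3] - 2); z0 <- pmax(z0, 0)
  if (dims[1] == 1L) x0 <- rep(0, length(xi))
  if (dims[2] == 1L) y0 <- rep(0, length(yi))
  if (dims[3] == 1L) z0 <- rep(0, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  g <- function(ix, iy, iz) {
    a[cbind(pmin(ix, dims[1] - 1) + 1, pmin(iy, dims[2] - 1) + 1,
            pmin(iz, dims[3] - 1) + 1)]
  }
  c000 <- g(x0, y0, z0);       c100 <- g(x0 + 1, y0, z0)
  c010 <- g(x0, y0 + 1, z0);   c110 <- g(x0 + 1, y0 + 1, z0)
  c001 <- g(x0, y0, z0 + 1);   c101 <- g(x0 + 1, y0, z0 + 1)
  c011 <- g(x0, y0 + 1, z0 + 1); c111 <- g(x0 + 1, y0 + 1, z0 + 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a volume and its mask to a target voxel size
#'
#' The intensity image is resampled with trilinear interpolation and the mask
#' with nearest-neighbor interpolation (so it stays binary). The output grid
#' has `ceil(dim * spacing / target)` voxels per axis and shares the input's
#' world origin.
#'
#' @param image an [image_volume()].
#' @param mask the paired [roi_mask()].
#' @param target_spacing_mm positive numeric length-3, mm (default 3x3x3).
#' @return A list with elements `image` and `mask` on the new grid.
#' @export
resample_to_spacing <- function(image, mask, target_spacing_mm = c(3, 3, 3)) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (any(target_spacing_mm <= 0)) stopf("target spacing must be positive")
  ins <- image$spacing_mm
  dims <- dim(image$data)
  odims <- as.integer(ceiling(dims * ins / target_spacing_mm))
  # 0-based output index -> input voxel coordinate
  coord <- function(k) (seq_len(odims[k]) - 1) * target_spacing_mm[k] / ins[k]
  gx <- coord(1); gy <- coord(2); gz <- coord(3)
  grid <- expand.grid(x = gx, y = gy, z = gz)
  vals <- trilinear_at(image$data, grid$x, grid$y, grid$z)
  oimg <- image_volume(array(vals, odims), target_spacing_mm, image$origin_mm)
  nn <- function(v, n) pmin(pmax(round(v), 0), n - 1) + 1
  mvals <- mask$data[cbind(nn(grid$x, dims[1]), nn(grid$y, dims[2]),
                           nn(grid$z, dims[3]))]
  if (sum(mvals) < 1) {
    stopf("resampling to %s mm empties the ROI (tumor smaller than one target voxel)",
          paste(target_spacing_mm, collapse = "x"))
  }
  omask <- roi_mask(array(mvals, odims), target_spacing_mm, image$origin_mm)
  list(image = oimg, mask = omask)
}

#' Discretize ROI intensities into fixed-width gray-level bins
#'
#' Gray level of a voxel with intensity x is
#' `floor((x - min_ROI) / bin_width) + 1`, anchoring the first bin at the ROI
#' minimum, so the number of levels `Ng = floor((max - min)/bin_width) + 1`
#' is independent of intensities outside the ROI. Wavelet-derived images are
#' discretized independently with the same bin width because each derived
#' image has its own intensity scale.
#'
#' @param image an [image_volume()] (original or wavelet-derived).
#' @param mask the [roi_mask()] restricting the computation.
#' @param bin_width positive bin width in intensity units (default 25).
#' @return An object of class `discretized_roi` with fields `levels` (3D
#'   integer array cropped to the ROI bounding box, `NA` outside the ROI),
#'   `ng`, `bin_width`, `bin_anchor` (ROI minimum), `values` (raw ROI
#'   intensities), `n_voxels` and `spacing_mm`.
#' @export
discretize_roi <- function(image, mask, bin_width = 25) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (!identical(dim(image$data), dim(mask$data))) {
    stopf("geometry mismatch between image and mask")
  }
  inroi <- mask$data == 1L
  vals <- image$data[inroi]
  mn <- min(vals)
  levfull <- array(NA_integer_, dim(image$data))
  levfull[inroi] <- as.integer(floor((image$data[inroi] - mn) / bin_width)) + 1L
  ng <- max(levfull, na.rm = TRUE)
  # crop to ROI bounding box to keep texture scans cheap
  idx <- which(inroi, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  lev <- levfull[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
                 drop = FALSE]
  structure(
    list(levels = lev, ng = as.integer(ng), bin_width = bin_width,
         bin_anchor = mn, values = vals, n_voxels = length(vals),
         spacing_mm = image$spacing_mm),
    class = "discretized_roi"
  )
}
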