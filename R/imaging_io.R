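#' Construct an image volume
#'
#' The basic unit all filters and feature extractors operate on: a 3D scalar
#' grid with per-axis voxel spacing (mm) and a world-space origin. Voxel
#' indices are 0-based in the world mapping `world = origin + index * spacing`;
#' the first array dimension is the x axis (fastest-varying on disk).
#'
#' @param data numeric 3D array of intensities (arbitrary MR units).
#' @param spacing_mm positive numeric length-3 voxel size in mm.
#' @param origin_mm numeric length-3 world coordinate of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("image data must be a 3D array")
  }
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be 3 positive finite values")
  }
  if (any(!is.finite(data))) stopf("image contains non-finite values")
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "image_volume"
  )
}

#' Construct a binary region-of-interest mask
#'
#' @param data 3D array coercible to binary (values are binarized at > 0.5).
#' @param spacing_mm,origin_mm geometry, as for [image_volume()].
#' @return An object of class `roi_mask` whose data is an integer 0/1 array.
#' @export
roi_mask <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("mask data must be a 3D array")
  }
  bin <- array(as.integer(data > 0.5), dim(data))
  if (sum(bin) < 1L) stopf("empty ROI: mask has no foreground voxels")
  vol <- image_volume(bin, spacing_mm, origin_mm)
  structure(
    list(data = bin, spacing_mm = vol$spacing_mm, origin_mm = vol$origin_mm),
    class = "roi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d in ROI\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

nifti_geometry <- function(img, path) {
  pd <- RNifti::pixdim(img)
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (attr(x, "code") != 0 && any(abs(offdiag) > 1e-6 * max(abs(diag(rot)), 1))) {
    stopf("%s: only axis-aligned orientation matrices are supported", path)
  }
  list(spacing = abs(as.numeric(pd[1:3])), origin = as.numeric(x[1:3, 4]))
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image into an [image_volume()]. Orientation matrices
#' that are not axis-aligned are rejected rather than silently reinterpreted.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return An `image_volume`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) stopf("%s: expected a 3D image", path)
  geo <- nifti_geometry(img, path)
  attributes(a) <- list(dim = dim(a))
  image_volume(a, geo$spacing, geo$origin)
}

#' Read a NIfTI segmentation mask paired with a volume
#'
#' The mask is binarized at 0.5 and checked against its paired volume:
#' grid shape must match exactly and voxel spacing to within 1e-3 mm.
#'
#' @param path path to the mask NIfTI file.
#' @param paired the [image_volume()] the mask belongs to.
#' @return An `roi_mask`.
#' @export
load_mask <- function(path, paired) {
  stopifnot(inherits(paired, "image_volume"))
  vol <- load_volume(path)
  if (!identical(dim(vol$data), dim(paired$data))) {
    stopf("geometry mismatch: mask grid %s vs volume grid %s",
          paste(dim(vol$data), collapse = "x"),
          paste(dim(paired$data), collapse = "x"))
  }
  if (any(abs(vol$spacing_mm - paired$spacing_mm) > 1e-3)) {
    stopf("geometry mismatch: mask spacing differs from volume spacing by > 1e-3 mm")
  }
  roi_mask(vol$data, paired$spacing_mm, paired$origin_mm)
}

#' Write a volume or mask to NIfTI
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing_mm
  m <- diag(c(x$spacing_mm, 1))
  m[1:3, 4] <- x$origin_mm
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  dt <- if (inherits(x, "roi_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write / read a patient-by-feature table
#'
#' A feature table is a data frame with a character `id` column, one numeric
#' column per feature (and possibly clinical covariates), and an integer 0/1
#' `label` outcome column. CSV round-trips preserve column order and numeric
#' values to better than 12 significant digits.
#'
#' @param table a feature table data frame.
#' @param path CSV path.
#' @return `read_feature_table()` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  write.csv(format(table, digits = 17, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_feature_table(tab)
  tab
}

validate_feature_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) stopf("empty feature table")
  if (!"id" %in% names(table)) stopf("feature table must have an 'id' column")
  if (anyDuplicated(table$id)) stopf("duplicate patient ids in feature table")
  if (anyDuplicated(names(table))) stopf("duplicate feature names in feature table")
  invisible(table)
}
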