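#' Extraction configuration
#'
#' Bundles the preprocessing and filter parameters used by [extract_all()].
#' Defaults reproduce the extraction convention the feature catalog was built
#' for: resampling to an isotropic 3 mm grid, fixed bin width 25 anchored at
#' the ROI minimum, and a single-level stationary Coiflet-1 wavelet bank.
#'
#' @param bin_width gray-level bin width in intensity units.
#' @param target_spacing_mm isotropic resampling target (mm); set to `NULL`
#'   to extract on the native grid.
#' @param normalize `"none"` or `"histogram_match"`.
#' @param reference optional [image_volume()] used as the histogram-matching
#'   reference (required when `normalize = "histogram_match"`).
#' @param n_quantiles quantile knots for histogram matching.
#' @param wavelet_family wavelet family name (see [wavelet_bands()]).
#' @param gldm_alpha,gldm_delta,ngtdm_delta texture-matrix parameters.
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(bin_width = 25, target_spacing_mm = c(3, 3, 3),
                           normalize = c("none", "histogram_match"),
                           reference = NULL, n_quantiles = 256,
                           wavelet_family = "coif1",
                           gldm_alpha = 0, gldm_delta = 1, ngtdm_delta = 1) {
  normalize <- match.arg(normalize)
  if (normalize == "histogram_match" && is.null(reference)) {
    stopf("histogram_match normalization requires a reference volume")
  }
  structure(list(bin_width = bin_width, target_spacing_mm = target_spacing_mm,
                 normalize = normalize, reference = reference,
                 n_quantiles = n_quantiles, wavelet_family = wavelet_family,
                 gldm_alpha = gldm_alpha, gldm_delta = gldm_delta,
                 ngtdm_delta = ngtdm_delta),
            class = "extract_config")
}

nonshape_features <- function(droi, config) {
  blocks <- list(
    firstorder = first_order_features(droi),
    glcm = glcm_features(glcm_matrix(droi)),
    gldm = gldm_features(gldm_matrix(droi, config$gldm_alpha, config$gldm_delta)),
    glrlm = glrlm_features(glrlm_matrix(droi)),
    glszm = glszm_features(glszm_matrix(droi)),
    ngtdm = ngtdm_features(ngtdm_vector(droi, config$ngtdm_delta))
  )
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- unlist(lapply(names(blocks), function(cl) {
    paste0(cl, "_", names(blocks[[cl]]))
  }))
  out
}

#' Extract the full 841-feature radiomic vector for one patient
#'
#' Runs the whole single-patient pipeline: optional histogram-matching
#' normalization, resampling to the target grid, shape features on the
#' original mask, first-order + texture features on the original image, and
#' the same 92 non-shape features on each of the 8 stationary-wavelet
#' sub-band images (each sub-band discretized independently with the same bin
#' width). The result is ordered exactly as [feature_catalog()].
#'
#' @param image an [image_volume()].
#' @param mask the paired [roi_mask()].
#' @param config an [extract_config()].
#' @param id optional patient id used in error messages.
#' @return Named numeric vector of 841 finite values.
#' @export
extract_all <- function(image, mask, config = extract_config(), id = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  tag <- if (is.null(id)) "" else sprintf(" [patient %s]", id)
  res <- tryCatch({
    if (config$normalize == "histogram_match") {
      image <- histogram_match(image, config$reference, config$n_quantiles)
    }
    ts <- config$target_spacing_mm
    if (!is.null(ts) && any(abs(image$spacing_mm - ts) > 1e-9)) {
      rs <- resample_to_spacing(image, mask, ts)
      image <- rs$image
      mask <- rs$mask
    }
    sh <- shape_features(mask)
    names(sh) <- paste0("shape_", names(sh))
    droi <- discretize_roi(image, mask, config$bin_width)
    vals <- c(sh, nonshape_features(droi, config))
    names(vals) <- paste0("original_", names(vals))
    bands <- wavelet_bands(image, config$wavelet_family)
    for (lab in names(bands)) {
      droi_b <- discretize_roi(bands[[lab]], mask, config$bin_width)
      fb <- nonshape_features(droi_b, config)
      names(fb) <- paste0("wavelet_", lab, "_", names(fb))
      vals <- c(vals, fb)
    }
    vals
  }, error = function(e) {
    stopf("feature extraction failed%s: %s", tag, conditionMessage(e))
  })
  catalog <- feature_catalog()
  res <- res[catalog$name]   # enforce catalog order; errors if any name missing
  names(res) <- catalog$name
  if (any(!is.finite(res))) {
    bad <- names(res)[!is.finite(res)]
    stopf("non-finite feature values%s: %s", tag,
          paste(head(bad, 5), collapse = ", "))
  }
  res
}

#' Extract features for a whole cohort
#'
#' @param cohort a cohort object from [generate_cohort()] or a data frame
#'   with `id`, `volume_path`, `mask_path` and `label` columns.
#' @param config an [extract_config()]. When `normalize =
#'   "histogram_match"` and no reference is supplied, the first patient's
#'   volume is used as the cohort reference (and this is reported).
#' @param verbose print one progress line per patient.
#' @return A feature table data frame: `id`, the 841 features, `label`.
#' @export
extract_cohort <- function(cohort, config = extract_config(), verbose = FALSE) {
  records <- if (is.data.frame(cohort)) cohort else cohort$records
  stopifnot(all(c("id", "volume_path", "mask_path", "label") %in% names(records)))
  if (config$normalize == "histogram_match" && is.null(config$reference)) {
    config$reference <- load_volume(records$volume_path[1])
    message(sprintf("histogram-matching reference: first cohort image (%s)",
                    records$id[1]))
  }
  rows <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    t0 <- Sys.time()
    vol <- load_volume(records$volume_path[r])
    msk <- load_mask(records$mask_path[r], vol)
    rows[[r]] <- extract_all(vol, msk, config, id = records$id[r])
    if (verbose) {
      message(sprintf("[extract] patient=%s elapsed=%.2fs", records$id[r],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(id = records$id, tab, label = records$label,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  validate_feature_table(tab)
}
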