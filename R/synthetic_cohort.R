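#' Specification of a synthetic study cohort
#'
#' Describes a fully synthetic population emulating a 35-patient pre-RT MRI
#' glioblastoma cohort with an 8:27 pseudoprogression:non-pseudoprogression
#' split. Each patient gets an ellipsoidal tumor whose interior intensity is
#' a smoothed Gaussian random field with two plantable class effects:
#'
#' * `effect_floor` shifts the positive class's interior intensity level (and
#'   with it the intensity floor enforced by a lower clamp), making a
#'   minimum-intensity feature discriminative;
#' * `effect_zone` multiplies the positive class's smoothing correlation
#'   length, producing larger homogeneous gray-level zones and hence lower
#'   zone-size non-uniformity.
#'
#' `effect_floor = 0` and `effect_zone = 1` define the null cohort. The
#' default effect sizes place the planted classes three noise standard
#' deviations apart in intensity floor, the strongly-separable regime.
#'
#' @param n_patients cohort size (default 35).
#' @param n_positive number of pseudoprogression cases (default 8).
#' @param grid_shape voxels per axis (default 64^3).
#' @param spacing_mm voxel size in mm (default 1 mm isotropic).
#' @param tumor_radius_mm mean ellipsoid semi-axis length (default 14 mm).
#' @param effect_floor intensity-floor shift between classes, in the
#'   arbitrary MR intensity units of the generator (default `3 * noise_sd`).
#' @param effect_zone texture correlation-length multiplier for positives
#'   (default 2).
#' @param noise_sd voxelwise noise scale inside the tumor (default 30).
#' @param patient_sd between-patient intensity-scale variability: each
#'   patient's whole volume is offset by `N(0, patient_sd)` (default 45),
#'   emulating biological and scanner-session level differences so that no
#'   single planted feature separates the classes perfectly.
#' @param zone_jitter between-patient log-scale jitter of the texture
#'   correlation length (default `log(2)/2`), the zone-axis analogue of
#'   `patient_sd`. With the default `effect_zone = 2` both planted axes sit
#'   two between-patient standard deviations apart.
#' @param seed integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 35, n_positive = 8,
                        grid_shape = c(64, 64, 64), spacing_mm = c(1, 1, 1),
                        tumor_radius_mm = 14, effect_floor = 3 * noise_sd,
                        effect_zone = 2, noise_sd = 30, patient_sd = 45,
                        zone_jitter = log(2) / 2, seed = 1) {
  if (n_positive >= n_patients) stopf("n_positive must be < n_patients")
  if (any(spacing_mm <= 0)) stopf("all spacings must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 n_positive = as.integer(n_positive),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tumor_radius_mm = tumor_radius_mm,
                 effect_floor = effect_floor, effect_zone = effect_zone,
                 noise_sd = noise_sd, patient_sd = patient_sd,
                 zone_jitter = zone_jitter, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Separable Gaussian smoothing (periodic boundaries), kernel truncated at 3 sigma.
gaussian_smooth3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis_periodic(a, k, ax)
  }
  a
}

# Table 1 marginal frequencies used to sample clinical covariates.
clinical_marginals <- function() {
  list(
    gender = c(Male = 24, Female = 11),
    location = c("Right frontal lobe" = 8, "Right temporal lobe" = 6,
                 "Right parietal lobe" = 4, "Left temporal lobe" = 3,
                 "Left parietal lobe" = 5, "Other location" = 3, Unknown = 6),
    resection_extent = c(GTR = 12, NTR = 3, STR = 11, Biopsy = 7, None = 1,
                         Unknown = 1),
    # per-class resection counts, used only when a clinical effect is planted
    resection_by_class = list(
      pos = c(GTR = 1, NTR = 1, STR = 2, Biopsy = 4, None = 0, Unknown = 0),
      neg = c(GTR = 11, NTR = 2, STR = 9, Biopsy = 3, None = 1, Unknown = 1)
    ),
    age_range = c(8, 87)
  )
}

generate_patient_volume <- function(spec, positive, seed) {
  with_seed(seed, {
    dims <- spec$grid_shape
    sp <- spec$spacing_mm
    base_bg <- 60; sd_bg <- 15
    base_tumor <- 300
    # the floor effect is a global intensity offset (positives sit on a
    # shifted intensity scale), so it survives partial-volume mixing at the
    # tumor boundary when the grid is resampled; a per-patient random offset
    # adds realistic between-subject intensity-scale variability
    shift <- (if (positive) spec$effect_floor else 0) +
      rnorm(1, 0, spec$patient_sd)
    vol <- array(rnorm(prod(dims), base_bg + shift, sd_bg), dims)
    # ellipsoid semi-axes jittered per axis, center jittered around the middle
    semi <- spec$tumor_radius_mm * runif(3, 0.8, 1.2)
    cen <- (dims - 1) / 2 * sp + runif(3, -2, 2)
    ax <- (seq_len(dims[1]) - 1) * sp[1]
    ay <- (seq_len(dims[2]) - 1) * sp[2]
    az <- (seq_len(dims[3]) - 1) * sp[3]
    d2 <- outer(outer(((ax - cen[1]) / semi[1])^2, ((ay - cen[2]) / semi[2])^2,
                      "+"), ((az - cen[3]) / semi[3])^2, "+")
    inside <- d2 <= 1
    # interior: smoothed Gaussian random field, class-dependent correlation
    # length with per-patient log-normal jitter, rescaled to noise_sd, on a
    # class-shifted base level
    sigma_mm <- 2 * (if (positive) spec$effect_zone else 1) *
      exp(rnorm(1, 0, spec$zone_jitter))
    field <- gaussian_smooth3d(array(rnorm(prod(dims)), dims), sigma_mm / sp)
    field <- field / sd(field) * spec$noise_sd
    interior <- base_tumor + shift + field
    # lower clamp 2 noise-sd below the class base: pins the intensity floor
    interior <- pmax(interior, base_tumor + shift - 2 * spec$noise_sd)
    vol[inside] <- interior[inside]
    list(volume = image_volume(vol, sp), mask = roi_mask(inside * 1, sp),
         latent_shift = shift, latent_sigma = sigma_mm)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes one NIfTI volume and mask per patient plus a clinical covariate
#' CSV (`id,age,gender,location,resection_extent,label`) and a JSON manifest.
#' Exactly `n_positive` patients get label 1. Clinical covariates are sampled
#' independently of the outcome from the study-population marginal
#' frequencies unless `plant_clinical_effect = TRUE`, in which case the
#' extent of resection is drawn from class-specific frequencies.
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @param plant_clinical_effect plant a resection-extent association with the
#'   outcome (default `FALSE`: the clinical covariates carry no signal).
#' @return A list of class `cohort` with `records` (data frame), `spec`, and
#'   the paths of the clinical table and manifest.
#' @export
generate_cohort <- function(spec, out_dir, plant_clinical_effect = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  n <- spec$n_patients
  marg <- clinical_marginals()
  rec <- with_seed(child_seed(spec$seed, 0), {
    label <- integer(n)
    label[sample.int(n, spec$n_positive)] <- 1L
    draw <- function(freq, m) sample(names(freq), m, replace = TRUE,
                                     prob = freq / sum(freq))
    resection <- if (plant_clinical_effect) {
      out <- character(n)
      out[label == 1] <- draw(marg$resection_by_class$pos, sum(label == 1))
      out[label == 0] <- draw(marg$resection_by_class$neg, sum(label == 0))
      out
    } else draw(marg$resection_extent, n)
    data.frame(
      id = sprintf("pt%02d", seq_len(n)),
      label = label,
      age = round(runif(n, marg$age_range[1], marg$age_range[2]), 1),
      gender = draw(marg$gender, n),
      location = draw(marg$location, n),
      resection_extent = resection,
      stringsAsFactors = FALSE
    )
  })
  rec$volume_path <- file.path(out_dir, paste0(rec$id, "_vol.nii.gz"))
  rec$mask_path <- file.path(out_dir, paste0(rec$id, "_mask.nii.gz"))
  rec$latent_shift <- NA_real_
  rec$latent_sigma <- NA_real_
  for (r in seq_len(n)) {
    pv <- generate_patient_volume(spec, rec$label[r] == 1L,
                                  child_seed(spec$seed, r))
    write_volume(pv$volume, rec$volume_path[r])
    write_volume(pv$mask, rec$mask_path[r])
    # ground-truth latent effect parameters, kept for plantedness checks
    rec$latent_shift[r] <- pv$latent_shift
    rec$latent_sigma[r] <- pv$latent_sigma
  }
  clinical_path <- file.path(out_dir, "clinical.csv")
  write.csv(rec[, c("id", "age", "gender", "location", "resection_extent",
                    "label")], clinical_path, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(spec = unclass(spec), n_patients = n, n_positive = spec$n_positive,
         patients = rec[, c("id", "label", "volume_path", "mask_path")]),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  structure(list(records = rec, spec = spec, clinical_path = clinical_path,
                 manifest_path = manifest_path, dir = out_dir),
            class = "cohort")
}

#' Tiny hand-checkable phantom volumes
#'
#' Fixtures whose texture matrices can be enumerated by hand:
#' `constant` (8x8x8, all voxels 100), `two_level_rod` (1x1x4 with
#' intensities giving gray levels 1,1,1,2 at bin width 25), `checker`
#' (4x4x4 two-level parity lattice) and `digital_ball` (radius 5 voxels).
#' All phantoms use 3 mm isotropic spacing so that the default extraction
#' grid matches the native grid.
#'
#' @param kind one of `"constant"`, `"two_level_rod"`, `"checker"`,
#'   `"digital_ball"`.
#' @param value intensity of the constant phantom (default 100).
#' @return A list with `image` ([image_volume()]) and `mask` ([roi_mask()]).
#' @export
generate_phantom <- function(kind = c("constant", "two_level_rod", "checker",
                                      "digital_ball"), value = 100) {
  kind <- match.arg(kind)
  sp <- c(3, 3, 3)
  if (kind == "constant") {
    # 8^3 so the full extraction pipeline (wavelet filter length 6) runs on it
    a <- array(value, c(8, 8, 8))
    return(list(image = image_volume(a, sp), mask = roi_mask(array(1, c(8, 8, 8)), sp)))
  }
  if (kind == "two_level_rod") {
    a <- array(c(0, 0, 0, 25), c(1, 1, 4))   # bin width 25 -> levels 1,1,1,2
    return(list(image = image_volume(a, sp), mask = roi_mask(array(1, c(1, 1, 4)), sp)))
  }
  if (kind == "checker") {
    idx <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
    a <- array(25 * ((idx$x + idx$y + idx$z) %% 2), c(4, 4, 4))
    return(list(image = image_volume(a, sp), mask = roi_mask(array(1, c(4, 4, 4)), sp)))
  }
  # digital ball of radius 5 voxels in a 13^3 grid
  r <- 5
  n <- 2 * r + 3
  cen <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array(as.numeric((g$x - cen)^2 + (g$y - cen)^2 + (g$z - cen)^2 <= r^2),
                c(n, n, n))
  list(image = image_volume(array(value, c(n, n, n)), sp),
       mask = roi_mask(ball, sp))
}

#' Assess whether a selected signature is built on the planted effects
#'
#' The generator plants exactly two latent effect axes per cohort: the
#' intensity-floor shift (`latent_shift`) and the texture correlation length
#' (`latent_sigma`). A selected feature is a *planted readout* if its
#' absolute Spearman correlation with one of the latent axes reaches the
#' given threshold. Recovery holds when every selected feature clears the
#' `weak` threshold (no noise feature selected) and at least one clears the
#' `strong` threshold.
#'
#' @param selected character vector of selected feature names.
#' @param table the extracted feature table.
#' @param records the cohort's `records` data frame (with `latent_shift`,
#'   `latent_sigma`).
#' @param strong,weak Spearman correlation thresholds (defaults 0.7 / 0.5).
#' @return A list with `recovered` (logical) and the per-feature maximal
#'   latent correlations `rho`.
#' @export
assess_planted_recovery <- function(selected, table, records,
                                    strong = 0.7, weak = 0.5) {
  stopifnot(all(c("latent_shift", "latent_sigma") %in% names(records)),
            length(selected) >= 1L)
  axes <- cbind(floor = records$latent_shift,
                zone = log(records$latent_sigma))
  rho <- vapply(selected, function(f) {
    max(abs(cor(axes, table[[f]], method = "spearman")))
  }, numeric(1))
  list(recovered = all(rho >= weak) && any(rho >= strong), rho = rho)
}
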