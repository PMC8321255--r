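test_that("label counts are conserved for any seed", {
  for (seed in c(1, 17, 404)) {
    dir <- file.path(tempdir(), paste0("coh-lab-", seed))
    co <- generate_cohort(cohort_spec(n_patients = 10, n_positive = 3,
                                      grid_shape = c(16, 16, 16),
                                      tumor_radius_mm = 5, seed = seed), dir)
    expect_equal(sum(co$records$label), 3)
    expect_equal(nrow(co$records), 10)
    unlink(dir, recursive = TRUE)
  }
})

test_that("generation is byte-deterministic given the seed", {
  spec <- cohort_spec(n_patients = 3, n_positive = 1,
                      grid_shape = c(16, 16, 16), tumor_radius_mm = 5,
                      seed = 33)
  d1 <- file.path(tempdir(), "coh-det-1")
  d2 <- file.path(tempdir(), "coh-det-2")
  co1 <- generate_cohort(spec, d1)
  co2 <- generate_cohort(spec, d2)
  for (r in seq_len(3)) {
    expect_identical(unname(tools::md5sum(co1$records$volume_path[r])),
                     unname(tools::md5sum(co2$records$volume_path[r])))
    expect_identical(unname(tools::md5sum(co1$records$mask_path[r])),
                     unname(tools::md5sum(co2$records$mask_path[r])))
  }
  expect_identical(readLines(co1$clinical_path), readLines(co2$clinical_path))

  co3 <- generate_cohort(cohort_spec(n_patients = 3, n_positive = 1,
                                     grid_shape = c(16, 16, 16),
                                     tumor_radius_mm = 5, seed = 34),
                         file.path(tempdir(), "coh-det-3"))
  v1 <- load_volume(co1$records$volume_path[1])
  v3 <- load_volume(co3$records$volume_path[1])
  expect_false(identical(v1$data, v3$data))
  for (d in c(d1, d2, file.path(tempdir(), "coh-det-3"))) {
    unlink(d, recursive = TRUE)
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_patients = 8, n_positive = 8), "n_positive")
  expect_error(cohort_spec(spacing_mm = c(1, 0, 1)), "positive")
})

test_that("phantoms have their stated hand-checkable structure", {
  const <- generate_phantom("constant")
  expect_equal(length(unique(const$image$data[const$mask$data == 1])), 1L)

  rod <- generate_phantom("two_level_rod")
  d <- discretize_roi(rod$image, rod$mask, 25)
  expect_equal(d$ng, 2L)
  expect_equal(as.vector(d$levels), c(1L, 1L, 1L, 2L))
  expect_equal(glszm_matrix(d)$n_zones, 2L)

  ball <- generate_phantom("digital_ball")
  sf <- shape_features(ball$mask)
  expect_equal(sf[["Elongation"]], 1, tolerance = 1e-6)
  expect_equal(sf[["Flatness"]], 1, tolerance = 1e-6)

  expect_error(generate_phantom("nope"))
})

test_that("increasing the floor effect monotonically separates the minimum feature", {
  # Monte-Carlo over small volumes: group-standardized difference of the ROI
  # minimum must grow with effect_floor
  sds <- vapply(c(0, 45, 90), function(ef) {
    spec <- cohort_spec(n_patients = 40, n_positive = 20,
                        grid_shape = c(24, 24, 24), tumor_radius_mm = 8,
                        effect_floor = ef, seed = 555)
    mins <- function(positive, offset) {
      vapply(1:20, function(i) {
        pv <- radpseudo:::generate_patient_volume(
          spec, positive, radpseudo:::child_seed(spec$seed, offset + i))
        min(pv$volume$data[pv$mask$data == 1])
      }, numeric(1))
    }
    m1 <- mins(TRUE, 0); m0 <- mins(FALSE, 100)
    abs(mean(m1) - mean(m0)) / sqrt((var(m1) + var(m0)) / 2)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})
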