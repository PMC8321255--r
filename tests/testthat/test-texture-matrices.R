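# Worked micro-examples with hand-derived values, then exhaustive agreement
# with the brute-force oracles on random small ROIs.

test_that("GLCM micro-examples match hand enumeration", {
  # 1x1x4 rod with levels 1,2,1,2: only the z-direction has pairs
  d <- droi_from_levels(array(c(1L, 2L, 1L, 2L), c(1, 1, 4)))
  tm <- glcm_matrix(d)
  nz <- which(vapply(tm$directions, sum, numeric(1)) > 0)
  expect_length(nz, 1L)
  p <- tm$directions[[nz]] / sum(tm$directions[[nz]])
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- radpseudo:::glcm_features_one(tm$directions[[nz]])
  expect_equal(f[["JointEnergy"]], 0.5)
  expect_equal(f[["Contrast"]], 1.0)

  # constant ROI: single cell, Contrast 0, JointEnergy 1
  dc <- droi_from_levels(array(1L, c(2, 2, 2)))
  fc <- glcm_features(glcm_matrix(dc))
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["JointEnergy"]], 1)
  expect_length(fc, 23L)
})

test_that("GLSZM micro-examples match hand enumeration", {
  # 2x2x1 constant: one zone of size 4
  d1 <- droi_from_levels(array(1L, c(2, 2, 1)))
  f1 <- glszm_features(glszm_matrix(d1))
  expect_equal(f1[["SizeZoneNonUniformityNormalized"]], 1.0)
  # 1,1,1,2 rod: zones {3, 1} -> SZNN = (1 + 1)/4
  d2 <- droi_from_levels(array(c(1L, 1L, 1L, 2L), c(1, 1, 4)))
  f2 <- glszm_features(glszm_matrix(d2))
  expect_equal(f2[["SizeZoneNonUniformityNormalized"]], 0.5)
  expect_length(f2, 16L)
})

test_that("GLRLM micro-examples match hand enumeration", {
  d <- droi_from_levels(array(c(1L, 1L, 1L, 2L), c(1, 1, 4)))
  tm <- glrlm_matrix(d)
  # the z-direction has runs (1, len 3) and (2, len 1)
  nz <- which(vapply(tm$directions, sum, numeric(1)) == 2)
  f <- radpseudo:::glrlm_features_one(tm$directions[[nz[1]]], d$n_voxels)
  expect_equal(f[["ShortRunEmphasis"]], (1 / 9 + 1) / 2, tolerance = 1e-12)

  dc <- droi_from_levels(array(1L, c(1, 1, 4)))
  tmc <- glrlm_matrix(dc)
  nzc <- which(vapply(tmc$directions, function(m) sum(m) == 1 && m[1, 4] == 1,
                      logical(1)))
  fc <- radpseudo:::glrlm_features_one(tmc$directions[[nzc[1]]], 4)
  expect_equal(fc[["RunPercentage"]], 0.25)
  expect_length(glrlm_features(tm), 16L)
})

test_that("GLDM micro-examples match hand enumeration", {
  # constant 2x2x2, alpha 0: every voxel has 7 equal neighbors
  d <- droi_from_levels(array(1L, c(2, 2, 2)))
  tm <- gldm_matrix(d)
  expect_equal(dim(tm$matrix), c(1L, 8L))
  expect_equal(tm$matrix[1, 8], 8)       # D(1, dep = 7) = 8
  f <- gldm_features(tm)
  expect_equal(f[["DependenceNonUniformityNormalized"]], 1.0)
  expect_length(f, 14L)

  single <- droi_from_levels(array(1L, c(1, 1, 1)))
  tms <- gldm_matrix(single)
  expect_equal(tms$matrix[1, 1], 1)      # D(1, dep = 0) = 1
})

test_that("NGTDM micro-examples match hand enumeration", {
  dc <- droi_from_levels(array(1L, c(2, 2, 2)))
  fc <- ngtdm_features(ngtdm_vector(dc))
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["Complexity"]], 0)
  expect_length(fc, 5L)

  # 1x1x3 rod [1,2,1]: s_1 = 2, s_2 = 1, n = (2, 1)
  d <- droi_from_levels(array(c(1L, 2L, 1L), c(1, 1, 3)))
  tm <- ngtdm_vector(d)
  expect_equal(tm$n_i, c(2, 1))
  expect_equal(tm$s_i, c(2, 1))
})

test_that("texture matrices agree cell-for-cell with brute-force enumeration", {
  set.seed(99)
  offs <- radpseudo:::direction_offsets_13()
  for (trial in 1:20) {
    dims <- sample(2:6, 3, replace = TRUE)
    ng_req <- sample(2:4, 1)
    lev0 <- random_levels(dims, ng_req)
    d <- droi_from_levels(lev0)
    lev <- d$levels
    ng <- d$ng

    glcm <- glcm_matrix(d)
    glrlm <- glrlm_matrix(d)
    for (k in seq_len(nrow(offs))) {
      expect_equal(glcm$directions[[k]], oracle_glcm(lev, offs[k, ], ng))
      expect_equal(glrlm$directions[[k]],
                   oracle_glrlm(lev, offs[k, ], ng)[, seq_len(ncol(glrlm$directions[[k]])), drop = FALSE])
    }
    szm <- glszm_matrix(d)
    orc <- oracle_glszm(lev, ng)
    expect_equal(szm$matrix[, seq_len(ncol(orc)), drop = FALSE], orc)
    expect_true(ncol(szm$matrix) == ncol(orc) ||
                  all(szm$matrix[, -seq_len(ncol(orc))] == 0))

    gld <- gldm_matrix(d)
    orcd <- oracle_gldm(lev, ng)
    expect_equal(gld$matrix, orcd)

    ngt <- ngtdm_vector(d)
    orcn <- oracle_ngtdm(lev, ng)
    expect_equal(ngt$n_i, orcn$n_i)
    expect_equal(ngt$s_i, orcn$s_i, tolerance = 1e-12)
  }
})

test_that("normalized matrices sum to one and NonUniformityNormalized stays in (0, 1]", {
  set.seed(5)
  for (trial in 1:10) {
    d <- droi_from_levels(random_levels(c(4, 4, 4), 3))
    for (tm in list(glszm_matrix(d), gldm_matrix(d))) {
      expect_equal(sum(tm$matrix / sum(tm$matrix)), 1, tolerance = 1e-12)
    }
    fs <- glszm_features(glszm_matrix(d))
    fr <- glrlm_features(glrlm_matrix(d))
    fd <- gldm_features(gldm_matrix(d))
    vals <- c(fs[["SizeZoneNonUniformityNormalized"]],
              fs[["GrayLevelNonUniformityNormalized"]],
              fr[["RunLengthNonUniformityNormalized"]],
              fr[["GrayLevelNonUniformityNormalized"]],
              fd[["DependenceNonUniformityNormalized"]])
    expect_true(all(vals > 0 & vals <= 1))
  }
})

test_that("direction-averaged features are invariant to axis flips and permutations", {
  set.seed(6)
  lev <- random_levels(c(4, 5, 3), 3, p_hole = 0.15)
  d <- droi_from_levels(lev)
  base_glcm <- glcm_features(glcm_matrix(d))
  base_glrlm <- glrlm_features(glrlm_matrix(d))
  transforms <- list(
    function(a) aperm(a, c(2, 1, 3)),
    function(a) aperm(a, c(3, 2, 1)),
    function(a) a[dim(a)[1]:1, , , drop = FALSE],
    function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(1, 3, 2))
  )
  for (tf in transforms) {
    dt <- droi_from_levels(tf(lev))
    expect_equal(glcm_features(glcm_matrix(dt)), base_glcm, tolerance = 1e-12)
    expect_equal(glrlm_features(glrlm_matrix(dt)), base_glrlm, tolerance = 1e-12)
  }
})

test_that("discretized-domain features ignore constant intensity shifts", {
  set.seed(8)
  vals <- array(rnorm(5^3, 0, 40), c(5, 5, 5))
  msk <- roi_mask(array(1, c(5, 5, 5)))
  d1 <- discretize_roi(image_volume(vals), msk, 25)
  d2 <- discretize_roi(image_volume(vals + 333), msk, 25)
  expect_equal(glcm_features(glcm_matrix(d1)), glcm_features(glcm_matrix(d2)))
  expect_equal(glszm_features(glszm_matrix(d1)),
               glszm_features(glszm_matrix(d2)))
})
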