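test_that("z-scoring standardizes every kept feature row", {
  tab <- data.frame(id = c("a", "b", "c"), f1 = c(1, 2, 3), f2 = c(5, 5, 5),
                    f3 = c(10, 0, 20), label = c(1, 0, 0))
  expect_warning(Z <- zscore_matrix(tab), "constant")
  expect_equal(unname(Z["f1", ]), c(-1, 0, 1))
  expect_false("f2" %in% rownames(Z))
  expect_true(all(abs(rowMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 1, sd) - 1) < 1e-10))
  expect_error(zscore_matrix(tab[1, ]), "at least 2")
})

test_that("identical profiles merge first; average linkage heights are exact", {
  # three items with pairwise correlation distances 0, 0.8, 0.9:
  # the identical pair merges at 0, then average linkage merges the third
  # at (0.8 + 0.9) / 2 = 0.85
  d <- stats::as.dist(matrix(c(0, 0.0, 0.8,
                               0.0, 0, 0.9,
                               0.8, 0.9, 0), 3, 3))
  hc <- stats::hclust(d, method = "average")
  expect_equal(sort(hc$height), c(0, 0.85))

  # and through the package path: two identical profiles + one independent
  set.seed(31)
  base <- rnorm(20)
  mat <- rbind(a = base, b = base, c = rnorm(20))
  hc2 <- hier_cluster(mat, "rows")
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)
  first_merge <- hc2$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))
})

test_that("dendrogram heights are monotone and the two-way cut is total", {
  set.seed(32)
  mat <- matrix(rnorm(30 * 10), 30, 10)
  hc <- hier_cluster(mat, "rows")
  expect_true(all(diff(hc$height) >= -1e-12))
  cl <- cut_two(hc)
  expect_setequal(unique(cl), c(1, 2))
})

test_that("clustering is invariant to positive affine per-feature transforms", {
  set.seed(33)
  tab <- as.data.frame(matrix(rnorm(20 * 8), 20, 8))
  tab <- cbind(id = paste0("p", 1:20), tab)
  r1 <- cluster_cohort(tab)
  tab2 <- tab
  for (j in 2:9) tab2[[j]] <- tab2[[j]] * runif(1, 0.5, 4) + runif(1, -10, 10)
  r2 <- cluster_cohort(tab2)
  expect_equal(r1$patient_clusters, r2$patient_clusters)
  expect_equal(r1$patient_dendrogram$height, r2$patient_dendrogram$height,
               tolerance = 1e-10)
})

test_that("a planted two-group cohort is recovered by the patient cut", {
  # block structure: two patient groups with opposite feature shifts
  rand_index <- function(a, b) {
    n <- length(a)
    agree <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
    agree / choose(n, 2)
  }
  set.seed(34)
  hits <- vapply(1:5, function(trial) {
    truth <- rep(c(1, 2), times = c(15, 20))
    shift <- ifelse(truth == 1, 1.5, -1.5)
    X <- sapply(1:40, function(j) shift * sample(c(-1, 1), 1) + rnorm(35))
    tab <- cbind(data.frame(id = paste0("p", 1:35)), as.data.frame(X))
    res <- cluster_cohort(tab)
    rand_index(res$patient_clusters, truth)
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.8)
})
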