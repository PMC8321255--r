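test_that("the ANOVA screen reproduces closed-form F-test p-values", {
  tab <- data.frame(id = paste0("p", 1:6), f = c(1, 2, 3, 2, 3, 4),
                    label = c(1, 1, 1, 0, 0, 0))
  p <- anova_screen(tab)
  # F = 1.5 on (1, 4) df
  expect_equal(unname(p["f"]), pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(p["f"]), 0.288, tolerance = 1e-2)
  # cross-check against stats::aov on the same data
  a <- summary(stats::aov(f ~ factor(label), data = tab))[[1]]
  expect_equal(unname(p["f"]), a[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("the ANOVA screen handles degenerate and strong features", {
  tab <- data.frame(
    id = paste0("p", 1:35),
    same = rep(1, 35),                       # identical everywhere -> p = 1
    split = c(rep(1, 8), rep(2, 27)),        # zero within-variance -> p = 0
    label = c(rep(1, 8), rep(0, 27))
  )
  set.seed(1)
  tab$strong <- tab$label + rnorm(35, 0, 0.1)  # means 1 apart, sd 0.1
  p <- anova_screen(tab)
  expect_equal(unname(p["same"]), 1)
  expect_equal(unname(p["split"]), 0)
  expect_lt(unname(p["strong"]), 1e-10)
  expect_error(anova_screen(data.frame(x = 1:3, label = c(1, 1, 1))),
               "single class")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlation pruning keeps the lowest-FDR member of each cluster", {
  set.seed(10)
  n <- 35
  base <- rnorm(n)
  tab <- data.frame(
    a = base,                         # a and b byte-identical
    b = base,
    c = base * 0.9 + rnorm(n, 0, 0.12),  # |r| ~ 0.95 with a
    d = rnorm(n),                     # independent
    e = rnorm(n)
  )
  fdr <- c(a = 0.05, b = 0.01, c = 0.03, d = 0.02, e = 0.04)
  pr <- correlation_prune(tab, names(tab), fdr, cutoff = 0.9)
  expect_equal(unname(pr$clusters["a"]), unname(pr$clusters["b"]))
  # b has the lowest FDR of its cluster
  expect_true("b" %in% pr$representatives)
  expect_false("a" %in% pr$representatives)
  expect_true(all(c("d", "e") %in% pr$representatives))

  # mutually independent features: everyone is their own cluster
  set.seed(11)
  ind <- as.data.frame(matrix(rnorm(35 * 6), 35, 6))
  pr2 <- correlation_prune(ind, names(ind), setNames(runif(6), names(ind)))
  expect_equal(length(pr2$representatives), 6L)
})

test_that("pruning is invariant to input column order", {
  set.seed(12)
  n <- 35
  base <- rnorm(n)
  tab <- data.frame(a = base, b = base + rnorm(n, 0, 0.05), c = rnorm(n),
                    d = rnorm(n))
  fdr <- c(a = 0.01, b = 0.2, c = 0.05, d = 0.03)
  r1 <- correlation_prune(tab, c("a", "b", "c", "d"), fdr)
  r2 <- correlation_prune(tab, c("d", "c", "b", "a"), fdr)
  expect_setequal(r1$representatives, r2$representatives)
})

test_that("SFFS recovers planted features against noise competitors", {
  # two informative features + eight noise features; both planted features
  # should be selected in nearly every seeded run
  hits <- 0L
  n <- 60
  for (seed in 1:20) {
    set.seed(seed + 9000)
    lab <- rep(c(1, 0), each = n / 2)
    tab <- data.frame(
      sig1 = lab + rnorm(n, 0, 0.5),
      sig2 = lab + rnorm(n, 0, 0.5)
    )
    for (j in 1:8) tab[[paste0("noise", j)]] <- rnorm(n)
    tab$label <- lab
    sf <- sffs_select(tab, setdiff(names(tab), "label"), max_size = 3,
                      repeats = 5, seed = seed, num_trees = 100)
    if (all(c("sig1", "sig2") %in% sf$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("SFFS degenerate and structural contracts hold", {
  set.seed(3)
  tab <- data.frame(only = rnorm(30), label = rep(c(1, 0), 15))
  sf <- sffs_select(tab, "only", repeats = 3, num_trees = 50)
  expect_equal(sf$selected, "only")

  expect_error(sffs_select(tab, character(0)), "no candidate")

  # best-at-size scores are non-decreasing in subset size
  set.seed(4)
  n <- 40; lab <- rep(c(1, 0), each = 20)
  tab2 <- data.frame(a = lab + rnorm(n, 0, 0.8), b = lab + rnorm(n, 0, 0.8),
                     c = rnorm(n), d = rnorm(n), label = lab)
  sf2 <- sffs_select(tab2, c("a", "b", "c", "d"), repeats = 5, seed = 2,
                     num_trees = 100)
  sc <- sf2$scores[is.finite(sf2$scores)]
  expect_true(all(diff(sc) >= -0.02))  # small scorer noise tolerated

  # the top-3 subset generates exactly the 7 candidate models
  cm <- candidate_models(c("x", "y", "z"))
  expect_length(cm, 7L)
  expect_equal(sum(lengths(cm) == 1), 3L)
  expect_equal(sum(lengths(cm) == 2), 3L)
  expect_equal(sum(lengths(cm) == 3), 1L)
})

test_that("the BH screen controls false discoveries on null feature tables", {
  # 200 simulated null cohorts of 841 independent features: the fraction of
  # cohorts with any FDR < 0.1 discovery must stay near the nominal level
  set.seed(20260902)
  any_disc <- 0L
  for (i in 1:200) {
    X <- matrix(rnorm(35 * 841), 35, 841)
    tab <- as.data.frame(X)
    tab$label <- c(rep(1, 8), rep(0, 27))
    fdr <- bh_adjust(anova_screen(tab))
    if (any(fdr < 0.1)) any_disc <- any_disc + 1L
  }
  expect_lte(any_disc / 200, 0.15)
})
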