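# The four-stage feature-selection cascade: univariate ANOVA screening,
# Benjamini-Hochberg FDR filtering at 0.1, correlation-based redundancy
# pruning at |r| >= 0.9, and sequential floating forward selection (SFFS)
# maximizing cross-validated AUC of a random-forest model.

#' Univariate ANOVA screen
#'
#' One-way two-group ANOVA F-test per feature (equivalent to a pooled-
#' variance t-test), testing equality of class means. Features with zero
#' within-group variance but unequal means get p = 0 (infinitely strong
#' separation in the F limit); features identical across all patients get
#' p = 1.
#'
#' @param table feature table with numeric feature columns.
#' @param labels binary 0/1 outcome vector (defaults to `table$label`).
#' @param features character vector of feature columns to screen (defaults
#'   to all numeric columns except `label`).
#' @return Named vector of p-values.
#' @export
anova_screen <- function(table, labels = table$label, features = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], "label")
  }
  X <- as.matrix(table[, features, drop = FALSE])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0); n <- n1 + n0
  m1 <- colMeans(X[labels == 1, , drop = FALSE])
  m0 <- colMeans(X[labels == 0, , drop = FALSE])
  ssw <- colSums(sweep(X[labels == 1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[labels == 0, , drop = FALSE], 2, m0)^2)
  gm <- colMeans(X)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  msw <- ssw / (n - 2)
  f <- ssb / msw
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  # degenerate features: no within-group variance
  zero_w <- ssw == 0
  p[zero_w & ssb > 0] <- 0
  p[zero_w & ssb == 0] <- 1
  setNames(p, features)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, clipped at 1).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prune correlated features, keeping the strongest of each cluster
#'
#' Features are clustered by average-linkage hierarchical clustering on the
#' distance `1 - |Pearson r|`, and the dendrogram is cut at distance
#' `1 - cutoff` so that each cluster groups features correlated (positively
#' or negatively) at the cutoff level. Within each cluster only the feature
#' with the lowest FDR-adjusted p-value is kept; ties are broken by input
#' (catalog) order.
#'
#' @param table feature table containing the features.
#' @param features character vector of features that passed the FDR filter.
#' @param fdr named FDR-adjusted p-values for (at least) those features.
#' @param cutoff absolute-correlation clustering cutoff (default 0.9).
#' @return A list with `representatives` (character), `clusters` (named
#'   integer vector) and `fdr`.
#' @export
correlation_prune <- function(table, features, fdr, cutoff = 0.9) {
  if (length(features) < 1L) stopf("no features to prune")
  fdr <- fdr[features]
  if (length(features) == 1L) {
    return(list(representatives = features,
                clusters = setNames(1L, features), fdr = fdr))
  }
  X <- as.matrix(table[, features, drop = FALSE])
  cm <- abs(cor(X))
  cm[!is.finite(cm)] <- 1   # constant features: treat as perfectly redundant
  hc <- hclust(stats::as.dist(1 - cm), method = "average")
  cl <- cutree(hc, h = 1 - cutoff)
  reps <- vapply(split(seq_along(features), cl), function(idx) {
    features[idx][which.min(fdr[idx])]
  }, character(1))
  # order representatives by catalog (input) order
  reps <- features[sort(match(reps, features))]
  list(representatives = reps, clusters = setNames(cl, features), fdr = fdr)
}

# Mean test AUC over repeated stratified k-fold CV for one feature subset;
# the fold assignments are fixed by the seed so all subsets evaluated during
# a search see identical folds.
cv_auc_score <- function(table, features, labels, repeats = 20, k = 3,
                         seed = 1, num_trees = 500) {
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  labels <- as.integer(labels)
  total <- 0
  count <- 0
  for (rep_i in seq_len(repeats)) {
    folds <- stratified_folds(labels, k, seed = child_seed(seed, rep_i))
    for (fold_i in seq_len(k)) {
      te <- folds == fold_i
      probs <- fit_predict_rf(X[!te, , drop = FALSE], labels[!te],
                              X[te, , drop = FALSE], num_trees,
                              child_seed(seed, rep_i * 101 + fold_i))
      total <- total + auc(labels[te], probs)
      count <- count + 1
    }
  }
  total / count
}

#' Sequential floating forward selection
#'
#' Greedy forward selection with conditional backward exclusion: at each
#' step the feature whose inclusion maximizes mean cross-validated AUC of
#' the random-forest model is added; after each inclusion, any previously
#' added feature (other than the newest) whose removal improves on the best
#' known score at the smaller size is floated out. Deterministic given the
#' master seed, which fixes the fold assignments shared by every candidate
#' evaluation.
#'
#' @param table feature table.
#' @param candidates character vector of candidate features (the pruning
#'   stage's representatives).
#' @param labels binary 0/1 outcome (defaults to `table$label`).
#' @param max_size maximum subset size (default 3).
#' @param repeats,k internal cross-validation scorer dimensions (default
#'   20 x 3-fold).
#' @param seed master seed.
#' @param num_trees random-forest ensemble size inside the scorer.
#' @return A list with `selected` (in inclusion order), `scores` (best mean
#'   CV AUC at each subset size along the search), and `n_evaluations`.
#' @export
sffs_select <- function(table, candidates, labels = table$label, max_size = 3,
                        repeats = 20, k = 3, seed = 1, num_trees = 500) {
  if (length(candidates) < 1L) stopf("no candidate features")
  labels <- as.integer(labels)
  max_size <- min(max_size, length(candidates))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(subset) {
    key <- paste(sort(subset), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- cv_auc_score(table, subset, labels, repeats, k, seed, num_trees)
    cache[[key]] <- val
    val
  }
  current <- character(0)
  best_at_size <- rep(-Inf, max_size)
  best_set_at_size <- vector("list", max_size)
  inclusion_order <- character(0)
  while (length(current) < max_size) {
    pool <- setdiff(candidates, current)
    sc <- vapply(pool, function(f) score(c(current, f)), numeric(1))
    add <- pool[which.max(sc)]
    current <- c(current, add)
    inclusion_order <- c(inclusion_order, add)
    sz <- length(current)
    if (sc[add] > best_at_size[sz]) {
      best_at_size[sz] <- sc[[add]]
      best_set_at_size[[sz]] <- current
    }
    # conditional exclusion: float out a feature (not the newest) if doing
    # so beats the best known score at the reduced size
    repeat {
      if (length(current) <= 2L) break
      drop_pool <- setdiff(current, add)
      sc_drop <- vapply(drop_pool, function(f) score(setdiff(current, f)),
                        numeric(1))
      worst <- drop_pool[which.max(sc_drop)]
      sz1 <- length(current) - 1L
      if (sc_drop[worst] > best_at_size[sz1]) {
        current <- setdiff(current, worst)
        best_at_size[sz1] <- sc_drop[[worst]]
        best_set_at_size[[sz1]] <- current
      } else break
    }
  }
  list(selected = current,
       scores = setNames(best_at_size[seq_len(max_size)],
                         paste0("size", seq_len(max_size))),
       best_sets = best_set_at_size,
       inclusion_order = inclusion_order,
       n_evaluations = n_eval)
}

#' Run the full four-stage selection cascade
#'
#' ANOVA screen, BH-FDR filter at `fdr_cutoff`, correlation pruning at
#' `corr_cutoff`, and SFFS up to `max_size` features.
#'
#' @param table feature table with a `label` column.
#' @param features columns to consider (defaults to the full catalog subset
#'   present in the table).
#' @param fdr_cutoff FDR threshold (default 0.1).
#' @param corr_cutoff correlation-pruning cutoff (default 0.9).
#' @param max_size maximal SFFS subset size (default 3).
#' @param seed master seed for the SFFS scorer.
#' @param sffs_repeats internal CV repeats inside SFFS (default 20).
#' @param num_trees random-forest size inside SFFS.
#' @param max_candidates SFFS pool cap: the search considers only the
#'   `max_candidates` representatives with the smallest FDR (default 20),
#'   which keeps the wrapper search tractable without touching the screening
#'   and pruning stages.
#' @return A list of class `selection_report`: `p_values`, `fdr`,
#'   `passed` (features under the FDR cutoff), `clusters`,
#'   `representatives`, `selected`, `sffs` (full SFFS output), and a
#'   per-feature summary data frame `report`.
#' @export
select_features <- function(table, features = NULL, fdr_cutoff = 0.1,
                            corr_cutoff = 0.9, max_size = 3, seed = 1,
                            sffs_repeats = 20, num_trees = 500,
                            max_candidates = 20) {
  p <- anova_screen(table, features = features)
  features <- names(p)
  fdr <- setNames(bh_adjust(p), features)
  passed <- features[fdr < fdr_cutoff]
  if (!length(passed)) {
    report <- data.frame(feature = features, p_value = unname(p),
                         fdr = unname(fdr), passed = FALSE,
                         cluster = NA_integer_, representative = FALSE,
                         selected = FALSE)
    return(structure(list(p_values = p, fdr = fdr, passed = character(0),
                          clusters = integer(0), representatives = character(0),
                          selected = character(0), sffs = NULL,
                          report = report),
                     class = "selection_report"))
  }
  pr <- correlation_prune(table, passed, fdr, corr_cutoff)
  pool <- pr$representatives
  if (length(pool) > max_candidates) {
    pool <- pool[order(fdr[pool])][seq_len(max_candidates)]
    pool <- pr$representatives[pr$representatives %in% pool]
  }
  sf <- sffs_select(table, pool, labels = table$label,
                    max_size = max_size, repeats = sffs_repeats, seed = seed,
                    num_trees = num_trees)
  report <- data.frame(
    feature = features, p_value = unname(p), fdr = unname(fdr),
    passed = features %in% passed,
    cluster = unname(pr$clusters[features]),
    representative = features %in% pr$representatives,
    selected = features %in% sf$selected
  )
  structure(list(p_values = p, fdr = fdr, passed = passed,
                 clusters = pr$clusters, representatives = pr$representatives,
                 selected = sf$selected, sffs = sf, report = report),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d screened, %d passed FDR, %d representatives, selected: %s\n",
    length(x$p_values), length(x$passed), length(x$representatives),
    paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Enumerate the candidate models from the top-ranked features
#'
#' From the (up to) three top-ranked features, builds every non-empty subset:
#' three 1-feature, three 2-feature and one 3-feature model, 7 in total.
#'
#' @param selected character vector of up to 3 selected features.
#' @return A list of character vectors, one per candidate model.
#' @export
candidate_models <- function(selected) {
  stopifnot(length(selected) >= 1L)
  out <- list()
  for (sz in seq_along(selected)) {
    cmb <- utils::combn(selected, sz, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
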