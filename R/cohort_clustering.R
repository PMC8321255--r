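# Unsupervised heatmap-style analysis of the cohort: z-score standardized
# features, average-linkage hierarchical clustering on correlation distance
# for both features and patients, and a two-cluster patient cut.

#' Standardize a feature table to z-scores
#'
#' Produces a features-by-patients matrix in which each feature row is
#' centered and scaled to unit sample standard deviation. Constant features
#' cannot be standardized and are dropped with a warning.
#'
#' @param table feature table with an `id` column and numeric feature
#'   columns (a `label` column is ignored).
#' @param features columns to include (default: all numeric except `label`).
#' @return Numeric matrix (features x patients) with patient ids as column
#'   names.
#' @export
zscore_matrix <- function(table, features = NULL) {
  if (nrow(table) < 2L) stopf("need at least 2 patients to standardize")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], "label")
  }
  X <- t(as.matrix(table[, features, drop = FALSE]))
  colnames(X) <- table$id
  sds <- apply(X, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s) from z-scoring",
                    sum(const)))
    X <- X[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (X - rowMeans(X)) / sds
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Items (rows of `mat` for `axis = "rows"`, columns for `axis = "cols"`)
#' are clustered agglomeratively with average linkage on the distance
#' `1 - Pearson r` between item profiles (signed correlation: opposite
#' patterns are maximally distant).
#'
#' @param mat numeric matrix.
#' @param axis `"rows"` (features) or `"cols"` (patients).
#' @return An [stats::hclust] object.
#' @export
hier_cluster <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") mat <- t(mat)
  if (nrow(mat) < 2L) stopf("need at least 2 items to cluster")
  cm <- cor(t(mat))
  cm[!is.finite(cm)] <- 1    # identical/degenerate profiles: distance 0
  hclust(stats::as.dist(1 - cm), method = "average")
}

#' Cut a dendrogram into two groups
#'
#' @param dendrogram an [stats::hclust] object.
#' @return Integer cluster labels in `{1, 2}`.
#' @export
cut_two <- function(dendrogram) {
  cutree(dendrogram, k = 2)
}

#' Heatmap-style cohort clustering
#'
#' Standardizes all features to z-scores, clusters features and patients by
#' average linkage on correlation distance, and cuts the patient dendrogram
#' into two groups.
#'
#' @inheritParams zscore_matrix
#' @return A list of class `cluster_result`: `standardized` (features x
#'   patients z-score matrix), `feature_dendrogram`, `patient_dendrogram`,
#'   `patient_clusters` (named 1/2 labels).
#' @export
cluster_cohort <- function(table, features = NULL) {
  Z <- zscore_matrix(table, features)
  fd <- hier_cluster(Z, "rows")
  pd <- hier_cluster(Z, "cols")
  pc <- cut_two(pd)
  structure(list(standardized = Z, feature_dendrogram = fd,
                 patient_dendrogram = pd, patient_clusters = pc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d features x %d patients; patient clusters: %s\n",
              nrow(x$standardized), ncol(x$standardized),
              paste(table(x$patient_clusters), collapse = " / ")))
  invisible(x)
}
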