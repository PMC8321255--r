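# Repeated stratified 3-fold cross-validated random-forest evaluation of the
# radiomic, clinical and combined signatures, plus the ROC / precision-recall
# metric machinery.

#' Stratified k-fold assignment
#'
#' Assigns every observation to exactly one of `k` folds so that per-class
#' counts across folds differ by at most 1 (for the 8:27 study split and
#' k = 3 this forces positive counts 3/3/2 and negative counts 9/9/9).
#' Which fold receives the extra member is randomized.
#'
#' @param labels binary 0/1 outcome vector.
#' @param k number of folds (default 3).
#' @param seed RNG seed (optional).
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 3, seed = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stopf("class %d has %d members, fewer than k = %d", cl, length(idx), k)
      }
      folds[idx] <- sample(rep_len(sample.int(k), length(idx)))
    }
  })
  folds
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Concordance probability that a random positive outscores a random
#' negative, with 0.5 credit for ties.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stopf("both classes must be present")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the sum of precision at each
#' positive-retrieving threshold weighted by the recall increment.
#'
#' @inheritParams auc
#' @return PRAUC in `(0, 1]`.
#' @export
prauc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

binary_metrics <- function(labels, probs, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  c(f1 = f1, tpr = tpr, tnr = tnr)
}

max_f1 <- function(labels, probs) {
  thr <- sort(unique(probs))
  max(vapply(thr, function(t) binary_metrics(labels, probs, t)[["f1"]],
             numeric(1)))
}

# ROC as a step function TPR(FPR), evaluated on a grid (vertical averaging).
roc_at_grid <- function(labels, scores, fpr_grid) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(1 - y))
  vapply(fpr_grid, function(f) max(tpr[fpr <= f]), numeric(1))
}

# Precision as a function of recall, evaluated on a grid: for each recall
# level, the best precision achievable at recall >= that level.
pr_at_grid <- function(labels, scores, recall_grid) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  vapply(recall_grid, function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
}

#' Model specification for a signature
#'
#' @param signature one of `"radiomic"`, `"clinical"`, `"combined"`.
#' @param features character vector of feature-table column names used as
#'   predictors (clinical columns already numerically encoded, see
#'   [encode_clinical()]).
#' @param num_trees random-forest ensemble size (default 500).
#' @param seed master seed controlling folds and per-fit tree randomness.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(signature = c("radiomic", "clinical", "combined"),
                       features, num_trees = 500, seed = 1) {
  signature <- match.arg(signature)
  structure(list(signature = signature, features = features,
                 num_trees = num_trees, seed = as.integer(seed)),
            class = "model_spec")
}

#' One-hot encode the clinical covariates
#'
#' Age stays numeric; gender, tumor location and extent of resection are
#' expanded to one indicator column per observed level (including explicit
#' `Unknown` levels); no imputation is performed.
#'
#' @param clinical data frame with columns `age`, `gender`, `location`,
#'   `resection_extent` (e.g. the clinical table written by
#'   [generate_cohort()]).
#' @return A numeric data frame of encoded covariates; its column names are
#'   the clinical feature names to pass to [model_spec()].
#' @export
encode_clinical <- function(clinical) {
  stopifnot(all(c("age", "gender", "location", "resection_extent")
                %in% names(clinical)))
  out <- data.frame(clinical_age = as.numeric(clinical$age))
  for (col in c("gender", "location", "resection_extent")) {
    levs <- sort(unique(as.character(clinical[[col]])))
    for (lv in levs) {
      nm <- paste0("clinical_", col, "_", gsub("[^A-Za-z0-9]+", ".", lv))
      out[[nm]] <- as.numeric(clinical[[col]] == lv)
    }
  }
  out
}

fit_predict_rf <- function(xtr, ytr, xte, num_trees, seed) {
  fit <- ranger::ranger(
    x = xtr, y = factor(ytr, levels = c(0, 1)),
    num.trees = num_trees, mtry = max(1L, floor(sqrt(ncol(xtr)))),
    probability = TRUE, seed = seed, num.threads = 1,
    min.node.size = 1
  )
  stats::predict(fit, data = xte, num.threads = 1)$predictions[, "1"]
}

#' Evaluate a signature with repeated stratified k-fold cross-validation
#'
#' For each repeat, patients are split into stratified folds; a random forest
#' (probability ensemble of `num_trees` randomized trees, `sqrt(p)` candidate
#' features per split) is trained on k-1 folds and scored on the held-out
#' fold. AUC and PRAUC are computed per held-out fold; F1/TPR/TNR use the
#' probability threshold `threshold` (0.5 by default; a max-F1-over-
#' thresholds column is also reported). Average ROC and PR curves are built
#' by vertical averaging over all folds on fixed 101-point grids.
#'
#' @param spec a [model_spec()].
#' @param table feature table containing the spec's feature columns and a
#'   `label` column.
#' @param repeats number of cross-validation repeats (default 1000).
#' @param k folds per repeat (default 3).
#' @param threshold probability threshold for F1/TPR/TNR.
#' @return An object of class `cv_result`: `fold_metrics` (repeats*k rows),
#'   `summary` (mean and sd per metric), `roc_curve`, `pr_curve`,
#'   `oof_predictions` (patients x repeats out-of-fold probabilities),
#'   `labels`, `spec`, `repeats`, `k`.
#' @export
evaluate_model <- function(spec, table, repeats = 1000, k = 3,
                           threshold = 0.5) {
  stopifnot(inherits(spec, "model_spec"))
  missing_feats <- setdiff(spec$features, names(table))
  if (length(missing_feats)) {
    stopf("features missing from table: %s",
          paste(head(missing_feats, 5), collapse = ", "))
  }
  labels <- as.integer(table$label)
  X <- as.matrix(table[, spec$features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  grid <- seq(0, 1, length.out = 101)
  fold_metrics <- vector("list", repeats * k)
  oof <- matrix(NA_real_, n, repeats)
  roc_acc <- numeric(101)
  pr_acc <- numeric(101)
  row <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- stratified_folds(labels, k, seed = child_seed(spec$seed, rep_i))
    for (fold_i in seq_len(k)) {
      te <- folds == fold_i
      stopifnot(sum(labels[te]) >= 1)   # stratification guarantees positives
      probs <- fit_predict_rf(X[!te, , drop = FALSE], labels[!te],
                              X[te, , drop = FALSE], spec$num_trees,
                              child_seed(spec$seed, rep_i * 101 + fold_i))
      oof[te, rep_i] <- probs
      bm <- binary_metrics(labels[te], probs, threshold)
      fold_auc <- auc(labels[te], probs)
      fold_pr <- prauc(labels[te], probs)
      roc_acc <- roc_acc + roc_at_grid(labels[te], probs, grid)
      pr_acc <- pr_acc + pr_at_grid(labels[te], probs, grid)
      row <- row + 1L
      fold_metrics[[row]] <- data.frame(
        repeat_id = rep_i, fold = fold_i, auc = fold_auc, prauc = fold_pr,
        f1 = bm[["f1"]], f1_max = max_f1(labels[te], probs),
        tpr = bm[["tpr"]], tnr = bm[["tnr"]]
      )
    }
  }
  fm <- do.call(rbind, fold_metrics)
  metr <- c("auc", "prauc", "f1", "f1_max", "tpr", "tnr")
  summ <- data.frame(
    metric = metr,
    mean = vapply(metr, function(m) mean(fm[[m]]), numeric(1)),
    sd = vapply(metr, function(m) sd(fm[[m]]), numeric(1)),
    row.names = NULL
  )
  # per-repeat pooled out-of-fold PRAUC: average precision on 11-12-sample
  # folds carries a large small-sample bias (null expectation ~0.38 at the
  # 8:27 split), so the prevalence-comparable PRAUC is the pooled one
  pooled_pr <- vapply(seq_len(repeats), function(r) prauc(labels, oof[, r]),
                      numeric(1))
  summ <- rbind(summ, data.frame(metric = "prauc_pooled",
                                 mean = mean(pooled_pr), sd = sd(pooled_pr)))
  structure(list(
    fold_metrics = fm, summary = summ,
    roc_curve = data.frame(fpr = grid, tpr = roc_acc / (repeats * k)),
    pr_curve = data.frame(recall = grid, precision = pr_acc / (repeats * k)),
    oof_predictions = oof, labels = labels, spec = spec,
    repeats = repeats, k = k
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s signature, %d x %d-fold CV\n",
              x$spec$signature, x$repeats, x$k))
  print(x$summary, digits = 3)
  invisible(x)
}

#' One-tailed paired t-test between two cross-validation results
#'
#' Pairs fold-level AUC values by (repeat, fold) — the two results must have
#' been produced with the same repeat/fold structure and matched seeds — and
#' tests the mean difference `AUC_a - AUC_b` in the stated direction.
#' Zero-variance differences are resolved by sign (p = 0, 1 or 0.5).
#'
#' @param result_a,result_b `cv_result` objects from [evaluate_model()].
#' @param alternative `"greater"` tests whether `a` outperforms `b`.
#' @return A list with `p_value`, `t`, `mean_diff`, `df`.
#' @export
compare_models <- function(result_a, result_b,
                           alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(result_a, "cv_result"), inherits(result_b, "cv_result"))
  fa <- result_a$fold_metrics
  fb <- result_b$fold_metrics
  if (nrow(fa) != nrow(fb) ||
      !identical(fa$repeat_id, fb$repeat_id) || !identical(fa$fold, fb$fold)) {
    stopf("unpaired cross-validation structures")
  }
  if (result_a$spec$seed != result_b$spec$seed) {
    stopf("results were produced with different master seeds; folds are unpaired")
  }
  d <- fa$auc - fb$auc
  if (alternative == "less") d <- -d
  m <- mean(d)
  s <- sd(d)
  df <- length(d) - 1
  if (s == 0 || !is.finite(s)) {
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(p_value = p, t = if (m == 0) 0 else sign(m) * Inf,
                mean_diff = mean(fa$auc - fb$auc), df = df))
  }
  t <- m / (s / sqrt(length(d)))
  list(p_value = pt(t, df, lower.tail = FALSE), t = t,
       mean_diff = mean(fa$auc - fb$auc), df = df)
}

#' Operating cutoff on the logit scale for a target sensitivity
#'
#' Sweeps all achievable probability cutoffs on pooled out-of-fold
#' predictions, keeps those reaching `TPR >= target_tpr` (classification rule
#' `prob >= cutoff`), and returns the one minimizing FPR (ties broken toward
#' the largest cutoff). The cutoff is reported as `log(p / (1 - p))`.
#'
#' @param labels binary 0/1 vector.
#' @param probabilities predicted probabilities in (0, 1).
#' @param target_tpr target true positive rate (default 0.8).
#' @return A list of class `cutoff_result`: `cutoff_logit`, `cutoff_prob`,
#'   `tpr`, `fpr`, `target_reached` (and, if the target is unreachable, the
#'   achieved maximum in `tpr`).
#' @export
find_logit_cutoff <- function(labels, probabilities, target_tpr = 0.8) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) stopf("both classes must be present")
  thr <- sort(unique(probabilities))
  stats_at <- t(vapply(thr, function(t) {
    pred <- probabilities >= t
    c(tpr = sum(pred & labels == 1) / sum(labels == 1),
      fpr = sum(pred & labels == 0) / sum(labels == 0))
  }, numeric(2)))
  ok <- stats_at[, "tpr"] >= target_tpr
  if (!any(ok)) {
    best <- which.max(stats_at[, "tpr"])
    return(structure(list(cutoff_logit = qlogis_safe(thr[best]),
                          cutoff_prob = thr[best],
                          tpr = stats_at[best, "tpr"],
                          fpr = stats_at[best, "fpr"],
                          target_reached = FALSE), class = "cutoff_result"))
  }
  cand <- which(ok)
  cand <- cand[stats_at[cand, "fpr"] == min(stats_at[cand, "fpr"])]
  best <- cand[which.max(thr[cand])]
  structure(list(cutoff_logit = qlogis_safe(thr[best]),
                 cutoff_prob = thr[best],
                 tpr = unname(stats_at[best, "tpr"]),
                 fpr = unname(stats_at[best, "fpr"]),
                 target_reached = TRUE), class = "cutoff_result")
}

qlogis_safe <- function(p) {
  eps <- 1e-12
  log(pmin(pmax(p, eps), 1 - eps) / (1 - pmin(pmax(p, eps), 1 - eps)))
}
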