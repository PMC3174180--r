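# Classification metrics and cross-validated objective evaluation.

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred vectors of +1/-1 labels.
#' @return list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1L & pred == 1L),
       tn = sum(truth == -1L & pred == -1L),
       fp = sum(truth == -1L & pred == 1L),
       fn = sum(truth == 1L & pred == -1L))
}

#' Sensitivity, specificity, MCC and average class-wise accuracy
#'
#' Sn = TP/(TP+FN) controls false negatives, Sp = TN/(TN+FP) controls
#' false positives, MCC balances both, and ACA = (Sn+Sp)/2. MCC is defined
#' as 0 when any factor of its denominator is 0.
#'
#' @param counts list/vector with `tp`, `tn`, `fp`, `fn`.
#' @return named numeric vector `c(Sn, Sp, MCC, ACA)`.
#' @export
sn_sp_mcc_aca <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  if (tp + fn < 1L) stop("Sn undefined: no positive examples", call. = FALSE)
  if (tn + fp < 1L) stop("Sp undefined: no negative examples", call. = FALSE)
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(Sn = sn, Sp = sp, MCC = mcc, ACA = (sn + sp) / 2)
}

#' Precision and recall
#'
#' Precision = TP/(TP+FP), the fraction of predicted targets that are
#' true; recall = sensitivity.
#'
#' @inheritParams sn_sp_mcc_aca
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (tp + fp < 1L) stop("precision undefined: no predicted positives",
                         call. = FALSE)
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative; ties
#' get half credit.
#'
#' @param scores numeric prediction scores.
#' @param labels +1/-1 truth labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: within each class, a seeded shuffle then
# round-robin fold labels. Returns an integer fold id per row.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated (Sn, Sp, MCC) objectives of a feature mask
#'
#' Stratified k-fold cross-validation with a seeded shuffle; confusion
#' counts are pooled over folds (micro aggregation) before computing the
#' objective triple. Set `aggregate = "per-fold"` for macro averaging.
#'
#' @param X feature matrix; `y` +1/-1 labels (each class count >= k).
#' @param mask feature indices used to train.
#' @param params an [svm_params()].
#' @param k number of folds (default 5).
#' @param seed fold-shuffle seed.
#' @param aggregate `"pooled"` (default) or `"per-fold"`.
#' @return named numeric `c(Sn, Sp, MCC)` with attributes `counts` (the
#'   pooled confusion counts) and `accuracy` (pooled (TP+TN)/n).
#' @export
cv_objectives <- function(X, y, mask = seq_len(ncol(X)), params, k = 5L,
                          seed = 1L, aggregate = c("pooled", "per-fold")) {
  aggregate <- match.arg(aggregate)
  y <- as.integer(y)
  if (min(sum(y == 1L), sum(y == -1L)) < k) {
    stop("each class needs at least k = ", k, " examples", call. = FALSE)
  }
  folds <- stratified_folds(y, k, seed)
  pooled <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  per_fold <- matrix(NA_real_, k, 3L)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_model(X[tr, , drop = FALSE], y[tr], mask, params)
    pred <- predict_class(model, X[!tr, , drop = FALSE])
    cc <- confusion_counts(y[!tr], pred)
    pooled <- Map(`+`, pooled, cc)
    if (aggregate == "per-fold") per_fold[f, ] <- sn_sp_mcc_aca(cc)[1:3]
  }
  out <- if (aggregate == "pooled") {
    sn_sp_mcc_aca(pooled)[1:3]
  } else {
    setNames(colMeans(per_fold), c("Sn", "Sp", "MCC"))
  }
  attr(out, "counts") <- pooled
  attr(out, "accuracy") <- (pooled$tp + pooled$tn) / length(y)
  out
}

#' Pearson correlation of class mean profiles within a feature category
#'
#' Correlates the per-feature means (over examples) of one category's
#' features in the positive matrix against the negative matrix. A high
#' correlation indicates the category discriminates poorly between classes.
#'
#' @param pos_matrix,neg_matrix feature matrices in catalog column order.
#' @param category feature category, 1..7.
#' @param catalog a [feature_catalog()].
#' @return Pearson r.
#' @export
category_correlation <- function(pos_matrix, neg_matrix, category,
                                 catalog = feature_catalog()) {
  idx <- catalog$entries$index[catalog$entries$category == category]
  if (length(idx) < 2L) stop("category with < 2 features", call. = FALSE)
  if (nrow(pos_matrix) == 0L || nrow(neg_matrix) == 0L) {
    stop("empty feature matrix", call. = FALSE)
  }
  cor(colMeans(pos_matrix[, idx, drop = FALSE]),
      colMeans(neg_matrix[, idx, drop = FALSE]))
}
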