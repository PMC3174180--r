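# Wrapper feature selection: AMOSA over 90-bit feature masks with
# cross-validated (Sn, Sp, MCC) SVM objectives, final-solution choice by
# balanced-training accuracy, and archive analytics (common features,
# feature selection ratio).

#' Cross-validated objectives of one feature-mask bitstring
#'
#' Delegates to [cv_objectives()] on the columns selected by the bitstring.
#'
#' @param bits 0/1 integer vector, length = number of features; >= 1 set bit.
#' @param X,y feature matrix and +1/-1 labels.
#' @param params an [svm_params()].
#' @param seed fold-shuffle seed.
#' @param k folds (default 5).
#' @return named numeric `c(Sn, Sp, MCC)` (attributes as in
#'   [cv_objectives()]).
#' @export
evaluate_mask <- function(bits, X, y, params, seed = 1L, k = 5L) {
  if (sum(bits) == 0L) stop("mask with zero set bits", call. = FALSE)
  cv_objectives(X, y, which(bits == 1L), params, k = k, seed = seed)
}

#' Select a feature subset by archived multi-objective simulated annealing
#'
#' Runs [amosa_run()] over feature-mask bitstrings with 5-fold
#' cross-validated sensitivity, specificity and MCC as the three
#' objectives, then picks, among the archived non-dominated masks, the one
#' with the highest pooled cross-validation accuracy on the (balanced)
#' training data; ties go to larger MCC, then fewer selected features,
#' then the lexicographically smallest bitstring.
#'
#' @param X feature matrix (catalog column order); `y` +1/-1 labels
#'   (balanced classes recommended; a warning is emitted otherwise).
#' @param schedule an [amosa_schedule()].
#' @param params an [svm_params()] used for every objective evaluation.
#' @param cv_seed fold-shuffle seed shared by all evaluations.
#' @param k cross-validation folds.
#' @return list with `mask` (selected feature indices), `bits`, `archive`
#'   (the final `amosa_archive`), `accuracy` (per archived member) and
#'   `objectives` (the winning member's Sn/Sp/MCC).
#' @export
select_features <- function(X, y, schedule = amosa_schedule(),
                            params = svm_params(8, 1 / ncol(X)),
                            cv_seed = 1L, k = 5L) {
  y <- as.integer(y)
  if (sum(y == 1L) != sum(y == -1L)) {
    warning("unbalanced classes: the accuracy-based final pick assumes ",
            "balanced training data", call. = FALSE)
  }
  stats_cache <- new.env(parent = emptyenv())
  evaluator <- function(bits) {
    key <- bits_key(bits)
    hit <- stats_cache[[key]]
    if (is.null(hit)) {
      obj <- evaluate_mask(bits, X, y, params, seed = cv_seed, k = k)
      hit <- list(obj = as.numeric(obj), accuracy = attr(obj, "accuracy"))
      stats_cache[[key]] <- hit
    }
    hit$obj
  }
  archive <- amosa_run(evaluator, ncol(X), schedule)
  n <- nrow(archive$bits)
  acc <- numeric(n)
  for (i in seq_len(n)) {
    key <- bits_key(archive$bits[i, ])
    hit <- stats_cache[[key]]
    if (is.null(hit)) {  # member could predate a cache (not expected)
      obj <- evaluate_mask(archive$bits[i, ], X, y, params,
                           seed = cv_seed, k = k)
      hit <- list(obj = as.numeric(obj), accuracy = attr(obj, "accuracy"))
    }
    acc[i] <- hit$accuracy
  }
  keys <- apply(archive$bits, 1L, bits_key)
  ord <- order(-acc, -archive$obj[, 3L], rowSums(archive$bits), keys)
  best <- ord[1L]
  list(mask = which(archive$bits[best, ] == 1L),
       bits = archive$bits[best, ],
       archive = archive,
       accuracy = acc,
       objectives = setNames(archive$obj[best, ], c("Sn", "Sp", "MCC")))
}

#' Features common to most archived solutions
#'
#' Returns the feature indices set in at least `ceiling(threshold * n)` of
#' the `n` archive members (default: at least 90% of the solutions).
#'
#' @param archive an `amosa_archive` of feature-mask solutions.
#' @param threshold required fraction of members (default 0.90).
#' @return integer vector of feature indices.
#' @export
common_features <- function(archive, threshold = 0.90) {
  n <- nrow(archive$bits)
  if (n == 0L) stop("empty archive", call. = FALSE)
  need <- ceiling(threshold * n)
  which(colSums(archive$bits) >= need)
}

#' Per-category feature selection ratio (FSR)
#'
#' For each catalog category, the percentage of its features retained by
#' the mask: `100 * |mask in category| / |category|`, to 2 decimals.
#'
#' @param mask selected feature indices (subset of 1..90).
#' @param catalog a [feature_catalog()].
#' @return data.frame with `category`, `total`, `selected`, `fsr`.
#' @export
feature_selection_ratio <- function(mask, catalog = feature_catalog()) {
  stopifnot(all(mask %in% catalog$entries$index))
  cats <- sort(unique(catalog$entries$category))
  total <- vapply(cats, function(c) sum(catalog$entries$category == c),
                  integer(1L))
  sel <- vapply(cats, function(c) {
    sum(mask %in% catalog$entries$index[catalog$entries$category == c])
  }, integer(1L))
  data.frame(category = cats, total = total, selected = sel,
             fsr = round(100 * sel / total, 2L))
}
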