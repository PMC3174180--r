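# Decision-score ranking of interactions and rank-distribution /
# resampling comparison analyses.

#' Rank scored interactions by decision value
#'
#' Descending: rank 1 is the highest score; tied scores share the mean
#' rank. Input order never affects the assigned ranks.
#'
#' @param ids interaction identifiers.
#' @param scores decision values.
#' @return data.frame `id`, `score`, `rank`, sorted by rank.
#' @export
rank_interactions <- function(ids, scores) {
  stopifnot(length(ids) == length(scores))
  if (length(ids) == 0L) {
    return(data.frame(id = character(), score = numeric(), rank = numeric(),
                      stringsAsFactors = FALSE))
  }
  r <- rank(-scores, ties.method = "average")
  out <- data.frame(id = ids, score = scores, rank = r,
                    stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Fraction of true positives within the top percentile of a ranked list
#'
#' The percentile boundary is inclusive and uses a ceiling cutoff:
#' rank <= `ceiling(pct/100 * n)`, a deterministic convention for short
#' lists.
#'
#' @param ranks rank positions (from [rank_interactions()]).
#' @param truth logical (or 0/1) true-positive flags, aligned with `ranks`.
#' @param pct percentile (default 20).
#' @return fraction in `[0, 1]`.
#' @export
top_percentile_fraction <- function(ranks, truth, pct = 20) {
  truth <- as.logical(truth)
  if (sum(truth) == 0L) stop("no true positives in the ranked list",
                             call. = FALSE)
  cutoff <- ceiling(pct / 100 * length(ranks))
  sum(truth & ranks <= cutoff) / sum(truth)
}

#' Fraction of true positives in the top half of a ranked list
#'
#' Equivalent to [top_percentile_fraction()] at the 50th percentile.
#'
#' @inheritParams top_percentile_fraction
#' @return fraction in `[0, 1]`.
#' @export
within_half_ratio <- function(ranks, truth) {
  top_percentile_fraction(ranks, truth, pct = 50)
}

#' Compare two ranked lists of true-positive positions
#'
#' Two-sided Wilcoxon rank-sum test on the normalized rank positions of
#' the true positives under two rankers; a small p-value means one ranker
#' places its true positives systematically nearer the top. Exact
#' enumeration is used below 20 observations per group (when free of
#' ties), the tie-corrected normal approximation otherwise.
#'
#' @param ranks_a,ranks_b true-positive rank positions, each normalized by
#'   its own list length (or raw, if the lists have equal length).
#' @return two-sided p-value.
#' @export
compare_rank_lists <- function(ranks_a, ranks_b) {
  if (length(ranks_a) == 0L || length(ranks_b) == 0L) {
    stop("empty rank list", call. = FALSE)
  }
  if (length(unique(c(ranks_a, ranks_b))) == 1L) {
    return(1)  # all positions identical: no evidence either way
  }
  exact <- length(ranks_a) < 20L && length(ranks_b) < 20L &&
    !any(duplicated(c(ranks_a, ranks_b)))
  suppressWarnings(
    wilcox.test(ranks_a, ranks_b, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Resampled metric comparison of two scorers
#'
#' Repeatedly draws `sample_size` pairs without replacement (redrawing
#' until both classes are present), computes Sn, Sp, MCC and precision for
#' both scorers on each draw (predicted class = sign of score), and
#' compares the two scorers per metric with a two-sided Wilcoxon rank-sum
#' test across the repeats.
#'
#' @param scores_a,scores_b decision values from the two scorers, aligned
#'   with `labels`.
#' @param labels +1/-1 truth labels.
#' @param sample_size pairs drawn per repeat (default 100).
#' @param repeats number of repeats (default 100).
#' @param seed RNG seed.
#' @return list with `p_values` (named: Sn, Sp, MCC, precision) and
#'   `metrics_a`/`metrics_b` (repeats x 4 matrices).
#' @export
resampled_metric_comparison <- function(scores_a, scores_b, labels,
                                        sample_size = 100L, repeats = 100L,
                                        seed = 1L) {
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  if (n < sample_size) stop("dataset smaller than sample_size", call. = FALSE)
  metric_names <- c("Sn", "Sp", "MCC", "precision")
  one <- function(scores, idx) {
    truth <- labels[idx]
    pred <- ifelse(scores[idx] > 0, 1L, -1L)
    cc <- confusion_counts(truth, pred)
    m <- sn_sp_mcc_aca(cc)[1:3]
    prec <- if (cc$tp + cc$fp >= 1L) cc$tp / (cc$tp + cc$fp) else 0
    c(m, precision = prec)
  }
  A <- matrix(NA_real_, repeats, 4L, dimnames = list(NULL, metric_names))
  B <- A
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      repeat {
        idx <- sample.int(n, sample_size)
        if (any(labels[idx] == 1L) && any(labels[idx] == -1L)) break
      }
      A[r, ] <- one(scores_a, idx)
      B[r, ] <- one(scores_b, idx)
    }
  })
  p <- vapply(metric_names, function(m) {
    suppressWarnings(
      wilcox.test(A[, m], B[, m], alternative = "two.sided")$p.value
    )
  }, numeric(1L))
  list(p_values = p, metrics_a = A, metrics_b = B)
}
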