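# Archived multi-objective simulated annealing (AMOSA) over fixed-length
# bitstrings, maximization, with a pluggable objective evaluator.
#
# The archive stores mutually non-dominated solutions under a soft limit SL
# (never exceeded) and a hard limit HL (enforced by single-linkage
# clustering whenever the size passes SL, and again at termination).
# Acceptance of a perturbed solution follows the three-case domination
# logic, with probabilistic acceptance 1 / (1 + exp(dom_avg / T)) when the
# new point is dominated, where dom_avg averages the amount of domination
# of the dominating solutions over the new point, so high temperatures are
# more permissive.

#' Pareto dominance (maximization)
#'
#' `a` dominates `b` iff `a >= b` componentwise with strict `>` in at
#' least one component.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors of unequal length",
                                   call. = FALSE)
  all(a >= b) && any(a > b)
}

#' Amount of domination between two objective vectors
#'
#' The product, over objectives where the two vectors differ, of
#' `|a_i - b_i| / R_i` with `R_i` the range of objective i. Equal vectors
#' give 0.
#'
#' @param a,b numeric objective vectors.
#' @param ranges strictly positive objective ranges.
#' @return non-negative real.
#' @export
domination_amount <- function(a, b, ranges) {
  if (any(ranges <= 0)) stop("objective ranges must be > 0", call. = FALSE)
  d <- abs(a - b)
  differ <- d > 0
  if (!any(differ)) return(0)
  prod(d[differ] / ranges[differ])
}

#' Annealing schedule and archive limits
#'
#' @param Tmax,Tmin initial and final temperatures (`Tmax > Tmin > 0`).
#' @param alpha geometric cooling factor in (0, 1).
#' @param iters_per_temp iterations at each temperature.
#' @param n_init number of initial solutions.
#' @param hc_iters hill-climbing refinement steps per initial solution.
#' @param HL,SL hard and soft archive limits (`SL >= HL`).
#' @param seed RNG seed; all randomness in a run derives from it.
#' @return list of class `amosa_schedule`.
#' @export
amosa_schedule <- function(Tmax = 100, Tmin = 1e-4, alpha = 0.9,
                           iters_per_temp = 50L, n_init = 10L,
                           hc_iters = 20L, HL = 30L, SL = 60L, seed = 1L) {
  stopifnot(Tmax > Tmin, Tmin > 0, alpha > 0, alpha < 1, iters_per_temp >= 1,
            n_init >= 1, hc_iters >= 0, HL >= 1, SL >= HL)
  structure(list(Tmax = Tmax, Tmin = Tmin, alpha = alpha,
                 iters_per_temp = as.integer(iters_per_temp),
                 n_init = as.integer(n_init), hc_iters = as.integer(hc_iters),
                 HL = as.integer(HL), SL = as.integer(SL),
                 seed = as.integer(seed)),
            class = "amosa_schedule")
}

new_archive <- function(bits, obj) {
  structure(list(bits = bits, obj = obj), class = "amosa_archive")
}

#' @export
print.amosa_archive <- function(x, ...) {
  cat("AMOSA archive: ", nrow(x$bits), " non-dominated solution(s), ",
      ncol(x$obj), " objectives\n", sep = "")
  invisible(x)
}

# Indices of rows of `obj` not dominated by any other row.
nondominated_rows <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(obj[j, ], obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

bits_key <- function(bits) paste(bits, collapse = "")

# Flip one uniformly chosen bit; re-flip until at least one bit is set.
perturb_bits <- function(bits) {
  repeat {
    i <- sample.int(length(bits), 1L)
    bits[i] <- 1L - bits[i]
    if (any(bits == 1L)) return(bits)
  }
}

# Stateful evaluator wrapper: memoizes objective vectors by bitstring and
# tracks running per-objective min/max for Eq.-style range normalization.
make_tracker <- function(evaluator) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$lo <- NULL
  env$hi <- NULL
  env$evaluate <- function(bits) {
    key <- bits_key(bits)
    if (!is.null(env$cache[[key]])) return(env$cache[[key]])
    obj <- tryCatch(as.numeric(evaluator(bits)), error = function(e) {
      stop("objective evaluation failed for bitstring ", key, ": ",
           conditionMessage(e), call. = FALSE)
    })
    if (is.null(env$lo)) {
      env$lo <- obj
      env$hi <- obj
    } else {
      env$lo <- pmin(env$lo, obj)
      env$hi <- pmax(env$hi, obj)
    }
    env$cache[[key]] <- obj
    obj
  }
  env$ranges <- function() pmax(env$hi - env$lo, 1e-6)
  env
}

# Insert a non-dominated solution: drop members it dominates, append, and
# cluster-reduce to HL when the size exceeds SL. Duplicates are ignored.
archive_insert <- function(archive, bits, obj, schedule, validate = FALSE) {
  if (nrow(archive$bits) > 0L) {
    keys <- apply(archive$bits, 1L, bits_key)
    if (bits_key(bits) %in% keys) return(archive)
    dominated <- vapply(seq_len(nrow(archive$obj)),
                        function(i) dominates(obj, archive$obj[i, ]),
                        logical(1L))
    archive$bits <- archive$bits[!dominated, , drop = FALSE]
    archive$obj <- archive$obj[!dominated, , drop = FALSE]
  }
  archive$bits <- rbind(archive$bits, bits)
  archive$obj <- rbind(archive$obj, obj)
  rownames(archive$bits) <- rownames(archive$obj) <- NULL
  if (nrow(archive$bits) > schedule$SL) {
    archive <- cluster_reduce(archive, schedule$HL)
  }
  if (validate) assert_archive(archive, schedule$SL)
  archive
}

assert_archive <- function(archive, SL) {
  n <- nrow(archive$obj)
  if (n > SL) stop("archive invariant violated: size ", n, " > SL ", SL)
  if (length(nondominated_rows(archive$obj)) != n) {
    stop("archive invariant violated: dominated member present")
  }
  invisible(TRUE)
}

#' Reduce an archive to a target size by single-linkage clustering
#'
#' Clusters the members in objective space (Euclidean distance, single
#' linkage) into `target` clusters and keeps, from each cluster, the member
#' whose average distance to the other members of its cluster is minimal
#' (ties broken by lexicographically smallest bitstring). Archives already
#' within the target are returned unchanged.
#'
#' @param archive an `amosa_archive`.
#' @param target desired maximum size (the hard limit).
#' @return reduced `amosa_archive`.
#' @export
cluster_reduce <- function(archive, target) {
  n <- nrow(archive$obj)
  if (n <= target) return(archive)
  d <- as.matrix(dist(archive$obj))
  cl <- cutree(hclust(as.dist(d), method = "single"), k = target)
  keep <- integer(target)
  for (c in seq_len(target)) {
    members <- which(cl == c)
    if (length(members) == 1L) {
      keep[c] <- members
    } else {
      avg <- rowMeans(d[members, members, drop = FALSE]) *
        length(members) / (length(members) - 1L)  # exclude self-distance 0
      best <- members[avg == min(avg)]
      if (length(best) > 1L) {
        keys <- apply(archive$bits[best, , drop = FALSE], 1L, bits_key)
        best <- best[order(keys)]
      }
      keep[c] <- best[1L]
    }
  }
  keep <- sort(keep)
  new_archive(archive$bits[keep, , drop = FALSE],
              archive$obj[keep, , drop = FALSE])
}

#' Initialize the AMOSA archive
#'
#' Draws `n_init` random bitstrings (each guaranteed at least one set bit),
#' refines each by `hc_iters` hill-climbing steps (a single-bit-flip
#' neighbor is accepted iff it dominates the current point), keeps the
#' mutually non-dominated refined solutions, and cluster-reduces to HL if
#' needed. Deterministic under the schedule seed.
#'
#' @param evaluator function(bits) -> numeric objective vector
#'   (maximization); must be defined for every bitstring with >= 1 set bit.
#' @param L bitstring length.
#' @param schedule an [amosa_schedule()].
#' @return an `amosa_archive`.
#' @export
amosa_initialize <- function(evaluator, L, schedule = amosa_schedule()) {
  tracker <- make_tracker(evaluator)
  with_seed(schedule$seed,
            init_archive(tracker, L, schedule, validate = FALSE)$archive)
}

init_archive <- function(tracker, L, schedule, validate) {
  bits_mat <- matrix(0L, schedule$n_init, L)
  obj_mat <- NULL
  for (i in seq_len(schedule$n_init)) {
    bits <- sample(c(0L, 1L), L, replace = TRUE)
    if (!any(bits == 1L)) bits[sample.int(L, 1L)] <- 1L
    obj <- tracker$evaluate(bits)
    for (step in seq_len(schedule$hc_iters)) {
      cand <- perturb_bits(bits)
      cand_obj <- tracker$evaluate(cand)
      if (dominates(cand_obj, obj)) {
        bits <- cand
        obj <- cand_obj
      }
    }
    bits_mat[i, ] <- bits
    obj_mat <- rbind(obj_mat, obj)
  }
  keys <- apply(bits_mat, 1L, bits_key)
  uniq <- !duplicated(keys)
  bits_mat <- bits_mat[uniq, , drop = FALSE]
  obj_mat <- obj_mat[uniq, , drop = FALSE]
  nd <- nondominated_rows(obj_mat)
  archive <- new_archive(bits_mat[nd, , drop = FALSE],
                         obj_mat[nd, , drop = FALSE])
  rownames(archive$obj) <- NULL
  if (nrow(archive$bits) > schedule$HL) {
    archive <- cluster_reduce(archive, schedule$HL)
  }
  if (validate) assert_archive(archive, schedule$SL)
  list(archive = archive, tracker = tracker)
}

#' Run archived multi-objective simulated annealing
#'
#' Anneals from `Tmax` to `Tmin` by factor `alpha`, perturbing the current
#' point by one uniformly chosen bit flip per iteration and applying the
#' three-case acceptance logic: (a) the new point dominates the current
#' point - accept, and insert into the archive when no member dominates it;
#' (b) the current point dominates the new point - accept with probability
#' `1/(1 + exp(dom_avg/T))`, averaging the amount of domination of the
#' current point and any dominating archive members over the new point;
#' (c) mutually non-dominating - accept and insert when no archive member
#' dominates the new point, otherwise accept with the same probabilistic
#' form. Objective ranges for the amount of domination are running
#' min/max over all solutions evaluated so far, floored at 1e-6.
#'
#' @inheritParams amosa_initialize
#' @param validate check archive invariants after every insertion (used by
#'   the test suite; slows the run down).
#' @return final `amosa_archive` (mutually non-dominated, size <= HL) with
#'   attribute `"n_evaluated"` (distinct bitstrings evaluated).
#' @export
amosa_run <- function(evaluator, L, schedule = amosa_schedule(),
                      validate = FALSE) {
  tracker <- make_tracker(evaluator)
  with_seed(schedule$seed, {
    archive <- init_archive(tracker, L, schedule, validate)$archive
    cur_i <- sample.int(nrow(archive$bits), 1L)
    current <- archive$bits[cur_i, ]
    cur_obj <- archive$obj[cur_i, ]
    temp <- schedule$Tmax
    while (temp >= schedule$Tmin) {
      for (it in seq_len(schedule$iters_per_temp)) {
        new_bits <- perturb_bits(current)
        new_obj <- tracker$evaluate(new_bits)
        ranges <- tracker$ranges()
        dominating <- if (nrow(archive$obj) > 0L) {
          which(vapply(seq_len(nrow(archive$obj)),
                       function(i) dominates(archive$obj[i, ], new_obj),
                       logical(1L)))
        } else integer()
        if (dominates(new_obj, cur_obj)) {
          current <- new_bits
          cur_obj <- new_obj
          if (length(dominating) == 0L) {
            archive <- archive_insert(archive, new_bits, new_obj, schedule,
                                      validate)
          }
        } else if (dominates(cur_obj, new_obj)) {
          doms <- c(domination_amount(cur_obj, new_obj, ranges),
                    vapply(dominating, function(i) {
                      domination_amount(archive$obj[i, ], new_obj, ranges)
                    }, numeric(1L)))
          if (runif(1L) < 1 / (1 + exp(mean(doms) / temp))) {
            current <- new_bits
            cur_obj <- new_obj
          }
        } else {
          if (length(dominating) == 0L) {
            current <- new_bits
            cur_obj <- new_obj
            archive <- archive_insert(archive, new_bits, new_obj, schedule,
                                      validate)
          } else {
            doms <- vapply(dominating, function(i) {
              domination_amount(archive$obj[i, ], new_obj, ranges)
            }, numeric(1L))
            if (runif(1L) < 1 / (1 + exp(mean(doms) / temp))) {
              current <- new_bits
              cur_obj <- new_obj
            }
          }
        }
      }
      temp <- temp * schedule$alpha
    }
    if (nrow(archive$bits) > schedule$HL) {
      archive <- cluster_reduce(archive, schedule$HL)
    }
    structure(archive,
              n_evaluated = length(ls(tracker$cache)))
  })
}
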