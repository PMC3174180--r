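# Archived multi-objective simulated annealing: dominance, domination
# amount, archive maintenance, clustering reduction, annealing runs.

# two toy objective problems used throughout
toy_single_optimum <- function(bits) c(sum(bits[1:5]), sum(bits[6:10]))
toy_conflicting <- function(bits) c(sum(bits), sum(1 - bits))

fast_schedule <- function(seed) {
  amosa_schedule(Tmax = 1, Tmin = 0.01, alpha = 0.5, iters_per_temp = 20,
                 n_init = 5, hc_iters = 10, HL = 10, SL = 20, seed = seed)
}

test_that("Pareto dominance is weak dominance plus one strict component", {
  expect_true(dominates(c(0.9, 0.9), c(0.8, 0.9)))
  expect_false(dominates(c(0.9, 0.7), c(0.8, 0.8)))
  expect_false(dominates(c(0.5, 0.5), c(0.5, 0.5)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "unequal")
})

test_that("amount of domination multiplies normalized gaps over differing objectives", {
  expect_equal(domination_amount(c(0.8, 0.6), c(0.6, 0.5), c(1, 1)),
               0.2 * 0.1)
  # equal components are skipped, not counted as factor 0
  expect_equal(domination_amount(c(0.8, 0.5), c(0.6, 0.5), c(1, 1)), 0.2)
  expect_equal(domination_amount(c(0.3, 0.3), c(0.3, 0.3), c(1, 1)), 0)
  expect_error(domination_amount(c(1, 1), c(0, 0), c(1, 0)), "> 0")
})

test_that("domination amount is symmetric, non-negative, zero iff equal", {
  set.seed(600)
  for (i in 1:50) {
    a <- runif(3); b <- runif(3); r <- runif(3, 0.5, 2)
    expect_equal(domination_amount(a, b, r), domination_amount(b, a, r))
    expect_gte(domination_amount(a, b, r), 0)
  }
})

test_that("initialization returns a mutually non-dominated archive, seeded", {
  a1 <- amosa_initialize(toy_conflicting, 8, fast_schedule(3))
  expect_s3_class(a1, "amosa_archive")
  nd <- mirtarsvm:::nondominated_rows(a1$obj)
  expect_equal(length(nd), nrow(a1$obj))
  a2 <- amosa_initialize(toy_conflicting, 8, fast_schedule(3))
  expect_identical(a1, a2)
  one <- amosa_initialize(toy_conflicting, 8,
                          amosa_schedule(n_init = 1, seed = 1))
  expect_equal(nrow(one$bits), 1L)
})

test_that("single-linkage reduction keeps min-average-distance representatives", {
  arch <- mirtarsvm:::new_archive(
    bits = rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)),
    obj = cbind(c(0, 0.1, 1), c(0, 0.1, 1)))
  red <- cluster_reduce(arch, 2)
  expect_equal(nrow(red$obj), 2L)
  # cluster {0, 0.1} keeps one of its members; cluster {1} survives as-is
  expect_true(any(red$obj[, 1] == 1))
  expect_true(any(red$obj[, 1] %in% c(0, 0.1)))

  # identical objectives, target 1: a single representative remains
  same <- mirtarsvm:::new_archive(
    bits = rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)),
    obj = matrix(0.5, 3, 2))
  expect_equal(nrow(cluster_reduce(same, 1)$obj), 1L)

  # already within target: identity
  expect_identical(cluster_reduce(arch, 5), arch)
})

test_that("archive invariants hold after every insertion across seeded runs", {
  for (seed in 1:10) {
    a <- amosa_run(toy_single_optimum, 10, fast_schedule(seed),
                   validate = TRUE)  # validate errors on any violation
    expect_lte(nrow(a$bits), fast_schedule(seed)$HL)
    expect_equal(length(mirtarsvm:::nondominated_rows(a$obj)), nrow(a$obj))
  }
  for (seed in 1:10) {
    a <- amosa_run(toy_conflicting, 8, fast_schedule(seed), validate = TRUE)
    # conflicting objectives: no member may strictly dominate another
    # (members sharing a ones-count have equal objective vectors and are
    # mutually non-dominating, so they may coexist)
    expect_equal(length(mirtarsvm:::nondominated_rows(a$obj)), nrow(a$obj))
    expect_lte(nrow(a$bits), 10L)
  }
})

test_that("annealing runs are deterministic under a fixed seed", {
  a1 <- amosa_run(toy_conflicting, 8, fast_schedule(9))
  a2 <- amosa_run(toy_conflicting, 8, fast_schedule(9))
  expect_identical(a1, a2)
})

test_that("the single-optimum problem is solved in nearly all seeded runs", {
  hits <- 0L
  for (seed in 1:40) {
    a <- amosa_run(toy_single_optimum, 10, fast_schedule(seed))
    if (any(apply(a$bits, 1, function(b) all(b == 1L)))) hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # all-ones dominates every other bitstring
})

test_that("evaluator failures propagate with the offending bitstring", {
  bad <- function(bits) if (sum(bits) > 2) stop("boom") else c(1, 1)
  expect_error(amosa_run(bad, 6, fast_schedule(1)), "bitstring")
})
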