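# Confusion metrics, AUC, cross-validated objectives, category correlation.

test_that("worked confusion-metric values are reproduced", {
  perfect <- sn_sp_mcc_aca(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  m <- sn_sp_mcc_aca(list(tp = 3, tn = 3, fp = 1, fn = 1))
  expect_equal(unname(m["MCC"]), 0.5)  # (9-1)/sqrt(4^4)
  expect_equal(unname(m["ACA"]), (0.75 + 0.75) / 2)
  pr <- precision_recall(list(tp = 4, fp = 4, fn = 12, tn = 0))
  expect_equal(unname(pr), c(0.5, 0.25))
})

test_that("metric preconditions raise errors", {
  expect_error(sn_sp_mcc_aca(list(tp = 0, tn = 3, fp = 1, fn = 0)), "Sn undefined")
  expect_error(sn_sp_mcc_aca(list(tp = 3, tn = 0, fp = 0, fn = 1)), "Sp undefined")
  expect_error(precision_recall(list(tp = 0, fp = 0, fn = 3, tn = 2)),
               "precision undefined")
  expect_error(auc_score(1:5, rep(1L, 5)), "both classes")
})

test_that("metrics match direct-formula oracles on random confusion tables", {
  set.seed(300)
  for (i in 1:250) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    got <- sn_sp_mcc_aca(list(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(unname(got), unname(oracle_metrics(tp, tn, fp, fn)),
                 tolerance = 1e-12)
  }
})

test_that("MCC stays in [-1, 1] and |MCC| is label-swap invariant", {
  set.seed(301)
  for (i in 1:100) {
    c1 <- list(tp = sample(1:30, 1), tn = sample(1:30, 1),
               fp = sample(0:30, 1), fn = sample(0:30, 1))
    m <- sn_sp_mcc_aca(c1)["MCC"]
    expect_true(m >= -1 && m <= 1)
    swapped <- list(tp = c1$tn, tn = c1$tp, fp = c1$fn, fn = c1$fp)
    expect_equal(abs(m), abs(sn_sp_mcc_aca(swapped)["MCC"]),
                 ignore_attr = TRUE)
  }
})

test_that("AUC equals the brute-force ordered-pair fraction", {
  set.seed(302)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    labels <- sample(c(1L, -1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  expect_equal(auc_score(c(3, 4, 1, 2), c(1, 1, -1, -1)), 1.0)
  expect_equal(auc_score(rep(1, 10), rep(c(1, -1), 5)), 0.5)
})

test_that("cross-validated objectives are exact on separable data and seeded", {
  d <- separable_data(n_per_class = 25)
  cv1 <- cv_objectives(d$X, d$y, params = svm_params(8, 0.2), seed = 4)
  expect_equal(unname(cv1[1:3]), c(1, 1, 1), tolerance = 0.05)
  cv2 <- cv_objectives(d$X, d$y, params = svm_params(8, 0.2), seed = 4)
  expect_identical(cv1, cv2)
  expect_error(cv_objectives(d$X[1:6, ], d$y[1:6], params = svm_params(1, 1)),
               "at least k")
})

test_that("permuted labels give near-zero cross-validated MCC", {
  set.seed(400)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(1L, -1L), each = n / 2)  # labels independent of X
  cv <- cv_objectives(X, y, params = svm_params(1, 0.1), seed = 2)
  expect_lt(abs(cv["MCC"]), 0.15)
})

test_that("category correlation equals a direct Pearson computation", {
  set.seed(500)
  pos <- matrix(rnorm(20 * 90), 20, 90)
  neg <- matrix(rnorm(20 * 90), 20, 90)
  cat4 <- feature_catalog()$entries$index[feature_catalog()$entries$category == 4]
  mu_p <- apply(pos[, cat4], 2, mean)
  mu_n <- apply(neg[, cat4], 2, mean)
  direct <- sum((mu_p - mean(mu_p)) * (mu_n - mean(mu_n))) /
    sqrt(sum((mu_p - mean(mu_p))^2) * sum((mu_n - mean(mu_n))^2))
  expect_equal(category_correlation(pos, neg, 4), direct)
  expect_lt(abs(category_correlation(pos, neg, 4)), 1)
  # identical class means give r = 1; anti-proportional give r = -1
  expect_equal(category_correlation(pos, pos, 5), 1)
  expect_equal(category_correlation(pos, -pos, 5), -1)
})
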