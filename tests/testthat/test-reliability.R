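test_that("node reference estimates follow the threshold strictly", {
  fit <- small_fit(400, seed = 15)
  ref <- estimate_node_reference(fit$tree, fit$test)
  expect_equal(sum(ref$n_t), nrow(fit$test))          # partition
  expect_true(all(ref$P_hat >= 0 & ref$P_hat <= 1, na.rm = TRUE))
  k <- fit$tree$costs$threshold_k
  expect_equal(ref$c_hat[ref$n_t > 0],
               as.integer(ref$P_hat[ref$n_t > 0] > k))
  # boundary: exactly P_hat = k goes to class 0
  expect_equal(as.integer(0.5 > 0.5), 0L)
})

test_that("refined probability is the replicate mean", {
  expect_equal(refine_probability(rep(0.3, 7)), 0.3)
  expect_equal(refine_probability(c(0, 1)), 0.5)
  set.seed(1)
  p <- runif(250)
  expect_equal(refine_probability(p), sum(p) / 250, tolerance = 1e-12)
  expect_true(is.na(refine_probability(rep(NA_real_, 5))))
})

test_that("classification reliability counts threshold agreements", {
  expect_equal(classification_reliability(c(0.6, 0.4, 0.7, 0.2), 1, 0.5), 50)
  expect_equal(classification_reliability(rep(0.8, 10), 1, 0.5), 100)
  # boundary p_b = k counts as agreement with class 0
  expect_equal(classification_reliability(rep(0.5, 10), 0, 0.5), 100)
  # invariant to permuting replicates
  set.seed(3)
  p <- runif(100)
  expect_equal(classification_reliability(p, 1, 0.4),
               classification_reliability(sample(p), 1, 0.4))
})

test_that("logit shrinkage pulls probabilities to one half", {
  expect_equal(shrink_probability(0.5, 1e-4), 0.5)
  expect_equal(shrink_probability(0.003, 1e-4), 0.499855, tolerance = 1e-6)
  expect_lt(abs(shrink_probability(0.9, 1e-12) - 0.5), 1e-10)
  # clamping keeps the endpoints finite
  expect_true(all(is.finite(shrink_probability(c(0, 1), 1e-4))))
})

test_that("variance formulas match exact binomial moments", {
  # V_I from the closed form equals (mu4/mu2 - mu2)/(4 n^2) with moments
  # computed by direct enumeration of the binomial distribution
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:60, 1)
    p <- runif(1, 0.05, 0.95)
    x <- 0:n
    px <- dbinom(x, n, p)
    mu2 <- sum((x - n * p)^2 * px)
    mu4 <- sum((x - n * p)^4 * px)
    v <- node_variance(p, n, B = 500)
    expect_equal(v$V_I, (mu4 / mu2 - mu2) / (4 * n^2), tolerance = 1e-10)
  }
  # degenerate n = 3: the (n-3) term vanishes
  expect_equal(node_variance(0.3, 3, 500)$V_I, 1 / 36)
  expect_equal(node_variance(0.9, 3, 500)$V_I, 1 / 36)
  # p = 0.5, n = 103
  expect_equal(node_variance(0.5, 103, 500)$V_I,
               (0.5 * 100 + 1) / (4 * 103^2))
  expect_error(node_variance(0.5, 0, 500), "n_t")
})

test_that("the reference variance dominates the sampling variance", {
  expect_equal(reference_variance(0.3, 3), 1 / 36)
  n <- 40
  expect_equal(reference_variance(0.2, n),
               (2 * 0.25 * (n - 3) + 1) / (4 * n^2), tolerance = 1e-6)
  for (n in c(5, 18, 103)) {
    p <- seq(0, 1, 0.01)
    expect_true(all(reference_variance(p, n) + 1e-12 >=
                      node_variance(p, n, 500)$V_I))
  }
})

test_that("prediction reliability behaves as a worst-case ratio", {
  v <- node_variance(0.3, 3, 500)
  expect_equal(prediction_reliability(v$V_I, reference_variance(0.3, 3)), 100)
  # p = 0.5 attains the worst case for any n
  for (n in c(10, 50, 200)) {
    v <- node_variance(0.5, n, 500)
    expect_gt(prediction_reliability(v$V_I, reference_variance(0.5, n)),
              99.99)
  }
  v <- node_variance(0.339, 18, 500)
  expect_lt(abs(prediction_reliability(v$V_I, reference_variance(0.339, 18))
                - 90.9), 0.1)
  # monotone in p(1-p) at fixed n
  p <- seq(0.05, 0.5, 0.05)
  v <- node_variance(p, 18, 500)
  rp <- prediction_reliability(v$V_I, reference_variance(p, 18))
  expect_true(all(diff(rp) > 0))
  # V_II / V_I = 1/B exactly
  v <- node_variance(0.27, 44, 123)
  expect_equal(v$V_II / v$V_I, 1 / 123, tolerance = 1e-14)
})

test_that("flags mirror the reported decision rules", {
  rec <- data.frame(node_id = c(13, 51, 2), n_t = c(18, 3, 150),
                    R_c = c(13.4, 27.2, 100), R_P = c(90.88, 100, 1.75))
  out <- flag_nodes(rec, 0.95)
  expect_equal(out$classification_unreliable, c(TRUE, TRUE, FALSE))
  expect_equal(out$prediction_unreliable, c(FALSE, TRUE, FALSE))
  expect_equal(out$tiny_node, c(FALSE, FALSE, FALSE))
})

test_that("bootstrap matrices are deterministic and well-formed", {
  fit <- small_fit(200, seed = 19)
  M1 <- bootstrap_node_probabilities(fit$tree, fit$train, fit$test, B = 3,
                                     seed = 101, folds = 5)
  M2 <- bootstrap_node_probabilities(fit$tree, fit$train, fit$test, B = 3,
                                     seed = 101, folds = 5)
  expect_identical(M1, M2)
  expect_true(all(is.na(M1) | (M1 >= 0 & M1 <= 1)))
  expect_equal(sum(attr(M1, "n_t")), nrow(fit$test))
  expect_error(bootstrap_node_probabilities(fit$tree, fit$train, fit$test,
                                            B = 1), "B must")
  expect_error(bootstrap_node_probabilities(fit$tree, fit$train,
                                            fit$test[0, ], B = 2), "empty")
})

test_that("separable data gives near-degenerate replicate probabilities", {
  fit <- small_fit(400, seed = 25)
  nr <- node_reliability(fit$tree, fit$train, fit$test, B = 20, seed = 77,
                         folds = 5)
  rec <- nr$records
  M <- nr$matrix
  for (i in which(rec$n_t >= 10)) {
    # refit cutoffs drift by a few boundary rows at most (1/n_t granularity):
    # replicates stay near the planted risk and the classification is
    # stable — perfectly so once a node holds a couple dozen test rows
    planted <- round(rec$P_hat[i])
    if (rec$n_t[i] >= 20) {
      expect_gte(mean(abs(M[i, ] - planted) <= 0.2), 0.95)
      expect_equal(rec$R_c[i], 100)
    } else {
      expect_gte(rec$R_c[i], 95)
    }
  }
})

test_that("the reliability report writes a faithful CSV twin", {
  fit <- small_fit(200, seed = 29)
  nr <- node_reliability(fit$tree, fit$train, fit$test, B = 2, seed = 5,
                         folds = 5)
  path <- tempfile(fileext = ".csv")
  write_reliability(nr, path)
  back <- read.csv(path)
  expect_equal(back$node_id, nr$records$node_id)
  expect_equal(back$R_c_pct, round_half_up(nr$records$R_c, 2))
  jpath <- tempfile(fileext = ".json")
  write_reliability(nr, jpath)
  expect_equal(length(jsonlite::read_json(jpath)), nrow(nr$records))
})
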