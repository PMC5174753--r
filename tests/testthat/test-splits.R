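test_that("quartile binning produces balanced right-closed bins", {
  b <- bin_continuous(1:8)
  expect_equal(as.vector(table(b)), c(2, 2, 2, 2))
  expect_equal(nlevels(bin_continuous(rep(3, 10))), 1)
  expect_equal(nlevels(bin_continuous(c(1, 1, 2, 5, 5))), 3)
  set.seed(1)
  sizes <- as.vector(table(bin_continuous(runif(100))))
  expect_true(all(abs(sizes - 25) <= 1))
  expect_error(bin_continuous(numeric(0)), "empty")
})

test_that("curvature test detects association and is exact on 2x2 tables", {
  y <- rep(0:1, each = 100)
  expect_lt(curvature_test(factor(y), y), 1e-20)
  # (50,0;0,50) has Pearson statistic 100 on 1 df
  x <- factor(rep(c("a", "b"), each = 50))
  y2 <- rep(c(0, 1), each = 50)
  expect_equal(curvature_test(x, y2), pchisq(100, 1, lower.tail = FALSE))
  expect_error(curvature_test(runif(10), rep(1, 10)), "pure node")
  expect_true(is.na(curvature_test(rep(2, 20), rep(0:1, 10))))
})

test_that("curvature test holds its nominal type-I error", {
  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    x <- sample(letters[1:4], 200, replace = TRUE)
    y <- rbinom(200, 1, 0.5)
    curvature_test(factor(x), y) < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("interaction test flags a pure interaction the main effects miss", {
  res <- t(vapply(1:100, function(s) {
    set.seed(s)
    xi <- runif(400); xj <- runif(400)
    y <- as.integer((xi > 0.5) != (xj > 0.5))
    c(inter = interaction_test(xi, xj, y) < 0.05,
      nullmain = curvature_test(xi, y) > 0.05 && curvature_test(xj, y) > 0.05)
  }, c(TRUE, TRUE)))
  expect_gte(mean(res[, "inter"]), 0.95)
  # each marginal null test clears 0.05 w.p. ~0.95, so the pair does ~0.90;
  # 0.80 is three binomial Sds below that
  expect_gte(mean(res[, "nullmain"]), 0.80)
  # identical perfectly-predictive pair
  y <- rep(0:1, each = 100)
  expect_lt(interaction_test(y, y, y), 1e-20)
  # independence: corrected rejections at most nominal-ish
  rej <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    min(1, interaction_test(runif(150), runif(150), rbinom(150, 1, 0.4))) < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.10)
})

test_that("cost-weighted Gini matches its closed form", {
  expect_equal(cost_weighted_gini(10, 10, cost_spec(1, 1)), 0.5)
  expect_equal(cost_weighted_gini(10, 5, cost_spec(1, 2)), 0.5)
  expect_equal(cost_weighted_gini(7, 0), 0)
  expect_error(cost_weighted_gini(0, 0), "zero")
})

test_that("node class assignment follows the expected-cost threshold", {
  expect_equal(assign_node_class(0.6, cost_spec(1, 1)), 1L)
  expect_equal(assign_node_class(0.5, cost_spec(1, 1)), 0L)   # boundary
  expect_equal(assign_node_class(0.4, cost_spec(1, 2)), 1L)   # k = 1/3
  expect_equal(cost_spec(1, 2)$threshold_k, 1 / 3)
  expect_error(cost_spec(0, 1), "positive")
})

test_that("best univariate split separates a step function exactly", {
  x <- 1:6
  y <- as.integer(x > 3)
  s <- best_univariate_split(x, y, min_leaf = 3)
  expect_equal(s$rule$cutoff, 3.5)
  expect_equal(s$reduction, 0.5)      # the whole parent Gini
  expect_null(best_univariate_split(runif(9), rbinom(9, 1, 0.5), min_leaf = 5))
})

test_that("split search agrees with exhaustive enumeration", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(10:40, 1)
    costs <- cost_spec(1, sample(c(1, 2, 3), 1))
    x <- switch(sample(3, 1),
                rnorm(n),
                sample(1:5, n, replace = TRUE),
                factor(sample(letters[1:4], n, replace = TRUE)))
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    got <- best_univariate_split(x, y, costs, min_leaf = 2)
    want <- bf_best_split(x, y, costs, min_leaf = 2)
    expect_equal(is.null(got), is.null(want))
    if (is.null(got)) next
    expect_equal(got$reduction, want$reduction, tolerance = 1e-10)
    if (got$rule$type == "numeric" && is.numeric(x) && !is.factor(x))
      expect_equal(got$rule$cutoff, want$cutoff)
  }
})

test_that("linear split recovers a planted oblique boundary", {
  set.seed(42)
  xi <- runif(300, 0, 10); xj <- runif(300, 0, 10)
  y <- as.integer(0.5 * xi + xj > 10)
  s <- best_linear_split(xi, xj, y, coef_grid = c(0.1, 0.5, 1, 2))
  expect_equal(s$rule$a, 0.5)
  gap <- max(diff(sort(0.5 * xi + xj)))
  expect_lt(abs(s$rule$cutoff - 10), gap + 1e-9)
  # single direction a = 0 degenerates to a univariate split on x_j
  s0 <- best_linear_split(xi, xj, y, coef_grid = 0)
  u <- best_univariate_split(xj, y)
  expect_equal(s0$rule$cutoff, u$rule$cutoff)
  expect_equal(s0$reduction, u$reduction)
  expect_error(best_linear_split(xi, rep(1, 300), y), "non-constant")
})

test_that("two-level search picks the more informative orientation", {
  # XOR: both orientations give four pure grandchildren; tie keeps x_i
  set.seed(8)
  xi <- runif(400); xj <- runif(400)
  y <- as.integer((xi > 0.5) != (xj > 0.5))
  s <- two_level_interaction_split(xi, xj, y)
  expect_equal(s$first, "x_i")
  expect_lt(abs(s$rule$cutoff - 0.5), 0.1)
  # x_j pure given the x_i split: orientation (x_i then x_j) must win
  xi2 <- rep(c(0, 1), each = 50)
  xj2 <- runif(100)
  y2 <- as.integer(xi2 == 1 & xj2 > 0.5)
  s2 <- two_level_interaction_split(xi2, xj2, y2)
  expect_equal(s2$first, "x_i")
  expect_equal(s2$rule$cutoff, 0.5)
})

test_that("variable selection favours the planted root variable", {
  bmi <- vapply(1:50, function(s) {
    co <- generate_cohort(nafld_schema(), default_scenario(seed = s))
    sel <- select_split_variable(co[setdiff(names(co), "NAFLD")], co$NAFLD)
    if (sel$type == "single") sel$var else sel$vars[1]
  }, "")
  expect_gte(mean(bmi == "BMI"), 0.9)
  # single non-constant predictor
  set.seed(2)
  d <- data.frame(only = rnorm(50), flat = rep(1, 50))
  expect_equal(select_split_variable(d, rbinom(50, 1, 0.5))$var, "only")
  # a pure interaction selects the pair
  sel <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(xi = runif(400), xj = runif(400))
    y <- as.integer((d$xi > 0.5) != (d$xj > 0.5))
    select_split_variable(d, y)$type
  }, "")
  expect_true(all(sel == "pair"))
})

test_that("selection is unbiased between few- and many-valued predictors", {
  pick <- vapply(1:500, function(s) {
    set.seed(s)
    d <- data.frame(v2 = factor(sample(letters[1:2], 500, TRUE)),
                    v20 = factor(sample(paste0("l", 1:20), 500, TRUE)))
    select_split_variable(d, rbinom(500, 1, 0.5),
                          control = tree_control(do_interaction = FALSE))$var
  }, "")
  expect_lt(abs(mean(pick == "v2") - mean(pick == "v20")), 0.10)
})
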