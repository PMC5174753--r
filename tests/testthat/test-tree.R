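test_that("noise-free planted data is classified perfectly", {
  co <- generate_cohort(nafld_schema(), separable_scenario(600, seed = 3))
  # unit leaves let the tree isolate every planted region exactly
  tree <- grow_tree(co, "NAFLD",
                    control = tree_control(min_split = 2, min_leaf = 1))
  routed <- predict_route(tree, co)
  expect_equal(sum(routed$class != co$NAFLD), 0)
  # at the reported minimum node sizes a handful of boundary rows may be
  # stranded by the min-leaf feasibility constraint, nothing more
  tree5 <- grow_tree(co, "NAFLD")
  expect_lte(sum(predict_route(tree5, co)$class != co$NAFLD), 0.005 * 600)
})

test_that("growth respects node-size limits and the id scheme", {
  fit <- small_fit(400, seed = 21)
  nd <- fit$tree$nodes
  expect_true(all(nd$n0[nd$leaf] + nd$n1[nd$leaf] >= 5))
  # internal nodes have exactly the children 2t and 2t+1
  for (id in nd$id[!nd$leaf])
    expect_true(all(c(2 * id, 2 * id + 1) %in% nd$id))
  for (id in nd$id[nd$id > 1])
    expect_true((id %/% 2) %in% nd$id)
  # routing the training rows recovers the stored node counts
  routed <- predict_route(fit$tree, fit$train)
  for (i in which(nd$leaf))
    expect_equal(sum(routed$node == nd$id[i]), nd$n0[i] + nd$n1[i])
})

test_that("an unsplittable node yields the cost-weighted majority stump", {
  co <- generate_cohort(nafld_schema(),
                        default_scenario(n_subjects = 200, seed = 13))
  stump <- grow_tree(co, "NAFLD", cost_spec(1, 2),
                     tree_control(min_split = 10000))
  expect_equal(nrow(stump$nodes), 1)
  p <- mean(co$NAFLD)
  expect_equal(stump$nodes$pred, assign_node_class(p, cost_spec(1, 2)))
})

test_that("routing conventions: empty input, left on satisfied, unseen level", {
  fit <- small_fit(300, seed = 5)
  empty <- predict_route(fit$tree, fit$train[0, ])
  expect_equal(nrow(empty), 0)
  nd <- fit$tree$nodes
  root <- nd[nd$id == 1, ]
  if (!root$leaf && root$type == 1) {
    vn <- fit$tree$var_info$names[root$v1]
    x <- fit$train[[vn]]
    xv <- if (is.factor(x)) as.integer(x) else x
    routed <- predict_route(fit$tree, fit$train)
    sat <- xv <= root$cut
    # rows satisfying the root rule land in the subtree of node 2
    sub2 <- routed$node[sat]
    expect_true(all(floor(sub2 / 2^(floor(log2(sub2)) - 1)) == 2))
  }
  # unseen factor level routes right with a warning
  row1 <- fit$train[1, ]
  levels(row1$SEX) <- c(levels(row1$SEX), "zzz")
  row1$SEX <- factor("zzz", levels = levels(row1$SEX))
  expect_warning(predict_route(fit$tree, row1), "unseen")
})

test_that("raising the false-negative cost monotonically expands positives", {
  co <- generate_cohort(nafld_schema(), default_scenario(1000, seed = 17))
  tree <- grow_tree(co, "NAFLD")
  prev_pos <- NULL
  prev_sens <- -1
  prev_k <- Inf
  for (cfn in c(1, 1.5, 2, 4)) {
    relab <- update_costs(tree, cost_spec(1, cfn))
    expect_lt(relab$costs$threshold_k, prev_k)
    prev_k <- relab$costs$threshold_k
    pos <- which(predict_route(relab, co)$class == 1)
    if (!is.null(prev_pos)) expect_true(all(prev_pos %in% pos))
    prev_pos <- pos
    sens <- classification_metrics(
      contingency(co$NAFLD, predict_route(relab, co)$class))$sensitivity
    expect_gte(sens, prev_sens)
    prev_sens <- sens
  }
})

test_that("the engine's root split matches the R-level operations", {
  ctl <- tree_control(min_split = 10, min_leaf = 3, max_depth = 1,
                      do_linear = FALSE)
  for (s in 1:50) {
    set.seed(s)
    n <- 60
    d <- data.frame(
      c1 = rnorm(n), c2 = runif(n),
      f1 = factor(sample(letters[1:3], n, replace = TRUE)),
      o1 = factor(sample(c("lo", "mid", "hi"), n, replace = TRUE),
                  levels = c("lo", "mid", "hi"), ordered = TRUE))
    d$NAFLD <- rbinom(n, 1, plogis(d$c1 + (d$f1 == "a")))
    if (length(unique(d$NAFLD)) < 2) next
    tree <- grow_tree(d, "NAFLD", control = ctl)
    nd <- tree$nodes[tree$nodes$id == 1, ]
    if (nd$leaf) next
    sel <- select_split_variable(d[1:4], d$NAFLD, cost_spec(),
                                 tree_control(do_linear = FALSE))
    if (sel$type == "single") {
      expect_equal(tree$var_info$names[nd$v1], sel$var)
      ref <- best_univariate_split(d[[sel$var]], d$NAFLD, min_leaf = 3)
      if (nd$type == 1) expect_equal(nd$cut, ref$rule$cutoff)
      else expect_equal(
        tree$var_info$levels[[nd$v1]][tree$subsets[[which(tree$nodes$id == 1)]]],
        ref$rule$levels)
    } else {
      ref <- two_level_interaction_split(d[[sel$vars[1]]], d[[sel$vars[2]]],
                                         d$NAFLD, min_leaf = 3)
      picked <- if (ref$first == "x_i") sel$vars[1] else sel$vars[2]
      expect_equal(tree$var_info$names[nd$v1], picked)
      if (nd$type == 1) expect_equal(nd$cut, ref$rule$cutoff)
    }
  }
})

test_that("a planted oblique boundary is found by a linear root split", {
  set.seed(31)
  n <- 500
  d <- data.frame(u = runif(n, 0, 10), v = runif(n, 0, 10))
  d$NAFLD <- as.integer(0.5 * d$u + d$v > 10)
  tree <- grow_tree(d, "NAFLD", control = tree_control(do_interaction = FALSE))
  root <- tree$nodes[tree$nodes$id == 1, ]
  expect_equal(root$type, 3)
  # the second variable (by curvature p-value) carries coefficient 1, so
  # normalise the fitted boundary a*x_v1 + x_v2 <= c onto (0.5 u + v, 10)
  if (tree$var_info$names[root$v1] == "u") {
    cu <- root$a; cv <- 1
  } else {
    cu <- 1; cv <- root$a
  }
  expect_lt(abs(cu / cv - 0.5), 0.15)
  expect_lt(abs(root$cut / cv - 10), 1)
  expect_equal(sum(predict_route(tree, d)$class != d$NAFLD), 0)
})

test_that("growth rejects malformed inputs", {
  d <- data.frame(x = 1:10, NAFLD = rep(0:1, 5))
  expect_error(grow_tree(d[0, ], "NAFLD"), "empty")
  expect_error(grow_tree(d, "missing_outcome"), "not found")
  d2 <- d; d2$x[3] <- NA
  expect_error(grow_tree(d2, "NAFLD"), "missing")
  d3 <- d; d3$NAFLD <- d3$NAFLD + 1
  expect_error(grow_tree(d3, "NAFLD"), "0/1")
})
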