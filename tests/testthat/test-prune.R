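test_that("pruning recovers the compact planted tree on noise-free data", {
  co <- generate_cohort(nafld_schema(), separable_scenario(800, seed = 2))
  tree <- grow_tree(co, "NAFLD")
  pruned <- cv_prune(tree, co, seed = 4)
  routed <- predict_route(pruned, co)
  # min-leaf feasibility can strand at most a few boundary rows
  expect_lte(sum(routed$class != co$NAFLD), 0.005 * 800)
  # the planted mechanism needs between 4 and 8 leaves as a binary tree
  expect_gte(n_leaves(pruned), 4)
  expect_lte(n_leaves(pruned), 8)
  expect_lte(n_leaves(pruned), n_leaves(tree))
})

test_that("pure-noise outcomes prune back to the root", {
  root <- vapply(1:50, function(s) {
    set.seed(s)
    d <- data.frame(a = runif(300), b = runif(300), c = runif(300),
                    NAFLD = rbinom(300, 1, 0.3))
    n_leaves(cv_prune(grow_tree(d, "NAFLD"), d, seed = s + 1000)) == 1
  }, TRUE)
  expect_gte(mean(root), 0.8)
})

test_that("the chosen subtree minimises the cross-validated cost", {
  fit <- small_fit(500, seed = 9)
  tab <- fit$tree$cv$table
  expect_false(is.null(tab))
  chosen <- tab$cv_cost[tab$alpha == fit$tree$cv$alpha]
  expect_true(all(chosen <= tab$cv_cost + 1e-9))
  # in particular no worse than keeping the full tree
  expect_lte(chosen, tab$cv_cost[1])
})

test_that("the pruning sequence is nested with non-decreasing alphas", {
  co <- generate_cohort(nafld_schema(),
                        default_scenario(n_subjects = 500, seed = 23))
  tree <- grow_tree(co, "NAFLD")
  steps <- prune_sequence(tree)
  al <- vapply(steps, `[[`, 0, "alpha")
  expect_true(all(diff(al) >= -1e-12))
  sizes <- vapply(steps, `[[`, 0L, "size")
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[1], n_leaves(tree))
  expect_equal(sizes[length(sizes)], 1L)
  # leaves of each step are a partition boundary: every deeper leaf has an
  # ancestor (or itself) in the next step's leaf set
  for (k in seq_len(length(steps) - 1)) {
    for (id in steps[[k]]$leaf_ids) {
      anc <- id
      while (anc > 1 && !(anc %in% steps[[k + 1]]$leaf_ids))
        anc <- anc %/% 2
      expect_true(anc %in% steps[[k + 1]]$leaf_ids)
    }
  }
})

test_that("fold counts are validated", {
  fit <- small_fit(200, seed = 3)
  expect_error(cv_prune(fit$tree, fit$train, folds = 1), "folds")
  expect_error(cv_prune(fit$tree, fit$train, folds = 10000), "folds")
})
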