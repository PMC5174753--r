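# Shared fixtures and independent oracles for the test suite.

# Exhaustive split enumeration: the independent oracle for the split search.
# Evaluates every candidate cutoff (numeric) or every proper level subset
# (nominal) directly from the impurity definition.
bf_gini <- function(w0, w1) if (w0 + w1 <= 0) 0 else 2 * w0 * w1 / (w0 + w1)^2

bf_reduction <- function(left, y, w) {
  W <- sum(w)
  gp <- bf_gini(sum(w[y == 0]), sum(w[y == 1]))
  gl <- bf_gini(sum(w[left & y == 0]), sum(w[left & y == 1]))
  gr <- bf_gini(sum(w[!left & y == 0]), sum(w[!left & y == 1]))
  gp - sum(w[left]) / W * gl - sum(w[!left]) / W * gr
}

bf_best_split <- function(x, y, costs, min_leaf) {
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  best <- NULL
  if (is.numeric(x) && !is.factor(x)) {
    u <- sort(unique(x))
    if (length(u) < 2) return(NULL)
    for (cut in (head(u, -1) + tail(u, -1)) / 2) {
      left <- x <= cut
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      red <- bf_reduction(left, y, w)
      if (is.null(best) || red > best$reduction + 1e-12)
        best <- list(cutoff = cut, reduction = red)
    }
  } else {
    lev <- levels(factor(x))[table(factor(x)) > 0]
    if (length(lev) < 2) return(NULL)
    for (mask in 1:(2^length(lev) - 2)) {   # every proper nonempty subset
      S <- lev[bitwAnd(mask, 2^(seq_along(lev) - 1)) > 0]
      left <- as.character(x) %in% S
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      red <- bf_reduction(left, y, w)
      if (is.null(best) || red > best$reduction + 1e-12)
        best <- list(levels = S, reduction = red)
    }
  }
  best
}

# small separable scenario: deterministic planted risks in {0, 1}, so the
# planted tree classifies the training data perfectly
separable_scenario <- function(n = 600, seed = 1) {
  default_scenario(
    n_subjects = n, seed = seed,
    planted_rules = list(
      list(when = 'BMI %in% c("UW", "N")',  risk = 0),
      list(when = 'WHR > 0.9 & ALT > 17.5', risk = 1),
      list(when = 'TG > 247.5',             risk = 1),
      list(when = 'TRUE',                   risk = 0)))
}

# a tiny fitted tree plus its split, reused by routing/reliability tests
small_fit <- function(n = 300, seed = 7, costs = cost_spec()) {
  co <- generate_cohort(nafld_schema(), separable_scenario(n, seed))
  sp <- split_train_test(co, 0.7, seed = seed + 1)
  tree <- cv_prune(grow_tree(sp$train, "NAFLD", costs), sp$train,
                   seed = seed + 2)
  list(tree = tree, train = sp$train, test = sp$test)
}
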