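# Node-level operations of the split search, exposed as plain R functions.
# They mirror the C++ engine exactly (binning, tie rules, weighting), and the
# test suite cross-checks the engine against them and against brute-force
# enumeration.

#' Bin a continuous vector at its empirical quartiles
#'
#' Produces at most four bins with breaks at the first, second and third
#' empirical quartiles; boundary values fall in the lower bin.  With fewer
#' than four distinct values, each distinct value gets its own bin.
#'
#' @param values numeric vector (non-empty).
#' @return A factor with levels `"B1"`, `"B2"`, ...
#' @export
bin_continuous <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  u <- sort(unique(values))
  if (length(u) < 4) {
    bin <- match(values, u)
    nb <- length(u)
  } else {
    breaks <- unique(quantile(values, c(0.25, 0.5, 0.75), type = 7,
                              names = FALSE))
    bin <- rowSums(outer(values, breaks, ">")) + 1L
    nb <- length(breaks) + 1L
  }
  factor(paste0("B", bin), levels = paste0("B", seq_len(nb)))
}

# weighted Pearson chi-squared p-value of a bins x class table; zero-margin
# rows/columns are dropped from the degrees of freedom
.chisq_p <- function(t0, t1) {
  rt <- t0 + t1
  c0 <- sum(t0); c1 <- sum(t1); N <- c0 + c1
  df <- (sum(rt > 0) - 1) * ((c0 > 0) + (c1 > 0) - 1)
  if (df < 1 || N <= 0) return(NA_real_)
  e0 <- rt * c0 / N; e1 <- rt * c1 / N
  stat <- sum(((t0 - e0)^2 / e0)[e0 > 0]) + sum(((t1 - e1)^2 / e1)[e1 > 0])
  pchisq(stat, df, lower.tail = FALSE)
}

.as_bins <- function(x) {
  if (is.numeric(x) && !is.factor(x)) bin_continuous(x) else factor(x)
}

#' Curvature (main-effect) test of one predictor
#'
#' Pearson chi-squared test of independence between the (quartile-binned)
#' predictor and the binary outcome on the cost-weighted contingency table.
#' This is the unbiased split-variable screen: every predictor is reduced to
#' at most four categories before testing, so variables with many values get
#' no selection advantage.
#'
#' @param x predictor column (numeric or factor); ordinal factors keep their
#'   levels as bins.
#' @param y binary 0/1 outcome.
#' @param weights per-row cost weights (default 1).
#' @return The p-value, or `NA` when no test is computable (constant
#'   predictor).
#' @export
curvature_test <- function(x, y, weights = NULL) {
  if (length(unique(y)) < 2)
    stop("pure node: curvature test undefined", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))
  b <- .as_bins(x)
  t0 <- vapply(levels(b), function(l) sum(weights[b == l & y == 0]), 0)
  t1 <- vapply(levels(b), function(l) sum(weights[b == l & y == 1]), 0)
  .chisq_p(t0, t1)
}

# coarse two-level binning for interaction tests; NULL when degenerate.
# Numeric and ordinal variables are cut at the node median, nominal ones
# grouped by class share.
.coarse_bin <- function(x, y, weights) {
  if ((is.numeric(x) && !is.factor(x)) || is.ordered(x)) {
    xv <- if (is.factor(x)) as.integer(x) else x
    med <- quantile(xv, 0.5, type = 7, names = FALSE)
    b <- as.integer(xv > med)
  } else {
    x <- factor(x)
    if (nlevels(x) == 2) {
      b <- as.integer(x) - 1L
    } else {
      w1 <- vapply(levels(x), function(l) sum(weights[x == l & y == 1]), 0)
      wt <- vapply(levels(x), function(l) sum(weights[x == l]), 0)
      pl <- ifelse(wt > 0, w1 / wt, 0)
      pnode <- sum(weights[y == 1]) / sum(weights)
      b <- as.integer(pl[as.integer(x)] > pnode)
    }
  }
  if (length(unique(b)) < 2) return(NULL)
  b
}

#' Interaction test of a predictor pair
#'
#' Chi-squared test of the outcome against the 2 x 2 cross-classification of
#' the coarsely binned pair (median cuts for numeric predictors, class-share
#' grouping for nominal ones).  Bonferroni correction over all tested pairs
#' is applied by the caller.
#'
#' @param x_i,x_j predictor columns, non-constant at the node.
#' @param y binary 0/1 outcome.
#' @param weights per-row cost weights (default 1).
#' @return The p-value, or `NA` when a coarse binning is degenerate.
#' @export
interaction_test <- function(x_i, x_j, y, weights = NULL) {
  if (length(unique(y)) < 2)
    stop("pure node: interaction test undefined", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))
  bi <- .coarse_bin(x_i, y, weights)
  bj <- .coarse_bin(x_j, y, weights)
  if (is.null(bi) || is.null(bj)) return(NA_real_)
  cell <- bi * 2L + bj
  t0 <- vapply(0:3, function(cc) sum(weights[cell == cc & y == 0]), 0)
  t1 <- vapply(0:3, function(cc) sum(weights[cell == cc & y == 1]), 0)
  .chisq_p(t0, t1)
}

#' Cost-weighted Gini impurity
#'
#' With class weights `w1 = n1 * cost_fn` and `w0 = n0 * cost_fp`, the
#' impurity is `2 w0 w1 / (w0 + w1)^2` — the ordinary Gini index of the
#' weighted class shares.
#'
#' @param n0,n1 per-class counts at the node (non-negative, not both zero).
#' @param costs a [cost_spec()].
#' @return The impurity in `[0, 0.5]`.
#' @export
cost_weighted_gini <- function(n0, n1, costs = cost_spec()) {
  if (n0 < 0 || n1 < 0 || n0 + n1 == 0)
    stop("counts must be non-negative and not all zero", call. = FALSE)
  w0 <- n0 * costs$cost_fp
  w1 <- n1 * costs$cost_fn
  2 * w0 * w1 / (w0 + w1)^2
}

.gini_w <- function(w0, w1) {
  W <- w0 + w1
  if (W <= 0) return(0)
  2 * w0 * w1 / W^2
}

# shared threshold scan used by numeric and linear splits; `v` is the score,
# feasibility in raw counts; ties keep the smallest cutoff
.scan_threshold <- function(v, y, w, min_leaf) {
  n <- length(v)
  o <- order(v)
  vs <- v[o]; ys <- y[o]; ws <- w[o]
  W1 <- sum(ws[ys == 1]); W0 <- sum(ws) - W1
  W <- W0 + W1
  gp <- .gini_w(W0, W1)
  lw0 <- 0; lw1 <- 0
  best <- -1; cut <- NA_real_
  for (i in seq_len(n - 1)) {
    if (ys[i] == 1) lw1 <- lw1 + ws[i] else lw0 <- lw0 + ws[i]
    if (vs[i] == vs[i + 1]) next
    if (i < min_leaf || (n - i) < min_leaf) next
    g <- (lw0 + lw1) / W * .gini_w(lw0, lw1) +
      (W0 - lw0 + W1 - lw1) / W * .gini_w(W0 - lw0, W1 - lw1)
    if (gp - g > best + 1e-12) {
      best <- gp - g
      cut <- (vs[i] + vs[i + 1]) / 2
    }
  }
  if (is.na(cut)) NULL else list(cutoff = cut, reduction = best)
}

#' Best univariate split of one variable
#'
#' Numeric (and ordinal) variables are scanned over midpoints between
#' consecutive distinct sorted values; categorical variables over level
#' subsets ordered by weighted class-1 share (at most L-1 candidates).  The
#' returned rule maximises the decrease in cost-weighted Gini impurity
#' subject to both children holding at least `min_leaf` rows; ties keep the
#' smallest cutoff / first subset in scan order.
#'
#' @param x predictor column.
#' @param y binary 0/1 outcome.
#' @param costs a [cost_spec()] (class weights).
#' @param min_leaf minimum rows per child.
#' @return `list(rule = , reduction = )` where `rule` has `type`
#'   (`"numeric"` or `"subset"`) and `cutoff` or `levels`; `NULL` when no
#'   feasible split exists.
#' @export
best_univariate_split <- function(x, y, costs = cost_spec(), min_leaf = 5) {
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  if (is.numeric(x) && !is.factor(x)) {
    sc <- .scan_threshold(x, y, w, min_leaf)
    if (is.null(sc)) return(NULL)
    return(list(rule = list(type = "numeric", cutoff = sc$cutoff),
                reduction = sc$reduction))
  }
  x <- factor(x)
  if (is.ordered(x)) {
    sc <- .scan_threshold(as.integer(x), y, w, min_leaf)
    if (is.null(sc)) return(NULL)
    return(list(rule = list(type = "numeric", cutoff = sc$cutoff),
                reduction = sc$reduction))
  }
  lv <- levels(x)[tabulate(x, nlevels(x)) > 0]
  if (length(lv) < 2) return(NULL)
  lw0 <- vapply(lv, function(l) sum(w[x == l & y == 0]), 0)
  lw1 <- vapply(lv, function(l) sum(w[x == l & y == 1]), 0)
  ln <- vapply(lv, function(l) sum(x == l), 0)
  o <- order(lw1 / (lw0 + lw1), seq_along(lv))
  W0 <- sum(lw0); W1 <- sum(lw1); W <- W0 + W1
  gp <- .gini_w(W0, W1)
  aw0 <- 0; aw1 <- 0; an <- 0
  best <- -1; bk <- NA_integer_
  for (k in seq_len(length(lv) - 1)) {
    aw0 <- aw0 + lw0[o[k]]; aw1 <- aw1 + lw1[o[k]]; an <- an + ln[o[k]]
    if (an < min_leaf || (length(y) - an) < min_leaf) next
    g <- (aw0 + aw1) / W * .gini_w(aw0, aw1) +
      (W0 - aw0 + W1 - aw1) / W * .gini_w(W0 - aw0, W1 - aw1)
    if (gp - g > best + 1e-12) { best <- gp - g; bk <- k }
  }
  if (is.na(bk)) return(NULL)
  list(rule = list(type = "subset", levels = sort(lv[o[seq_len(bk)]])),
       reduction = unname(best))
}

#' Best bivariate linear split of two continuous variables
#'
#' Scores `a * x_i + x_j` are scanned for the best threshold over a grid of
#' directions.  By default the grid is 41 angles uniform in (-pi/2, pi/2)
#' applied to the standardised variables, back-transformed so `x_j`'s
#' coefficient is 1; a raw coefficient grid can be supplied instead.
#'
#' @param x_i,x_j continuous predictor columns, both non-constant.
#' @param y binary 0/1 outcome.
#' @param costs a [cost_spec()].
#' @param min_leaf minimum rows per child.
#' @param coef_grid optional numeric vector of raw slopes `a` to scan.
#' @param n_angles size of the default standardised-angle grid.
#' @return `list(rule = list(type = "linear", a = , cutoff = ),
#'   reduction = )`, or `NULL` when no feasible split exists.
#' @export
best_linear_split <- function(x_i, x_j, y, costs = cost_spec(), min_leaf = 5,
                              coef_grid = NULL, n_angles = 41) {
  if (sd(x_i) == 0 || sd(x_j) == 0)
    stop("both variables must be non-constant", call. = FALSE)
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  best <- NULL
  if (is.null(coef_grid)) {
    mi <- mean(x_i); mj <- mean(x_j); si <- sd(x_i); sj <- sd(x_j)
    for (k in seq_len(n_angles)) {
      th <- -pi / 2 + k * pi / (n_angles + 1)
      t <- tan(th)
      sc <- .scan_threshold(t * (x_i - mi) / si + (x_j - mj) / sj, y, w,
                            min_leaf)
      if (!is.null(sc) &&
          (is.null(best) || sc$reduction > best$reduction + 1e-12)) {
        a <- t * sj / si
        best <- list(rule = list(type = "linear", a = a,
                                 cutoff = sj * sc$cutoff + a * mi + mj),
                     reduction = sc$reduction)
      }
    }
  } else {
    for (a in coef_grid) {
      sc <- .scan_threshold(a * x_i + x_j, y, w, min_leaf)
      if (!is.null(sc) &&
          (is.null(best) || sc$reduction > best$reduction + 1e-12)) {
        best <- list(rule = list(type = "linear", a = a, cutoff = sc$cutoff),
                     reduction = sc$reduction)
      }
    }
  }
  best
}

# parent-normalised total impurity of splitting on `rule_x` then optimally
# splitting each child on variable b
.two_level_total <- function(split_x, x, b_col, y, costs, min_leaf) {
  left <- if (split_x$rule$type == "numeric") {
    (if (is.factor(x)) as.integer(x) else x) <= split_x$rule$cutoff
  } else {
    as.character(x) %in% split_x$rule$levels
  }
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  W <- sum(w)
  tot <- 0
  for (side in list(left, !left)) {
    wc0 <- sum(w[side & y == 0]); wc1 <- sum(w[side & y == 1])
    imp <- .gini_w(wc0, wc1)
    if (sum(side) >= 2 * min_leaf) {
      cs <- best_univariate_split(b_col[side], y[side], costs, min_leaf)
      if (!is.null(cs)) imp <- imp - cs$reduction
    }
    tot <- tot + (wc0 + wc1) / W * imp
  }
  tot
}

# best top-level split on x judged by two-level total impurity; candidates
# are decile cutoffs (balanced first) plus the marginal-best rule
.two_level_top <- function(x, b_col, y, costs, min_leaf) {
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  mb <- best_univariate_split(x, y, costs, min_leaf)
  # balanced (median) candidates matter when the marginal is flat (a pure
  # interaction); a strong marginal cut is the two-level answer already
  flat <- is.null(mb) ||
    mb$reduction < 0.1 * .gini_w(sum(w[y == 0]), sum(w[y == 1]))
  cands <- list()
  if (flat && ((is.numeric(x) && !is.factor(x)) || is.ordered(x))) {
    xv <- if (is.factor(x)) as.integer(x) else x
    qs <- unique(quantile(xv, 0.5, type = 7, names = FALSE))
    for (q in qs) {
      nl <- sum(xv <= q)
      if (nl >= min_leaf && length(xv) - nl >= min_leaf)
        cands <- c(cands, list(list(type = "numeric", cutoff = q)))
    }
  }
  if (!is.null(mb)) cands <- c(cands, list(mb$rule))
  best <- NULL; best_total <- Inf
  for (rule in cands) {
    tot <- .two_level_total(list(rule = rule), x, b_col, y, costs, min_leaf)
    if (tot < best_total - 1e-12) {
      best_total <- tot
      left <- if (rule$type == "numeric") {
        (if (is.factor(x)) as.integer(x) else x) <= rule$cutoff
      } else as.character(x) %in% rule$levels
      W <- sum(w)
      red <- .gini_w(sum(w[y == 0]), sum(w[y == 1])) -
        sum(w[left]) / W * .gini_w(sum(w[left & y == 0]),
                                   sum(w[left & y == 1])) -
        sum(w[!left]) / W * .gini_w(sum(w[!left & y == 0]),
                                    sum(w[!left & y == 1]))
      best <- list(rule = rule, reduction = red)
    }
  }
  list(best = best, total = best_total)
}

#' Two-level interaction split
#'
#' For a pair flagged by the interaction test: split the node on `x_i` and
#' each child optimally on `x_j`, compute the total impurity of the
#' resulting partition, do the same with the roles reversed, and return the
#' top-level rule of the better orientation (ties keep `x_i`).  Because a
#' pure interaction leaves the marginal impurity of the top variable flat,
#' candidate top-level cutoffs include the node deciles (most balanced
#' first) besides the marginal-best rule.  When neither orientation admits
#' a feasible top-level split the pair yields no rule.
#'
#' @param x_i,x_j the flagged predictor pair.
#' @param y binary 0/1 outcome.
#' @param costs a [cost_spec()].
#' @param min_leaf minimum rows per child.
#' @return `list(first = "x_i"|"x_j", rule = , reduction = )`, or `NULL`.
#' @export
two_level_interaction_split <- function(x_i, x_j, y, costs = cost_spec(),
                                        min_leaf = 5) {
  oi <- .two_level_top(x_i, x_j, y, costs, min_leaf)
  oj <- .two_level_top(x_j, x_i, y, costs, min_leaf)
  if (!is.null(oi$best) && (is.null(oj$best) || oi$total <= oj$total + 1e-12))
    return(list(first = "x_i", rule = oi$best$rule,
                reduction = oi$best$reduction))
  if (!is.null(oj$best))
    return(list(first = "x_j", rule = oj$best$rule,
                reduction = oj$best$reduction))
  NULL
}

#' Select the split variable (or interacting pair) at a node
#'
#' Each predictor's curvature p-value is Bonferroni-adjusted by the number
#' of computable tests; pairs among the `interaction_top_k` strongest
#' candidates get interaction tests adjusted by the number of pairs.  The
#' smallest adjusted main-effect p-value wins unless an interaction pair's
#' adjusted p-value beats every main effect; ties break by column order.
#'
#' @param data `data.frame` of predictor columns at the node.
#' @param y binary 0/1 outcome.
#' @param costs a [cost_spec()] (class weights for the tests).
#' @param control a [tree_control()].
#' @return `list(type = "single", var = , p_adj = )` or
#'   `list(type = "pair", vars = c(, ), p_adj = )`; `NULL` when no test is
#'   computable (the node should be terminalised).
#' @export
select_split_variable <- function(data, y, costs = cost_spec(),
                                  control = tree_control()) {
  w <- ifelse(y == 1, costs$cost_fn, costs$cost_fp)
  pv <- vapply(data, function(x) curvature_test(x, y, w), 0)
  valid <- which(!is.na(pv))
  if (length(valid) == 0) return(NULL)
  m <- length(valid)
  ordv <- valid[order(pv[valid], valid)]
  main_adj <- min(1, pv[ordv[1]] * m)
  int_best <- NULL
  if (control$do_interaction && m >= 2 &&
      length(y) >= control$interaction_min_n) {
    cand <- ordv[seq_len(min(control$interaction_top_k, m))]
    npairs <- choose(length(cand), 2)
    for (ai in seq_len(length(cand) - 1)) {
      for (bi in seq(ai + 1, length(cand))) {
        i <- cand[ai]; j <- cand[bi]
        pij <- interaction_test(data[[i]], data[[j]], y, w)
        if (!is.na(pij) && (is.null(int_best) || pij < int_best$p))
          int_best <- list(p = pij, vars = c(i, j))
      }
    }
    if (!is.null(int_best)) int_best$p_adj <- min(1, int_best$p * npairs)
  }
  if (!is.null(int_best) && int_best$p_adj < main_adj) {
    vs <- int_best$vars
    # member with the smaller curvature p plays the first role
    if (pv[vs[2]] < pv[vs[1]]) vs <- rev(vs)
    return(list(type = "pair", vars = names(data)[vs],
                p_adj = int_best$p_adj))
  }
  list(type = "single", var = names(data)[ordv[1]], p_adj = main_adj)
}

#' Assign a class label from a node probability
#'
#' Expected-cost rule: label 1 iff `p_hat > k` with
#' `k = cost_fp / (cost_fp + cost_fn)`; the boundary `p_hat = k` goes to
#' class 0.
#'
#' @param p_hat class-1 proportion(s) in `[0, 1]`.
#' @param costs a [cost_spec()].
#' @return Integer 0/1 vector.
#' @export
assign_node_class <- function(p_hat, costs = cost_spec()) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1))
  as.integer(p_hat > costs$threshold_k)
}
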