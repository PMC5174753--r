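#' Misclassification cost specification
#'
#' `cost_fp` is the cost of classifying a disease-free subject as diseased
#' (a false positive) and `cost_fn` the cost of classifying a diseased
#' subject as disease-free.  The induced classification threshold is
#' `k = cost_fp / (cost_fp + cost_fn)`: a node is labelled "diseased" when
#' its class-1 proportion exceeds `k`, which minimises expected cost.  Equal
#' costs give `k = 0.5`; the 1:2 setting used for disease-sensitive trees
#' gives `k = 1/3`.
#'
#' @param cost_fp,cost_fn positive misclassification costs.
#' @return An object of class `cost_spec` with fields `cost_fp`, `cost_fn`,
#'   `threshold_k`.
#' @export
cost_spec <- function(cost_fp = 1, cost_fn = 1) {
  if (cost_fp <= 0 || cost_fn <= 0)
    stop("misclassification costs must be positive", call. = FALSE)
  structure(list(cost_fp = cost_fp, cost_fn = cost_fn,
                 threshold_k = cost_fp / (cost_fp + cost_fn)),
            class = "cost_spec")
}

#' Tree growth settings
#'
#' @param min_split minimum node size before a split is attempted.
#' @param min_leaf minimum training rows in each child.
#' @param max_depth depth cap (root has depth 0); keeps the `2t`/`2t+1` node
#'   ids inside integer range.
#' @param do_interaction run pairwise interaction tests?
#' @param interaction_top_k number of strongest main-effect variables whose
#'   pairs are screened for interactions.
#' @param interaction_min_n smallest node size at which pairs are screened
#'   (the 2 x 2 x 2 interaction table is data-starved below this).
#' @param do_linear allow bivariate linear splits?
#' @param n_angles number of direction-grid angles for linear splits.
#' @param linear_min_n smallest node size at which the linear-split
#'   direction grid is searched (an oblique boundary estimated from fewer
#'   rows is noise).
#' @param linear_preference multiplier applied to a linear split's impurity
#'   reduction when competing with the best univariate split (>1 favours
#'   linear splits, <1 penalises them).
#' @param interaction_alpha significance level below which an adjusted
#'   interaction p-value suppresses the linear-split search.
#' @return A list of class `tree_control`.
#' @export
tree_control <- function(min_split = 5, min_leaf = 5, max_depth = 30,
                         do_interaction = TRUE, interaction_top_k = 5,
                         interaction_min_n = 50,
                         do_linear = TRUE, n_angles = 41, linear_min_n = 50,
                         linear_preference = 1, interaction_alpha = 0.05) {
  stopifnot(min_split >= 2, min_leaf >= 1, max_depth >= 1, n_angles >= 1)
  structure(list(min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 do_interaction = isTRUE(do_interaction),
                 interaction_top_k = as.integer(interaction_top_k),
                 interaction_min_n = as.integer(interaction_min_n),
                 do_linear = isTRUE(do_linear),
                 n_angles = as.integer(n_angles),
                 linear_min_n = as.integer(linear_min_n),
                 linear_preference = linear_preference,
                 interaction_alpha = interaction_alpha),
            class = "tree_control")
}

# Encode a data.frame for the C++ engine: numeric columns stay numeric,
# ordered factors become ordinal level codes, unordered factors nominal
# codes.  `var_info` from a fitted tree enforces the training encoding on
# new data (unseen levels become NA and route right).
.encode_data <- function(data, outcome, var_info = NULL) {
  if (is.null(var_info)) {
    pred_names <- setdiff(names(data), outcome)
    kinds <- integer(length(pred_names))
    levels_list <- vector("list", length(pred_names))
    for (i in seq_along(pred_names)) {
      x <- data[[pred_names[i]]]
      if (is.character(x) || is.logical(x)) x <- factor(x)
      if (is.ordered(x)) { kinds[i] <- 1L; levels_list[[i]] <- levels(x) }
      else if (is.factor(x)) { kinds[i] <- 2L; levels_list[[i]] <- levels(x) }
      else if (is.numeric(x)) kinds[i] <- 0L
      else stop("unsupported predictor type in column '", pred_names[i], "'",
                call. = FALSE)
    }
    var_info <- list(names = pred_names, kinds = kinds, levels = levels_list)
  }
  n <- nrow(data)
  X <- matrix(NA_real_, n, length(var_info$names))
  unseen <- FALSE
  for (i in seq_along(var_info$names)) {
    nm <- var_info$names[i]
    if (!nm %in% names(data))
      stop("data lacks predictor column '", nm, "'", call. = FALSE)
    x <- data[[nm]]
    if (var_info$kinds[i] == 0L) {
      X[, i] <- as.numeric(x)
    } else {
      code <- match(as.character(x), var_info$levels[[i]])
      if (anyNA(code) && !anyNA(x)) unseen <- TRUE
      X[, i] <- code
    }
  }
  if (unseen)
    warning("unseen categorical level(s); affected rows route right",
            call. = FALSE)
  list(X = X, var_info = var_info,
       nlev = vapply(var_info$levels,
                     function(l) if (is.null(l)) 0L else length(l), 0L))
}

#' Grow a cost-sensitive classification tree
#'
#' Recursive growth with unbiased split-variable selection: at each node
#' every predictor gets a chi-squared curvature test (continuous predictors
#' binned at node-local quartiles), pairs of the strongest candidates get
#' Bonferroni-corrected interaction tests, and the winner is split by the
#' cutoff / level subset / bivariate linear rule maximising the decrease in
#' cost-weighted Gini impurity.  When an interaction pair wins, a two-level
#' search (split on one member, children on the other, both orientations)
#' picks the top-level rule.  Class-1 rows carry weight `cost_fn` and
#' class-0 rows `cost_fp`, so terminal labels follow the expected-cost rule
#' `p > k`.  Growth stops at pure nodes, nodes below `min_split`, or when no
#' feasible split leaves both children with `min_leaf` rows.
#'
#' @param data training `data.frame`; all non-outcome columns are
#'   predictors, with no missing values.
#' @param outcome name of the 0/1 outcome column.
#' @param costs a [cost_spec()].
#' @param control a [tree_control()].
#' @return An object of class `guide_tree` with a `nodes` table (node id in
#'   the `2t`/`2t+1` scheme, rule, per-class training counts, class-1
#'   proportion, predicted class).
#' @export
grow_tree <- function(data, outcome = "NAFLD", costs = cost_spec(),
                      control = tree_control()) {
  stopifnot(inherits(costs, "cost_spec"), inherits(control, "tree_control"))
  if (!outcome %in% names(data))
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  if (nrow(data) == 0) stop("empty training set", call. = FALSE)
  if (anyNA(data)) stop("missing values are not supported", call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  y <- as.integer(y)
  enc <- .encode_data(data, outcome)
  w <- ifelse(y == 1L, costs$cost_fn, costs$cost_fp)
  res <- grow_cpp(enc$X, y, w, enc$var_info$kinds, enc$nlev,
                  seq_len(nrow(data)), unclass(control))
  .make_tree(res, enc$var_info, outcome, costs, control)
}

.make_tree <- function(res, var_info, outcome, costs, control) {
  nodes <- data.frame(id = res$id, leaf = res$leaf == 1L, type = res$type,
                      v1 = res$v1, v2 = res$v2, a = res$a, cut = res$cut,
                      n0 = res$n0, n1 = res$n1, w0 = res$w0, w1 = res$w1,
                      pred = res$pred)
  nodes$p1 <- nodes$n1 / (nodes$n0 + nodes$n1)
  structure(list(nodes = nodes, subsets = res$left_levels,
                 var_info = var_info, outcome = outcome,
                 costs = costs, control = control),
            class = "guide_tree")
}

#' Route observations through a tree
#'
#' Each row descends from the root, going left iff it satisfies the node's
#' split condition, until it reaches a terminal node.  Rows with a
#' categorical level unseen in training route right (with a warning).
#'
#' @param tree a `guide_tree`.
#' @param rows a `data.frame` conforming to the training predictors.
#' @return `data.frame` with columns `node` (terminal node id) and `class`
#'   (the node's predicted class); zero rows in, zero rows out.
#' @export
predict_route <- function(tree, rows) {
  stopifnot(inherits(tree, "guide_tree"))
  if (nrow(rows) == 0)
    return(data.frame(node = integer(0), class = integer(0)))
  enc <- .encode_data(rows, tree$outcome, tree$var_info)
  nd <- tree$nodes
  out <- route_cpp(nd$id, as.integer(nd$leaf), nd$type, nd$v1, nd$v2,
                   nd$a, nd$cut, tree$subsets, nd$pred, enc$X)
  data.frame(node = out$node, class = out$pred)
}

#' Relabel a tree's nodes under different costs
#'
#' Keeps the grown structure but recomputes the class weights, the predicted
#' class of every node (expected-cost rule at the new threshold `k`) and the
#' stored cost specification.  Raising `cost_fn` lowers `k`, so the set of
#' nodes labelled class 1 — and hence the set of rows predicted positive —
#' can only grow.
#'
#' @param tree a `guide_tree`.
#' @param costs the new [cost_spec()].
#' @return The relabelled `guide_tree`.
#' @export
update_costs <- function(tree, costs) {
  stopifnot(inherits(tree, "guide_tree"), inherits(costs, "cost_spec"))
  tree$nodes$w0 <- tree$nodes$n0 * costs$cost_fp
  tree$nodes$w1 <- tree$nodes$n1 * costs$cost_fn
  tree$nodes$pred <- as.integer(tree$nodes$w1 > tree$nodes$w0)
  tree$costs <- costs
  tree
}

#' Number of terminal nodes
#' @param tree a `guide_tree`.
#' @return Integer count of leaves.
#' @export
n_leaves <- function(tree) sum(tree$nodes$leaf)

#' @export
print.guide_tree <- function(x, ...) {
  nd <- x$nodes
  cat("Cost-sensitive classification tree:",
      sum(!nd$leaf), "internal +", sum(nd$leaf), "terminal nodes\n")
  cat("  costs fp/fn =", x$costs$cost_fp, "/", x$costs$cost_fn,
      " (threshold k =", signif(x$costs$threshold_k, 4), ")\n")
  cat("  training rows:", nd$n0[1] + nd$n1[1],
      sprintf(" (class 1: %.1f%%)\n", 100 * nd$p1[1]))
  invisible(x)
}
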