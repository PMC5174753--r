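# Cost-complexity pruning.  Node risk is the cost-weighted training
# misclassification min(w0, w1); the weakest-link sequence collapses, at
# each step, the internal node(s) with the smallest
# g(t) = (risk(t) - risk(subtree_t)) / (leaves_t - 1).

#' Weakest-link pruning sequence of a grown tree
#'
#' @param tree a `guide_tree`.
#' @return A list of steps, each `list(alpha = , leaf_ids = , size = )`,
#'   from the full tree (`alpha = 0`) down to the root; alphas are
#'   non-decreasing and the subtrees nested.
#' @export
prune_sequence <- function(tree) {
  nd <- tree$nodes
  nn <- nrow(nd)
  pos <- integer(max(nd$id))
  pos[nd$id] <- seq_len(nn)
  depth <- floor(log2(nd$id))
  risk <- pmin(nd$w0, nd$w1)
  is_leaf <- nd$leaf
  # bottom-up subtree risk and leaf counts
  Rsub <- risk
  nl <- rep(1L, nn)
  for (i in order(depth, decreasing = TRUE)) {
    if (is_leaf[i]) next
    kl <- pos[2L * nd$id[i]]; kr <- pos[2L * nd$id[i] + 1L]
    Rsub[i] <- Rsub[kl] + Rsub[kr]
    nl[i] <- nl[kl] + nl[kr]
  }
  g <- ifelse(is_leaf, Inf, (risk - Rsub) / pmax(nl - 1L, 1L))
  alive <- rep(TRUE, nn)          # node still part of the current subtree
  leaf_now <- is_leaf
  steps <- list(list(alpha = 0, leaf_ids = sort(nd$id[leaf_now]),
                     size = sum(leaf_now)))
  desc_of <- function(i) {        # positions of strict descendants
    out <- integer(0); stack <- i
    while (length(stack)) {
      j <- stack[[1]]; stack <- stack[-1]
      if (!leaf_now[j]) {
        kids <- pos[c(2L * nd$id[j], 2L * nd$id[j] + 1L)]
        out <- c(out, kids); stack <- c(stack, kids)
      }
    }
    out
  }
  while (any(alive & !leaf_now)) {
    live <- which(alive & !leaf_now)
    amin <- min(g[live])
    coll <- live[g[live] <= amin + 1e-12]
    coll <- coll[order(depth[coll], decreasing = TRUE)]
    for (i in coll) {
      if (!alive[i] || leaf_now[i]) next
      dd <- desc_of(i)
      alive[dd] <- FALSE
      dR <- risk[i] - Rsub[i]; dn <- 1L - nl[i]
      leaf_now[i] <- TRUE
      Rsub[i] <- risk[i]; nl[i] <- 1L
      a <- nd$id[i]
      while (a > 1L) {           # update ancestors' aggregates and g
        a <- a %/% 2L
        j <- pos[a]
        Rsub[j] <- Rsub[j] + dR
        nl[j] <- nl[j] + dn
        g[j] <- (risk[j] - Rsub[j]) / max(nl[j] - 1L, 1L)
      }
    }
    steps[[length(steps) + 1L]] <-
      list(alpha = max(amin, 0), leaf_ids = sort(nd$id[alive & leaf_now]),
           size = sum(alive & leaf_now))
  }
  steps
}

# representative complexity values (geometric means of consecutive alphas)
.rep_alphas <- function(steps) {
  al <- vapply(steps, `[[`, 0, "alpha")
  k <- length(al)
  if (k == 1) return(0)
  reps <- numeric(k)
  for (i in seq_len(k - 1)) {
    reps[i] <- if (al[i] > 0) sqrt(al[i] * al[i + 1]) else al[i + 1] / 2
  }
  reps[k] <- if (al[k] > 0) 2 * al[k] else 1
  reps
}

# subtree of `tree` whose leaves are the step's leaf set
.prune_to <- function(tree, leaf_ids) {
  keep <- unique(unlist(lapply(leaf_ids, function(id) {
    path <- id
    while (id > 1) { id <- id %/% 2; path <- c(path, id) }
    path
  })))
  sel <- tree$nodes$id %in% keep
  tree$subsets <- tree$subsets[sel]
  tree$nodes <- tree$nodes[sel, , drop = FALSE]
  newleaf <- tree$nodes$id %in% leaf_ids
  tree$nodes$leaf <- newleaf
  tree$nodes$type[newleaf] <- 0L
  rownames(tree$nodes) <- NULL
  tree
}

# step index selected by a complexity value: last step with alpha <= a
.step_at <- function(steps, a) {
  al <- vapply(steps, `[[`, 0, "alpha")
  max(which(al <= a + 1e-15))
}

# Worker on pre-encoded data: grow on `rows` (indices into enc$X, possibly
# repeated, e.g. a bootstrap resample), then cross-validate the pruning
# sequence.  Fold assignment consumes the current RNG stream.
.fit_pruned_rows <- function(enc, y, w, rows, outcome, costs, control,
                             folds = 10, rule = "0se") {
  res <- grow_cpp(enc$X, y, w, enc$var_info$kinds, enc$nlev, rows,
                  unclass(control))
  tree <- .make_tree(res, enc$var_info, outcome, costs, control)
  steps <- prune_sequence(tree)
  if (length(steps) == 1) {
    tree$cv <- list(alpha = 0, table = NULL, rule = rule)
    return(tree)
  }
  reps <- .rep_alphas(steps)
  nr <- length(rows)
  fold <- integer(nr)
  for (cls in unique(y[rows])) {       # stratified fold assignment
    pos <- which(y[rows] == cls)
    fold[pos] <- sample(rep_len(seq_len(folds), length(pos)))
  }
  fold_cost <- matrix(0, folds, length(reps))
  for (f in seq_len(folds)) {
    tr <- rows[fold != f]; ho <- rows[fold == f]
    fres <- grow_cpp(enc$X, y, w, enc$var_info$kinds, enc$nlev, tr,
                     unclass(control))
    ft <- .make_tree(fres, enc$var_info, outcome, costs, control)
    fsteps <- prune_sequence(ft)
    nd <- ft$nodes
    routed <- route_cpp(nd$id, as.integer(nd$leaf), nd$type, nd$v1, nd$v2,
                        nd$a, nd$cut, ft$subsets, nd$pred,
                        enc$X[ho, , drop = FALSE])
    # ancestor chains of each held-out row's full-tree leaf as a matrix,
    # deepest first, padded with 0; the effective leaf under a pruned
    # subtree is the first chain entry lying in its leaf set
    maxd <- max(floor(log2(routed$node))) + 1L
    chainmat <- matrix(0L, length(ho), maxd)
    id <- routed$node
    for (d in seq_len(maxd)) {
      chainmat[, d] <- id
      id <- id %/% 2L
    }
    pred_by_id <- integer(max(nd$id))
    pred_by_id[nd$id] <- nd$pred
    who <- w[ho]; yho <- y[ho]
    for (ri in seq_along(reps)) {
      st <- fsteps[[.step_at(fsteps, reps[ri])]]
      hits <- matrix(chainmat %in% st$leaf_ids, nrow(chainmat))
      eff <- chainmat[cbind(seq_len(nrow(hits)), max.col(hits, "first"))]
      pr <- pred_by_id[eff]
      fold_cost[f, ri] <- sum(who[pr != yho])
    }
  }
  cv_cost <- colSums(fold_cost)
  se <- apply(fold_cost, 2, sd) * sqrt(folds)
  best <- max(which(cv_cost <= min(cv_cost) + 1e-9))  # ties -> smaller tree
  if (rule == "1se")
    best <- max(which(cv_cost <= cv_cost[best] + se[best]))
  chosen <- steps[[.step_at(steps, reps[best])]]
  out <- .prune_to(tree, chosen$leaf_ids)
  out$cv <- list(alpha = reps[best], rule = rule,
                 table = data.frame(alpha = reps,
                                    size = vapply(steps, `[[`, 0L, "size")[
                                      vapply(reps, function(a)
                                        .step_at(steps, a), 0L)],
                                    cv_cost = cv_cost, se = se))
  out
}

#' Prune a tree by cross-validated cost complexity
#'
#' Computes the weakest-link pruning sequence of the full tree (training
#' error = cost-weighted misclassification), estimates the held-out cost of
#' each complexity value by k-fold cross-validation (folds stratified by
#' outcome; each fold's tree is regrown with identical settings), and
#' returns the subtree whose complexity minimises the cross-validated cost.
#' Ties, and the optional `"1se"` rule, prefer the smaller tree.
#'
#' @param tree a `guide_tree` grown on `train`.
#' @param train the training `data.frame` the tree was grown on.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment; `NULL` uses the current
#'   RNG state.
#' @param rule `"0se"` (minimum CV cost, the default) or `"1se"` (largest
#'   complexity within one standard error of the minimum).
#' @return The pruned `guide_tree`; component `cv` records the complexity
#'   table (`alpha`, tree `size`, `cv_cost`, `se`) and the chosen value.
#' @export
cv_prune <- function(tree, train, folds = 10, seed = NULL,
                     rule = c("0se", "1se")) {
  rule <- match.arg(rule)
  stopifnot(inherits(tree, "guide_tree"))
  n <- nrow(train)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  y <- as.integer(train[[tree$outcome]])
  w <- ifelse(y == 1, tree$costs$cost_fn, tree$costs$cost_fp)
  enc <- .encode_data(train, tree$outcome, tree$var_info)
  if (!is.null(seed)) set.seed(seed)
  .fit_pruned_rows(enc, y, w, seq_len(n), tree$outcome, tree$costs,
                   tree$control, folds = folds, rule = rule)
}

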