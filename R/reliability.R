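# Bootstrap reliability of terminal nodes.  The fitted tree T defines a
# fixed partition of the test set; B bootstrap refits T_b re-predict the
# test rows of each original terminal node, giving per-node replicate
# probabilities p_b(t).  From these: the refined probability (their mean),
# the classification reliability (share of replicates agreeing with the
# node's class at threshold k), and a prediction-reliability ratio of the
# node's binomial sampling variance against a logit-shrinkage worst-case
# reference variance.

#' Reference class and proportion of each terminal node
#'
#' Routes the test set through the fitted tree and estimates, per terminal
#' node, the test count `n_t`, the observed class-1 proportion `P_hat`, and
#' the reference class `c_hat = 1{P_hat > k}` at the cost threshold `k`.
#'
#' @param tree a fitted `guide_tree`.
#' @param test test-set `data.frame`.
#' @return `data.frame` with columns `node_id`, `n_t`, `P_hat`, `c_hat`
#'   (`NA` for nodes receiving no test rows), one row per terminal node.
#' @export
estimate_node_reference <- function(tree, test) {
  ids <- sort(tree$nodes$id[tree$nodes$leaf])
  routed <- predict_route(tree, test)
  y <- as.integer(test[[tree$outcome]])
  n_t <- vapply(ids, function(t) sum(routed$node == t), 0L)
  P_hat <- vapply(ids, function(t) {
    r <- routed$node == t
    if (any(r)) mean(y[r]) else NA_real_
  }, 0)
  data.frame(node_id = ids, n_t = n_t, P_hat = P_hat,
             c_hat = ifelse(n_t > 0,
                            as.integer(P_hat > tree$costs$threshold_k),
                            NA_integer_))
}

#' Bootstrap replicate probabilities per terminal node
#'
#' For `b = 1..B`: resample the training rows with replacement (resamples
#' missing an outcome class are redrawn and counted), regrow and re-prune a
#' tree `T_b` with the settings of the original fit, and record, for every
#' terminal node `t` of the *original* tree, the fraction `p_b(t)` of the
#' test rows routed to `t` that `T_b` predicts class 1.
#'
#' @param tree the fitted `guide_tree`.
#' @param train training `data.frame` the tree was fitted on.
#' @param test test-set `data.frame` (non-empty).
#' @param B number of bootstrap replicates (>= 2; 500 by default, at which
#'   the resampling error component is negligible).
#' @param seed integer seed; all resampling and refitting randomness runs in
#'   one stream from this seed.
#' @param folds cross-validation folds for each refit's pruning.
#' @return Matrix (terminal nodes x B) of `p_b(t)`, `NA` rows for nodes
#'   without test data; attributes `node_id`, `n_t`, and `redraws` (number
#'   of single-class resamples that were redrawn).
#' @export
bootstrap_node_probabilities <- function(tree, train, test, B = 500,
                                         seed = 1, folds = 10) {
  stopifnot(inherits(tree, "guide_tree"))
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  ref <- estimate_node_reference(tree, test)
  routed <- predict_route(tree, test)
  groups <- lapply(ref$node_id, function(t) which(routed$node == t))
  n <- nrow(train)
  y <- as.integer(train[[tree$outcome]])
  w <- ifelse(y == 1, tree$costs$cost_fn, tree$costs$cost_fp)
  enc_train <- .encode_data(train, tree$outcome, tree$var_info)
  enc_test <- .encode_data(test, tree$outcome, tree$var_info)
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(NA_real_, length(ref$node_id), B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      redraws <- redraws + 1L
    }
    tb <- .fit_pruned_rows(enc_train, y, w, idx, tree$outcome, tree$costs,
                           tree$control, folds = folds)
    nd <- tb$nodes
    pred <- route_cpp(nd$id, as.integer(nd$leaf), nd$type, nd$v1, nd$v2,
                      nd$a, nd$cut, tb$subsets, nd$pred, enc_test$X)$pred
    for (gi in seq_along(groups)) {
      if (length(groups[[gi]]))
        P[gi, b] <- mean(pred[groups[[gi]]] == 1)
    }
  }
  structure(P, node_id = ref$node_id, n_t = ref$n_t, redraws = redraws)
}

#' Refined node probability
#'
#' The bootstrap-refined probability of a terminal node: the arithmetic
#' mean of its replicate probabilities.
#'
#' @param p_b numeric vector of replicate probabilities for one node.
#' @return Their mean (`NA` if the node had no test data).
#' @export
refine_probability <- function(p_b) {
  if (all(is.na(p_b))) return(NA_real_)
  mean(p_b)
}

#' Classification reliability of a terminal node
#'
#' The percentage of replicates whose probability falls on the reference
#' class's side of the threshold: strict `p_b > k` counts as agreement for a
#' class-1 node, `p_b <= k` for a class-0 node.
#'
#' @param p_b replicate probabilities for one node.
#' @param c_hat the node's reference class (0 or 1).
#' @param threshold_k classification threshold `k`.
#' @return `R_c` in percent (0-100).
#' @export
classification_reliability <- function(p_b, c_hat, threshold_k) {
  if (all(is.na(p_b)) || is.na(c_hat)) return(NA_real_)
  agree <- if (c_hat == 1) p_b > threshold_k else p_b <= threshold_k
  100 * mean(agree)
}

#' Logit shrinkage of a probability towards 0.5
#'
#' `p' = expit(eps * logit(p))`: with a small `eps` the result is very close
#' to 0.5 — the probability at which a binomial proportion has maximum
#' variance — while retaining a trace of `p`'s direction.  `p` is clamped to
#' `[1e-6, 1 - 1e-6]` before the logit, which is undefined at 0 and 1.
#'
#' @param p probability vector in `[0, 1]`.
#' @param epsilon shrinkage constant (default `1e-4`).
#' @return The shrunk probabilities.
#' @export
shrink_probability <- function(p, epsilon = 1e-4) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)), epsilon > 0)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  stats::plogis(epsilon * stats::qlogis(p))
}

#' Variance of a node's bootstrap probability
#'
#' The variance of the bootstrap standard error of a binomial proportion at
#' `(p, n)` splits into a sampling component and a resampling component.
#' Substituting the binomial moments (`mu2 = npq`,
#' `mu4 = npq(1 + 3pq(n-2))`) into the kurtosis expansion gives the
#' closed-form sampling component
#' `V_I = (2 p q (n - 3) + 1) / (4 n^2)`; the resampling component, due to
#' the finite number of bootstrap replicates, is `V_II = V_I / B` and
#' vanishes as `B` grows.
#'
#' @param p_B refined node probability.
#' @param n_t node test count (>= 1).
#' @param B number of bootstrap replicates.
#' @return `list(V_I = , V_II = , V = V_I + V_II)`.
#' @export
node_variance <- function(p_B, n_t, B) {
  if (any(n_t < 1)) stop("n_t must be at least 1", call. = FALSE)
  V_I <- (2 * p_B * (1 - p_B) * (n_t - 3) + 1) / (4 * n_t^2)
  list(V_I = V_I, V_II = V_I / B, V = V_I * (1 + 1 / B))
}

#' Worst-case reference variance of a node
#'
#' The sampling-variance formula evaluated at the logit-shrunk probability
#' `p' = shrink_probability(p_B, epsilon)`, i.e. essentially at `p = 0.5`
#' where the binomial variance is maximal:
#' `V_R = (2 p' q' (n - 3) + 1) / (4 n^2)`.
#'
#' @param p_B refined node probability.
#' @param n_t node test count (>= 1).
#' @param epsilon shrinkage constant.
#' @return `V_R(t)`.
#' @export
reference_variance <- function(p_B, n_t, epsilon = 1e-4) {
  if (any(n_t < 1)) stop("n_t must be at least 1", call. = FALSE)
  ps <- shrink_probability(p_B, epsilon)
  (2 * ps * (1 - ps) * (n_t - 3) + 1) / (4 * n_t^2)
}

#' Prediction reliability of a terminal node
#'
#' The ratio (in percent) of the node's observed sampling variance to the
#' worst-case reference variance: values near 100% mean the node's
#' probability is about as unstable as it could possibly be.
#'
#' @param V_I sampling variance component.
#' @param V_R reference (worst-case) variance, > 0.
#' @return `R_P` in percent; `NA` where `V_R` is 0 (degenerate `n_t < 3`
#'   nodes).
#' @export
prediction_reliability <- function(V_I, V_R) {
  ifelse(!is.na(V_R) & V_R > 0, 100 * V_I / V_R, NA_real_)
}

#' Flag unreliable nodes
#'
#' A node's classification is unreliable when `R_c <= 100 k'` and its
#' prediction unreliable when `R_P > 100 k'`.  Nodes with fewer than 3 test
#' rows are flagged `tiny_node` (the variance formulas degenerate there) and
#' nodes with none `no_test_data`.
#'
#' @param records reliability record `data.frame` (columns `n_t`, `R_c`,
#'   `R_P`).
#' @param k_prime reliability cutoff (default 0.95).
#' @return `records` with logical flag columns added.
#' @export
flag_nodes <- function(records, k_prime = 0.95) {
  records$classification_unreliable <-
    !is.na(records$R_c) & records$R_c <= 100 * k_prime
  records$prediction_unreliable <-
    !is.na(records$R_P) & records$R_P > 100 * k_prime
  records$tiny_node <- records$n_t > 0 & records$n_t < 3
  records$no_test_data <- records$n_t == 0
  records
}

#' Bootstrap reliability of every terminal node
#'
#' End-to-end reliability analysis: route the test set, bootstrap the
#' training set `B` times with identical growth and pruning settings, and
#' compute per terminal node the refined probability, classification
#' reliability `R_c`, the variance decomposition (`V_I`, `V_II`), the
#' logit-shrinkage reference variance `V_R`, the prediction reliability
#' `R_P = 100 V_I / V_R`, and the unreliability flags at cutoff `k'`.
#'
#' @param tree fitted `guide_tree`.
#' @param train,test the training and test sets.
#' @param B bootstrap replicates (default 500).
#' @param epsilon logit-shrinkage constant (default `1e-4`).
#' @param k_prime reliability decision cutoff (default 0.95).
#' @param seed integer seed for the bootstrap stream.
#' @param folds CV folds for refit pruning.
#' @param class_source `"test"` (reference class from the test-set
#'   proportion at threshold `k`, the default) or `"train"` (the fitted
#'   tree's terminal label).
#' @param include_resampling if `TRUE`, `R_P` uses the total variance
#'   `V = V_I + V_II` instead of the sampling component alone.
#' @return An object of class `node_reliability`: `records` (one row per
#'   terminal node), `matrix` (replicate probabilities), `settings`.
#' @export
node_reliability <- function(tree, train, test, B = 500, epsilon = 1e-4,
                             k_prime = 0.95, seed = 1, folds = 10,
                             class_source = c("test", "train"),
                             include_resampling = FALSE) {
  class_source <- match.arg(class_source)
  ref <- estimate_node_reference(tree, test)
  if (class_source == "train") {
    nd <- tree$nodes[tree$nodes$leaf, ]
    ref$c_hat <- nd$pred[match(ref$node_id, nd$id)]
  }
  M <- bootstrap_node_probabilities(tree, train, test, B = B, seed = seed,
                                    folds = folds)
  k <- tree$costs$threshold_k
  rec <- ref
  rec$P_B <- apply(M, 1, refine_probability)
  rec$R_c <- vapply(seq_len(nrow(rec)), function(i)
    classification_reliability(M[i, ], rec$c_hat[i], k), 0)
  ok <- rec$n_t >= 1
  rec$V_I <- rec$V_II <- rec$V <- rec$V_R <- rec$R_P <- NA_real_
  if (any(ok)) {
    v <- node_variance(rec$P_B[ok], rec$n_t[ok], B)
    rec$V_I[ok] <- v$V_I
    rec$V_II[ok] <- v$V_II
    rec$V[ok] <- v$V
    rec$V_R[ok] <- reference_variance(rec$P_B[ok], rec$n_t[ok], epsilon)
    num <- if (include_resampling) rec$V[ok] else rec$V_I[ok]
    rec$R_P[ok] <- prediction_reliability(num, rec$V_R[ok])
  }
  rec <- flag_nodes(rec, k_prime)
  structure(list(records = rec, matrix = M,
                 settings = list(B = B, epsilon = epsilon, k_prime = k_prime,
                                 threshold_k = k, seed = seed, folds = folds,
                                 class_source = class_source,
                                 include_resampling = include_resampling,
                                 redraws = attr(M, "redraws"))),
            class = "node_reliability")
}

#' @export
print.node_reliability <- function(x, ...) {
  r <- x$records
  cat("Terminal-node reliability (B =", x$settings$B, "replicates, k =",
      signif(x$settings$threshold_k, 4), ", k' =", x$settings$k_prime,
      ")\n")
  shown <- data.frame(node = r$node_id, n_t = r$n_t,
                      P_B = round(r$P_B, 3),
                      R_c = round_half_up(r$R_c, 2),
                      R_P = round_half_up(r$R_P, 2),
                      flags = apply(
                        r[c("classification_unreliable",
                            "prediction_unreliable", "tiny_node",
                            "no_test_data")], 1,
                        function(fl) paste(c("C", "P", "t", "0")[which(fl)],
                                           collapse = "")))
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Write a reliability report
#'
#' CSV or JSON twin of the per-node reliability table: `node_id`, `n_t`,
#' `P_B`, `R_c` and `R_P` (rounded to 2 decimals in the output), variance
#' components, and flags.
#'
#' @param x a `node_reliability` object.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_reliability <- function(x, path) {
  stopifnot(inherits(x, "node_reliability"))
  r <- x$records
  out <- data.frame(node_id = r$node_id, n_t = r$n_t,
                    P_B = r$P_B,
                    R_c_pct = round_half_up(r$R_c, 2),
                    R_P_pct = round_half_up(r$R_P, 2),
                    V_I = r$V_I, V_II = r$V_II, V_R = r$V_R,
                    classification_unreliable = r$classification_unreliable,
                    prediction_unreliable = r$prediction_unreliable,
                    tiny_node = r$tiny_node, no_test_data = r$no_test_data)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
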