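# Rendering and orchestration: human-readable tree displays, JSON/DOT
# export, and the end-to-end pipeline (simulate -> fit under both cost
# settings -> evaluate -> bootstrap reliability -> write reports).

# display label of an internal node's split condition
.rule_label <- function(tree, i) {
  nd <- tree$nodes[i, ]
  vn <- tree$var_info$names
  if (nd$type == 1) {
    vi <- nd$v1
    if (tree$var_info$kinds[vi] == 1L) {
      lev <- tree$var_info$levels[[vi]]
      sprintf("%s <= %s", vn[vi], lev[floor(nd$cut)])
    } else {
      sprintf("%s <= %s", vn[vi], format(signif(nd$cut, 6)))
    }
  } else if (nd$type == 2) {
    lev <- tree$var_info$levels[[nd$v1]][tree$subsets[[i]]]
    sprintf("%s in {%s}", vn[nd$v1], paste(lev, collapse = ","))
  } else {
    sprintf("%s*%s + %s <= %s", format(signif(nd$a, 3)), vn[nd$v1],
            vn[nd$v2], format(signif(nd$cut, 6)))
  }
}

# per-terminal test counts/proportions, aligned to node id
.test_stats <- function(tree, test) {
  if (is.null(test)) return(NULL)
  estimate_node_reference(tree, test)
}

#' Render a fitted tree as text or DOT
#'
#' The text form is an indented outline; each terminal line is a
#' three-part box — training count with its class-1 percentage, the node
#' id, and (when a test set is given) the test count with its class-1
#' percentage.  The DOT form encodes the predicted class as the node's
#' fill (dark = class 1) for graphviz rendering.
#'
#' @param tree a fitted `guide_tree`.
#' @param test optional test `data.frame` for the test-side of the boxes.
#' @param format `"text"` or `"dot"`.
#' @return Character vector of lines.
#' @export
render_tree <- function(tree, test = NULL, format = c("text", "dot")) {
  format <- match.arg(format)
  nd <- tree$nodes
  ts <- .test_stats(tree, test)
  box <- function(i) {
    id <- nd$id[i]
    left <- sprintf("%d (%.0f%%)", nd$n0[i] + nd$n1[i], 100 * nd$p1[i])
    right <- if (is.null(ts)) "" else {
      j <- match(id, ts$node_id)
      if (ts$n_t[j] > 0)
        sprintf(" | %d (%.0f%%)", ts$n_t[j], 100 * ts$P_hat[j])
      else " | 0 (-)"
    }
    sprintf("[%s | node %d%s] class=%d", left, id, right, nd$pred[i])
  }
  if (format == "text") {
    lines <- character(0)
    walk <- function(id, indent) {
      i <- match(id, nd$id)
      if (nd$leaf[i]) {
        lines <<- c(lines, paste0(indent, box(i)))
      } else {
        lines <<- c(lines, sprintf("%snode %d: %s?", indent, id,
                                   .rule_label(tree, i)))
        walk(2 * id, paste0(indent, "  "))
        walk(2 * id + 1, paste0(indent, "  "))
      }
    }
    walk(1L, "")
    return(lines)
  }
  lines <- c("digraph tree {", "  node [shape=box];")
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]
    lab <- if (nd$leaf[i]) box(i) else .rule_label(tree, i)
    style <- if (nd$leaf[i] && nd$pred[i] == 1)
      ", style=filled, fillcolor=gray40, fontcolor=white"
    else if (nd$leaf[i]) ", style=filled, fillcolor=white" else ""
    lines <- c(lines, sprintf("  n%d [label=\"%s\"%s];", id, lab, style))
    if (!nd$leaf[i])
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", id, 2 * id),
                 sprintf("  n%d -> n%d [label=\"no\"];", id, 2 * id + 1))
  }
  c(lines, "}")
}

#' Serialise a fitted tree to JSON
#'
#' Writes the node table (ids, rules with variable names, training counts
#' and class probabilities, predicted classes) plus the cost specification
#' and growth settings.
#'
#' @param tree a `guide_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
tree_to_json <- function(tree, path) {
  nd <- tree$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    rec <- list(id = nd$id[i], leaf = nd$leaf[i],
                n0 = nd$n0[i], n1 = nd$n1[i], p1 = nd$p1[i],
                class = nd$pred[i])
    if (!nd$leaf[i]) {
      rec$rule <- list(
        type = c("numeric", "subset", "linear")[nd$type[i]],
        variable = tree$var_info$names[nd$v1[i]],
        variable2 = if (nd$type[i] == 3) tree$var_info$names[nd$v2[i]],
        coefficient = if (nd$type[i] == 3) nd$a[i],
        cutoff = if (nd$type[i] != 2) nd$cut[i],
        levels = if (nd$type[i] == 2)
          tree$var_info$levels[[nd$v1[i]]][tree$subsets[[i]]],
        label = .rule_label(tree, i))
    }
    rec
  })
  jsonlite::write_json(
    list(nodes = nodes,
         costs = unclass(tree$costs),
         control = unclass(tree$control)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or take) a cohort, split it 70/30, fit a pruned tree under the
#' equal-cost and the 1:2 unequal-cost settings, evaluate both on training
#' and test data, run the bootstrap reliability analysis of each tree's
#' terminal nodes, and (optionally) write every artifact — tree JSON/DOT/
#' text, metric reports, reliability reports, and a run manifest — to an
#' output directory.  Identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param data optional cohort `data.frame`; when `NULL` one is generated
#'   from `schema` and `scenario`.
#' @param schema a [cohort_schema()].
#' @param scenario a [default_scenario()].
#' @param cost_settings named list of `c(cost_fp, cost_fn)` pairs.
#' @param train_fraction training proportion of the split.
#' @param control a [tree_control()].
#' @param folds CV folds for pruning.
#' @param B bootstrap replicates for the reliability stage (0 skips it).
#' @param epsilon,k_prime reliability settings.
#' @param seed master seed; stage seeds are derived as documented offsets
#'   (`seed` for generation via the scenario, `seed + 1` for the split,
#'   `seed + 2` for pruning, `seed + 3` for the bootstrap).
#' @param out_dir optional directory for artifacts.
#' @return (Invisibly) a list with, per cost setting: the fitted `tree`,
#'   `metrics` (train/test), and `reliability`; plus the `split` and the
#'   run `manifest`.
#' @export
run_pipeline <- function(data = NULL, schema = nafld_schema(),
                         scenario = default_scenario(),
                         cost_settings = list(equal = c(1, 1),
                                              unequal = c(1, 2)),
                         train_fraction = 0.7,
                         control = tree_control(), folds = 10,
                         B = 500, epsilon = 1e-4, k_prime = 0.95,
                         seed = 1, out_dir = NULL) {
  if (is.null(data)) {
    scenario$seed <- seed
    data <- generate_cohort(schema, scenario)
  }
  split <- split_train_test(data, train_fraction, seed = seed + 1,
                            outcome = schema$outcome)
  results <- list()
  for (nm in names(cost_settings)) {
    cc <- cost_settings[[nm]]
    costs <- cost_spec(cc[1], cc[2])
    tree <- grow_tree(split$train, schema$outcome, costs, control)
    tree <- cv_prune(tree, split$train, folds = folds, seed = seed + 2)
    mtr <- list(
      train = classification_metrics(contingency(
        split$train[[schema$outcome]],
        predict_route(tree, split$train)$class)),
      test = classification_metrics(contingency(
        split$test[[schema$outcome]],
        predict_route(tree, split$test)$class)))
    rel <- if (B > 0)
      node_reliability(tree, split$train, split$test, B = B,
                       epsilon = epsilon, k_prime = k_prime,
                       seed = seed + 3, folds = folds)
    results[[nm]] <- list(tree = tree, metrics = mtr, reliability = rel)
  }
  manifest <- list(
    seed = seed,
    stage_seeds = list(generate = seed, split = seed + 1, prune = seed + 2,
                       bootstrap = seed + 3),
    n = nrow(data), train_fraction = train_fraction,
    cost_settings = cost_settings, control = unclass(control),
    folds = folds, B = B, epsilon = epsilon, k_prime = k_prime,
    package_version = as.character(utils::packageVersion("leafboot")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      r <- results[[nm]]
      tree_to_json(r$tree, file.path(out_dir, paste0("tree_", nm, ".json")))
      writeLines(render_tree(r$tree, split$test, "text"),
                 file.path(out_dir, paste0("tree_", nm, ".txt")))
      writeLines(render_tree(r$tree, split$test, "dot"),
                 file.path(out_dir, paste0("tree_", nm, ".dot")))
      for (part in c("train", "test"))
        writeLines(format_contingency(contingency(
          split[[part]][[schema$outcome]],
          predict_route(r$tree, split[[part]])$class)),
          file.path(out_dir, paste0("metrics_", nm, "_", part, ".txt")))
      if (!is.null(r$reliability)) {
        write_reliability(r$reliability,
                          file.path(out_dir,
                                    paste0("reliability_", nm, ".csv")))
        write_reliability(r$reliability,
                          file.path(out_dir,
                                    paste0("reliability_", nm, ".json")))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(results, list(split = split, manifest = manifest)))
}
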