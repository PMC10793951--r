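# The three-node reaction-success classifier: fixed published thresholds and
# a trainable greedy decision tree with an internal-node budget.

#' The published three-threshold reaction rule
#'
#' A coupling is "on" only when all three reaction components are favorable:
#' the Cu-ligand interaction distance `d <= d_max` (a short distance marks a
#' stable, typically anionic Cu-L complex), the amine nitrogen NBO charge
#' `n_charge <= n_charge_max` (sufficient nucleophilicity), and the aryl
#' bromide buried volume `vbur <= vbur_max` (limited steric hindrance).
#' Each off-condition is a strict ">" of its threshold, so equality at a
#' threshold is on.
#'
#' @param d_max Cu-L distance cut in Angstrom.
#' @param n_charge_max Amine N NBO charge cut in au.
#' @param vbur_max Buried volume cut in percent (2.5 Angstrom radius).
#' @return A `fixed_rule` object.
#' @export
fixed_rule <- function(d_max = 2.07, n_charge_max = -0.803, vbur_max = 33.5) {
  if (!is.finite(d_max) || d_max <= 0) stop_invalid("d_max must be > 0")
  if (!is.finite(n_charge_max)) stop_invalid("n_charge_max must be finite")
  if (!is.finite(vbur_max) || vbur_max <= 0 || vbur_max >= 100) {
    stop_invalid("vbur_max must be in (0, 100)")
  }
  structure(list(d_max = d_max, n_charge_max = n_charge_max,
                 vbur_max = vbur_max), class = "fixed_rule")
}

#' @export
print.fixed_rule <- function(x, ...) {
  cat(sprintf("fixed rule: on iff d <= %.3g A  &  N charge <= %.4g au  &  %%VBur <= %.3g%%\n",
              x$d_max, x$n_charge_max, x$vbur_max))
  invisible(x)
}

#' Predict reaction outcome with the fixed rule
#'
#' @param d Cu-L distance(s), Angstrom.
#' @param n_charge Amine nitrogen NBO charge(s), au.
#' @param vbur Bromide buried volume(s), percent.
#' @param rule A `fixed_rule` (defaults to the published thresholds).
#' @return Character vector of `"on"`/`"off"`.
#' @examples
#' predict_fixed(1.95, -0.85, 30)   # "on"
#' predict_fixed(2.20, -0.85, 30)   # "off": d exceeds 2.07 A
#' @export
predict_fixed <- function(d, n_charge, vbur, rule = fixed_rule()) {
  stopifnot(inherits(rule, "fixed_rule"))
  for (nm in c("d", "n_charge", "vbur")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_invalid("feature '%s' must be finite numeric", nm)
    }
  }
  ifelse(d <= rule$d_max & n_charge <= rule$n_charge_max & vbur <= rule$vbur_max,
         "on", "off")
}

# Gini impurity of a label vector
gini <- function(y) {
  p <- mean(y == "on")
  2 * p * (1 - p)
}

# Best midpoint split of one leaf: returns NULL or list(feature, threshold,
# decrease, feature_idx). Decrease is the unnormalized impurity reduction
# n*G(parent) - n_l*G(left) - n_r*G(right); ties by feature order then
# ascending threshold (first hit wins).
best_split <- function(X, y, rows) {
  yy <- y[rows]
  parent <- length(rows) * gini(yy)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    v <- sort(unique(x))
    if (length(v) < 2L) next
    thr <- (v[-length(v)] + v[-1L]) / 2
    for (t in thr) {
      left <- x <= t
      dec <- parent - sum(left) * gini(yy[left]) - sum(!left) * gini(yy[!left])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature_idx = j, feature = colnames(X)[j], threshold = t,
                     decrease = dec)
      }
    }
  }
  best
}

# Best-first greedy tree growth under an internal-node budget. Nodes are a
# flat list; leaves predict their majority label (tie -> "off").
fit_tree <- function(X, y, max_nodes = 3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  nodes <- list(list(type = "leaf", rows = seq_along(y)))
  n_internal <- 0L
  repeat {
    if (n_internal >= max_nodes) break
    # evaluate the best split of every current leaf, pick the best leaf
    cand <- NULL
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      if (nd$type != "leaf") next
      sp <- best_split(X, y, nd$rows)
      if (is.null(sp) || sp$decrease <= 1e-12) next
      if (is.null(cand) || sp$decrease > cand$split$decrease + 1e-12) {
        cand <- list(i = i, split = sp)
      }
    }
    if (is.null(cand)) break
    nd <- nodes[[cand$i]]
    x <- X[nd$rows, cand$split$feature_idx]
    left_rows <- nd$rows[x <= cand$split$threshold]
    right_rows <- nd$rows[x > cand$split$threshold]
    li <- length(nodes) + 1L
    ri <- length(nodes) + 2L
    nodes[[cand$i]] <- list(type = "split", feature = cand$split$feature,
                            threshold = cand$split$threshold,
                            below = li, above = ri, order = n_internal + 1L)
    nodes[[li]] <- list(type = "leaf", rows = left_rows)
    nodes[[ri]] <- list(type = "leaf", rows = right_rows)
    n_internal <- n_internal + 1L
  }
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$type == "leaf") {
      yy <- y[nodes[[i]]$rows]
      nodes[[i]]$label <- if (sum(yy == "on") > sum(yy == "off")) "on" else "off"
      nodes[[i]]$n <- length(yy)
      nodes[[i]]$rows <- NULL
    } else {
      nodes[[i]]$rows <- NULL
    }
  }
  nodes
}

tree_predict_nodes <- function(nodes, newdata) {
  n <- nrow(newdata)
  out <- character(n)
  for (r in seq_len(n)) {
    i <- 1L
    repeat {
      nd <- nodes[[i]]
      if (nd$type == "leaf") { out[r] <- nd$label; break }
      v <- newdata[[nd$feature]][r]
      if (is.null(v) || !is.finite(v)) {
        stop_invalid("feature '%s' missing or non-finite in prediction input",
                     nd$feature)
      }
      i <- if (v <= nd$threshold) nd$below else nd$above
    }
  }
  out
}

# nodes summary table in growth order, with the side whose leaf-majority is
# "off" (reporting only; prediction walks the actual tree)
tree_nodes_table <- function(nodes) {
  idx <- which(vapply(nodes, function(n) n$type == "split", TRUE))
  idx <- idx[order(vapply(nodes[idx], function(n) n$order, 0L))]
  side_label <- function(i) {
    nd <- nodes[[i]]
    if (nd$type == "leaf") nd$label else NA_character_
  }
  data.frame(
    feature_name = vapply(nodes[idx], function(n) n$feature, ""),
    threshold = vapply(nodes[idx], function(n) n$threshold, 0),
    off_branch = vapply(nodes[idx], function(n) {
      b <- side_label(n$below); a <- side_label(n$above)
      if (identical(a, "off") && !identical(b, "off")) "above"
      else if (identical(b, "off") && !identical(a, "off")) "below"
      else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Train the three-node decision-tree classifier
#'
#' Greedy best-first binary recursive partitioning with Gini impurity, grown
#' to at most `max_nodes` internal nodes (a node-count budget — one node per
#' reaction component at the default 3 — not a depth cap). Split candidates
#' are midpoints of consecutive distinct feature values; values at a
#' threshold follow the "below" branch; leaves predict their majority label.
#' The data are split once into training and held-out test sets (seeded
#' simple random split) and metrics are reported for both.
#'
#' @param features data.frame of numeric reaction descriptors; must include
#'   `d`, `n_charge`, `vbur`, may include others.
#' @param labels `"on"`/`"off"` per row.
#' @param max_nodes Internal-node budget.
#' @param test_fraction Held-out fraction (default 0.25, a 75:25 split).
#' @param seed Integer seed for the split.
#' @return A `tree_model`: `tree` (node list), `nodes` (summary table in
#'   growth order), `train_metrics`, `test_metrics`, `max_nodes`, `seed`.
#' @export
train_tree <- function(features, labels, max_nodes = 3, test_fraction = 0.25,
                       seed = 42) {
  labels <- check_labels(labels)
  num <- features[vapply(features, is.numeric, TRUE)]
  need_cols(num, c("d", "n_charge", "vbur"), "features")
  n <- nrow(num)
  if (n != length(labels)) stop_invalid("features and labels length mismatch")
  if (n < 20L) stop_invalid("need n >= 20 reactions, got %d", n)
  if (length(unique(labels)) < 2L) stop_invalid("both classes must be present")
  test_idx <- with_seed(seed, sort(sample.int(n, size = round(test_fraction * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  nodes <- fit_tree(num[train_idx, , drop = FALSE], labels[train_idx], max_nodes)
  pred_tr <- tree_predict_nodes(nodes, num[train_idx, , drop = FALSE])
  model <- structure(
    list(tree = nodes, nodes = tree_nodes_table(nodes),
         max_nodes = as.integer(max_nodes),
         train_metrics = evaluate_binary(pred_tr, labels[train_idx]),
         test_metrics = NULL, cv_mean_accuracy = NA_real_,
         seed = as.integer(seed)),
    class = "tree_model"
  )
  if (length(test_idx)) {
    pred_te <- tree_predict_nodes(nodes, num[test_idx, , drop = FALSE])
    model$test_metrics <- evaluate_binary(pred_te, labels[test_idx])
  }
  model
}

#' @export
predict.tree_model <- function(object, newdata, ...) {
  tree_predict_nodes(object$tree, newdata)
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("decision tree (%d internal node(s), budget %d)\n",
              nrow(x$nodes), x$max_nodes))
  print(x$nodes)
  cat(sprintf("train accuracy %.3f", x$train_metrics$accuracy))
  if (!is.null(x$test_metrics)) {
    cat(sprintf(", test accuracy %.3f", x$test_metrics$accuracy))
  }
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the tree classifier
#'
#' Folds are assigned by dealing a seeded shuffle of each class round-robin,
#' so class proportions are preserved as closely as the counts allow. One
#' tree is fitted per fold on the remaining data (no inner test split) and
#' scored on the held-out fold.
#'
#' @inheritParams train_tree
#' @param folds Number of folds (>= 2; `folds = n` gives leave-one-out).
#' @return List: `mean_accuracy` (arithmetic mean of per-fold accuracies),
#'   `fold_accuracy`, `folds`, `seed`.
#' @export
cross_validate <- function(features, labels, folds = 4, seed = 42,
                           max_nodes = 3) {
  labels <- check_labels(labels)
  num <- features[vapply(features, is.numeric, TRUE)]
  n <- nrow(num)
  if (folds < 2L || folds > n) stop_invalid("folds must be in [2, %d]", n)
  fold_id <- integer(n)
  with_seed(seed, {
    start <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      # continue the round-robin across classes: fold sizes stay balanced,
      # so folds = n degenerates to true leave-one-out
      fold_id[idx] <- ((start + seq_along(idx) - 1L) %% folds) + 1L
      start <- start + length(idx)
    }
  })
  # every training partition must contain both classes
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold_id != f])) < 2L) {
      stop_invalid("fold %d leaves a single-class training set; reduce folds", f)
    }
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    nodes <- fit_tree(num[tr, , drop = FALSE], labels[tr], max_nodes)
    pred <- tree_predict_nodes(nodes, num[!tr, , drop = FALSE])
    mean(pred == labels[!tr])
  }, 0)
  list(mean_accuracy = mean(acc), fold_accuracy = acc,
       folds = as.integer(folds), seed = as.integer(seed))
}
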