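# Ligand screening: per-ligand activity labels, the single-node decision
# stump, and active-learning candidate reselection.

#' Per-ligand activity labels from a reaction table
#'
#' A ligand is "on" when its maximum yield across all products it was tested
#' against strictly exceeds the threshold — i.e. it ever achieved two
#' catalytic turnovers.
#'
#' @param reactions Reaction table (`product_id`, `ligand_id`,
#'   `yield_percent`).
#' @param threshold On/off cut in percent.
#' @return data.frame `ligand_id`, `max_yield`, `label`.
#' @export
ligand_activity_labels <- function(reactions, threshold = 20) {
  need_cols(reactions, c("ligand_id", "yield_percent"), "reactions")
  validate_yields(reactions$yield_percent)
  agg <- stats::aggregate(yield_percent ~ ligand_id, data = reactions, FUN = max)
  agg <- agg[order(agg$ligand_id), , drop = FALSE]
  data.frame(
    ligand_id = agg$ligand_id,
    max_yield = agg$yield_percent,
    label = label_outcome(agg$yield_percent, threshold),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fit a single-node decision stump
#'
#' Exhaustive search over every numeric feature, every candidate threshold
#' (midpoints of consecutive sorted distinct values), and both polarities,
#' returning the maximum-accuracy stump. Ties are broken by (1) larger F1,
#' (2) larger margin (distance from the threshold to the nearest training
#' value), (3) lexicographic feature name, (4) smaller threshold. Values
#' exactly at the threshold fall on the "below" side.
#'
#' @param features data.frame of numeric feature columns, one row per ligand
#'   (non-numeric columns such as `ligand_id` are ignored).
#' @param labels `"on"`/`"off"` per row; both classes must be present.
#' @return A `stump`: `feature_name`, `threshold`, `polarity`
#'   (`on_if_below`/`on_if_above`), `margin`, `train_metrics`.
#' @export
fit_stump <- function(features, labels) {
  labels <- check_labels(labels)
  num <- features[vapply(features, is.numeric, TRUE)]
  if (ncol(num) < 1L) stop_invalid("no numeric feature columns")
  if (nrow(num) != length(labels) || nrow(num) < 2L) {
    stop_invalid("need >= 2 rows and labels aligned with features")
  }
  if (length(unique(labels)) < 2L) {
    stop_invalid("both classes must be present to fit a stump")
  }
  best <- NULL
  for (fname in sort(names(num))) {
    x <- num[[fname]]
    check_numeric_finite(x, fname)
    v <- sort(unique(x))
    if (length(v) < 2L) next
    thresholds <- (v[-length(v)] + v[-1L]) / 2
    for (t in thresholds) {
      margin <- min(abs(x - t))
      for (pol in c("on_if_above", "on_if_below")) {
        pred <- stump_decide(x, t, pol)
        m <- evaluate_binary(pred, labels)
        cand <- list(feature_name = fname, threshold = t, polarity = pol,
                     margin = margin, train_metrics = m)
        if (is.null(best) || stump_better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) stop_invalid("no feature with at least two distinct values")
  structure(best, class = "stump")
}

stump_decide <- function(x, threshold, polarity) {
  below <- x <= threshold  # boundary goes to the "below" branch
  if (polarity == "on_if_below") ifelse(below, "on", "off")
  else ifelse(below, "off", "on")
}

# strict ordering: accuracy, F1, margin, feature name (lexicographic),
# threshold (ascending)
stump_better <- function(a, b) {
  if (a$train_metrics$accuracy != b$train_metrics$accuracy) {
    return(a$train_metrics$accuracy > b$train_metrics$accuracy)
  }
  if (a$train_metrics$f1 != b$train_metrics$f1) {
    return(a$train_metrics$f1 > b$train_metrics$f1)
  }
  if (a$margin != b$margin) return(a$margin > b$margin)
  if (a$feature_name != b$feature_name) return(a$feature_name < b$feature_name)
  a$threshold < b$threshold
}

#' @export
print.stump <- function(x, ...) {
  side <- if (x$polarity == "on_if_below") "<=" else ">"
  cat(sprintf("decision stump: on if %s %s %.4g (margin %.3g)\n",
              x$feature_name, side, x$threshold, x$margin))
  cat(sprintf("  training accuracy %.3f, F1 %.3f (n = %d)\n",
              x$train_metrics$accuracy, x$train_metrics$f1, x$train_metrics$n))
  invisible(x)
}

#' Predict ligand activity with a fitted stump
#'
#' @param stump A `stump`.
#' @param features data.frame (or named list) containing the stump's feature
#'   column.
#' @return Character vector of `"on"`/`"off"`.
#' @export
predict_stump <- function(stump, features) {
  stopifnot(inherits(stump, "stump"))
  if (!stump$feature_name %in% names(features)) {
    stop_invalid("feature '%s' missing from prediction input", stump$feature_name)
  }
  x <- features[[stump$feature_name]]
  check_numeric_finite(x, stump$feature_name)
  stump_decide(x, stump$threshold, stump$polarity)
}

#' Reselect candidate ligands predicted active
#'
#' The active-learning step: screens a pool of commercial candidates through
#' a fitted stump and returns those predicted "on", ordered by decreasing
#' margin from the threshold (most confidently active first, nearest-to-cut
#' last; ties by ligand id).
#'
#' @param candidates Ligand table containing the stump's feature column
#'   (typically `cu_l_distance`) and `ligand_id`.
#' @param stump A fitted `stump`.
#' @return The selected rows of `candidates`, reordered.
#' @export
select_candidates <- function(candidates, stump) {
  pred <- predict_stump(stump, candidates)
  sel <- candidates[pred == "on", , drop = FALSE]
  if (nrow(sel) == 0L) return(sel)
  margin <- abs(sel[[stump$feature_name]] - stump$threshold)
  key2 <- if ("ligand_id" %in% names(sel)) sel$ligand_id else seq_len(nrow(sel))
  sel[order(-margin, key2), , drop = FALSE]
}
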