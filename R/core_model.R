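# Core domain model: on/off labeling, control curation, binary metrics.
#
# Tables are plain data.frames validated against lightweight schemas (see
# read_table()); the record "types" of the workflow are rows of those tables.

#' Classify an assay yield as "on" or "off"
#'
#' A reaction is "on" when its yield strictly exceeds the threshold — the
#' two-catalytic-turnover convention (20% yield at 10 mol% catalyst loading).
#' A yield exactly at the threshold is "off".
#'
#' @param yield_percent Numeric vector of assay yields in percent. Values in
#'   `(100, 150]` are accepted with a warning (assay calibration noise);
#'   negative, non-finite, or `> 150` values are rejected.
#' @param threshold On/off cut in percent (default 20).
#' @return Character vector of `"on"`/`"off"`.
#' @examples
#' label_outcome(c(35, 20, 0))   # "on" "off" "off"
#' @export
label_outcome <- function(yield_percent, threshold = 20) {
  validate_yields(yield_percent)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop_invalid("threshold must be a single finite number")
  }
  ifelse(yield_percent > threshold, "on", "off")
}

validate_yields <- function(yield_percent, what = "yield_percent") {
  if (!is.numeric(yield_percent) || any(!is.finite(yield_percent))) {
    stop_invalid("%s must be finite numeric", what)
  }
  if (any(yield_percent < 0)) {
    stop_invalid("%s must be >= 0 (got %s)", what,
                 paste(yield_percent[yield_percent < 0], collapse = ", "))
  }
  if (any(yield_percent > 150)) {
    stop_invalid("%s above 150%% rejected (got %s)", what,
                 paste(yield_percent[yield_percent > 150], collapse = ", "))
  }
  if (any(yield_percent > 100)) {
    warning(sprintf("%d %s value(s) above 100%% accepted as assay noise",
                    sum(yield_percent > 100), what), call. = FALSE)
  }
  invisible(yield_percent)
}

#' Remove products with catalysis-independent background reactivity
#'
#' Each product must carry two controls: a ligand-free reaction (`no_ligand`)
#' and a reaction without ligand or copper (`no_ligand_no_cu`). A product
#' fails — i.e. its apparent reactivity may be SNAr or another background
#' pathway rather than Cu catalysis — when either control reaches
#' `control_threshold`.
#'
#' @param products Product table (`product_id`, `bromide_id`, `amine_id`).
#' @param controls Control table (`product_id`, `control_type`,
#'   `yield_percent`).
#' @param control_threshold Failure cut in percent; a control yield `>=` this
#'   value fails the product (default 20).
#' @return List with `passing` and `failed` product tables (a disjoint,
#'   exhaustive partition of the input, input order preserved) and `reasons`,
#'   a data.frame logging each failing control.
#' @export
apply_control_filter <- function(products, controls, control_threshold = 20) {
  need_cols(products, c("product_id"), "products")
  need_cols(controls, c("product_id", "control_type", "yield_percent"), "controls")
  validate_yields(controls$yield_percent, "control yield_percent")
  bad_type <- !(controls$control_type %in% c("no_ligand", "no_ligand_no_cu"))
  if (any(bad_type)) {
    stop_invalid("unknown control_type: %s",
                 paste(unique(controls$control_type[bad_type]), collapse = ", "))
  }
  for (pid in products$product_id) {
    for (ct in c("no_ligand", "no_ligand_no_cu")) {
      if (!any(controls$product_id == pid & controls$control_type == ct)) {
        stop_invalid("product %s is missing its %s control", pid, ct)
      }
    }
  }
  rel <- controls[controls$product_id %in% products$product_id &
                    controls$yield_percent >= control_threshold, , drop = FALSE]
  failed_ids <- unique(rel$product_id)
  fail <- products$product_id %in% failed_ids
  reasons <- data.frame(
    product_id = rel$product_id,
    control_type = rel$control_type,
    yield_percent = rel$yield_percent,
    stringsAsFactors = FALSE
  )
  if (nrow(reasons)) {
    message(sprintf("control filter: %d of %d products failed (%s)",
                    sum(fail), nrow(products),
                    paste(sort(failed_ids), collapse = ", ")))
  }
  list(
    passing = products[!fail, , drop = FALSE],
    failed = products[fail, , drop = FALSE],
    reasons = reasons
  )
}

#' Binary classification metrics with "on" as the positive class
#'
#' @param predicted,observed Equal-length vectors of `"on"`/`"off"` labels.
#' @return A `binary_metrics` object: `accuracy`, `f1`, `n`, and the 2x2
#'   `confusion` matrix (rows = observed, columns = predicted). F1 is 0 when
#'   its denominator vanishes (no true or predicted positives).
#' @export
evaluate_binary <- function(predicted, observed) {
  predicted <- check_labels(predicted, "predicted")
  observed <- check_labels(observed, "observed")
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop_invalid("predicted (%d) and observed (%d) must have equal length >= 1",
                 length(predicted), length(observed))
  }
  n <- length(predicted)
  tp <- sum(predicted == "on" & observed == "on")
  tn <- sum(predicted == "off" & observed == "off")
  fp <- sum(predicted == "on" & observed == "off")
  fn <- sum(predicted == "off" & observed == "on")
  confusion <- matrix(c(tp, fn, fp, tn), nrow = 2L,
                      dimnames = list(observed = LABELS, predicted = LABELS))
  f1 <- if ((2 * tp + fp + fn) == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(
    list(accuracy = (tp + tn) / n, f1 = f1, n = n, confusion = confusion),
    class = "binary_metrics"
  )
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("binary metrics (n = %d): accuracy %.3f, F1 %.3f\n",
              x$n, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Per-product substrate coordinates
#'
#' Joins each product to its amine's nitrogen NBO charge and its bromide's
#' buried volume — the two substrate features of the decision tree and the
#' axes of the confidence map.
#'
#' @param products,bromides,amines Validated tables.
#' @return data.frame with `product_id`, `n_charge` (au), `vbur` (%).
#' @export
product_feature_coords <- function(products, bromides, amines) {
  need_cols(products, c("product_id", "bromide_id", "amine_id"), "products")
  need_cols(bromides, c("bromide_id", "vbur"), "bromides")
  need_cols(amines, c("amine_id", "n_charge"), "amines")
  ib <- match(products$bromide_id, bromides$bromide_id)
  ia <- match(products$amine_id, amines$amine_id)
  if (anyNA(ib)) {
    stop_invalid("unresolvable bromide_id: %s",
                 paste(unique(products$bromide_id[is.na(ib)]), collapse = ", "))
  }
  if (anyNA(ia)) {
    stop_invalid("unresolvable amine_id: %s",
                 paste(unique(products$amine_id[is.na(ia)]), collapse = ", "))
  }
  data.frame(
    product_id = products$product_id,
    n_charge = amines$n_charge[ia],
    vbur = bromides$vbur[ib],
    stringsAsFactors = FALSE
  )
}

need_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) stop_invalid("%s must be a data.frame", what)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_invalid("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
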