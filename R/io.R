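# Table I/O with schema validation, flat config files, model serialization.

SCHEMAS <- list(
  ligands = list(required = c("ligand_id", "cu_l_distance"),
                 numeric = "cu_l_distance", id = "ligand_id"),
  bromides = list(required = c("bromide_id", "vbur"),
                  numeric = "vbur", id = "bromide_id"),
  amines = list(required = c("amine_id", "n_charge"),
                numeric = "n_charge", id = "amine_id"),
  products = list(required = c("product_id", "bromide_id", "amine_id"),
                  numeric = character(0), id = "product_id"),
  reactions = list(required = c("product_id", "ligand_id", "yield_percent"),
                   numeric = "yield_percent", id = NULL),
  controls = list(required = c("product_id", "control_type", "yield_percent"),
                  numeric = "yield_percent", id = NULL),
  candidates = list(required = c("candidate_id", "logp", "mol_weight"),
                    numeric = c("logp", "mol_weight"), id = "candidate_id"),
  queries = list(required = c("d", "n_charge", "vbur"),
                 numeric = c("d", "n_charge", "vbur"), id = NULL),
  truth = list(required = c("product_id", "ligand_id", "yield_percent",
                            "label_true"),
               numeric = "yield_percent", id = NULL)
)

#' Read and validate a CSV table
#'
#' Comma-separated, UTF-8, header row; lines starting with `#` (the
#' `schema_version` comment) are skipped. Extra columns beyond the schema are
#' carried through as extra descriptors; extra *numeric-looking* values are
#' parsed as numeric.
#'
#' @param path CSV file path.
#' @param schema One of `"ligands"`, `"bromides"`, `"amines"`, `"products"`,
#'   `"reactions"`, `"controls"`, `"candidates"`, `"queries"`, `"truth"`.
#' @return Validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(SCHEMAS)) {
    stop_invalid("unknown schema '%s'", schema)
  }
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  sc <- SCHEMAS[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(sc$required, names(df))
  if (length(missing)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  for (col in sc$numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop_invalid("%s: column '%s' has unparseable numeric value '%s' at row %d",
                     path, col, v[bad[1L]], bad[1L])
      }
      v <- num
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop_invalid("%s: column '%s' has missing/non-finite values at row %d",
                   path, col, which(!is.finite(v))[1L])
    }
    df[[col]] <- v
  }
  if (!is.null(sc$id) && anyDuplicated(df[[sc$id]])) {
    stop_invalid("%s: duplicated %s: %s", path, sc$id,
                 paste(unique(df[[sc$id]][duplicated(df[[sc$id]])]),
                       collapse = ", "))
  }
  if (schema %in% c("reactions", "controls")) {
    validate_yields(df$yield_percent)
  }
  if (schema == "reactions" &&
      anyDuplicated(paste(df$product_id, df$ligand_id))) {
    stop_invalid("%s: duplicate (product_id, ligand_id) rows", path)
  }
  if (schema == "ligands" && any(df$cu_l_distance <= 0)) {
    stop_invalid("%s: cu_l_distance must be > 0", path)
  }
  if (schema == "bromides" && any(df$vbur <= 0 | df$vbur >= 100)) {
    stop_invalid("%s: vbur must be in (0, 100)", path)
  }
  message(sprintf("read %s: %d row(s) [%s]", path, nrow(df), schema))
  df
}

#' Write a table as versioned CSV
#'
#' Prepends a `# schema_version: 1` comment line; numerics round-trip through
#' [read_table()] to better than 1e-12 relative error.
#'
#' @param df data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# schema_version: 1", con)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Workflow run configuration
#'
#' All tunables of the pipeline with their defaults: the 20% on/off and
#' control thresholds, the published rule thresholds, base-10 entropy,
#' thin-plate RBF with zero smoothing, 2 neighbors x top-3 ligands, and a
#' 6-ligand confidence floor.
#'
#' @param yield_threshold,control_threshold Percent cuts.
#' @param d_max,n_charge_max,vbur_max Fixed-rule thresholds.
#' @param entropy_base 10, 2, or e (any value > 1).
#' @param rbf_kernel,rbf_smoothing Confidence-map interpolation settings.
#' @param knn_k,top_n Recommender settings.
#' @param min_ligands_for_confidence Minimum panel size per product.
#' @param seed Integer.
#' @return A validated `run_config` list.
#' @export
run_config <- function(yield_threshold = 20, control_threshold = 20,
                       d_max = 2.07, n_charge_max = -0.803, vbur_max = 33.5,
                       entropy_base = 10, rbf_kernel = "thin_plate",
                       rbf_smoothing = 0, knn_k = 2, top_n = 3,
                       min_ligands_for_confidence = 6, seed = 42) {
  cfg <- list(yield_threshold = yield_threshold,
              control_threshold = control_threshold,
              d_max = d_max, n_charge_max = n_charge_max, vbur_max = vbur_max,
              entropy_base = entropy_base, rbf_kernel = rbf_kernel,
              rbf_smoothing = rbf_smoothing, knn_k = knn_k, top_n = top_n,
              min_ligands_for_confidence = min_ligands_for_confidence,
              seed = seed)
  if (yield_threshold < 0 || control_threshold < 0) {
    stop_invalid("thresholds must be >= 0")
  }
  if (!is.finite(entropy_base) || entropy_base <= 1) {
    stop_invalid("entropy_base must be > 1")
  }
  if (!rbf_kernel %in% c("thin_plate", "multiquadric", "gaussian")) {
    stop_invalid("unknown rbf_kernel '%s'", rbf_kernel)
  }
  if (rbf_smoothing < 0) stop_invalid("rbf_smoothing must be >= 0")
  if (knn_k < 1 || top_n < 1 || min_ligands_for_confidence < 1) {
    stop_invalid("knn_k, top_n, min_ligands_for_confidence must be >= 1")
  }
  fixed_rule(d_max, n_charge_max, vbur_max)  # range-validates the rule
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a flat file
#'
#' Accepts a flat `key: value` file (a YAML subset; `#` comments and blank
#' lines ignored) or a JSON object. Unknown keys and out-of-range values are
#' rejected; omitted keys take their [run_config()] defaults. The effective
#' configuration is logged.
#'
#' @param path File path, or `NULL` for pure defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*?)\\s*$", lines))
    bad <- lines[vapply(kv, length, 0L) != 3L]
    if (length(bad)) stop_invalid("unparseable config line: %s", bad[1L])
    vals <- lapply(kv, function(m) {
      v <- m[3L]
      suppressWarnings(num <- as.numeric(v))
      if (!is.na(num)) num else v
    })
    stats::setNames(vals, vapply(kv, `[[`, "", 2L))
  }
  unknown <- setdiff(names(raw), names(formals(run_config)))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(run_config, as.list(raw))
  message(sprintf("effective config: %s",
                  paste(sprintf("%s=%s", names(cfg), unlist(cfg)),
                        collapse = " ")))
  cfg
}

# Model serialization ---------------------------------------------------------

#' Serialize a stump, tree model, or confidence map to JSON
#'
#' @param object A `stump`, `tree_model`, or `confidence_map`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
model_to_json <- function(object, path) {
  obj <- if (inherits(object, "stump")) {
    list(type = "stump", feature_name = object$feature_name,
         threshold = object$threshold, polarity = object$polarity,
         margin = object$margin,
         metrics = metrics_to_list(object$train_metrics))
  } else if (inherits(object, "tree_model")) {
    list(type = "tree", max_nodes = object$max_nodes, seed = object$seed,
         nodes = object$nodes, tree = object$tree,
         train_metrics = metrics_to_list(object$train_metrics),
         test_metrics = if (!is.null(object$test_metrics)) {
           metrics_to_list(object$test_metrics)
         })
  } else if (inherits(object, "confidence_map")) {
    list(type = "confidence_map", kernel = object$kernel,
         smoothing = object$smoothing, points = object$points)
  } else {
    stop_invalid("cannot serialize object of class %s",
                 paste(class(object), collapse = "/"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

metrics_to_list <- function(m) {
  list(accuracy = m$accuracy, f1 = m$f1, n = m$n,
       confusion = as.vector(m$confusion))
}

#' Deserialize a model written by [model_to_json()]
#'
#' Confidence maps are refitted from their stored points (exact under zero
#' smoothing), so no solver state is stored on disk.
#'
#' @param path JSON file.
#' @return A `stump`, `tree_model`, or `confidence_map`.
#' @export
model_from_json <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  switch(obj$type,
    stump = structure(
      list(feature_name = obj$feature_name, threshold = obj$threshold,
           polarity = obj$polarity, margin = obj$margin,
           train_metrics = NULL),
      class = "stump"),
    tree = {
      nodes <- lapply(obj$tree, function(nd) {
        nd[c("type", "feature", "threshold", "below", "above", "order",
             "label", "n")][!vapply(nd[c("type", "feature", "threshold",
                                         "below", "above", "order", "label",
                                         "n")], is.null, TRUE)]
      })
      structure(
        list(tree = nodes,
             nodes = do.call(rbind, lapply(obj$nodes, as.data.frame)),
             max_nodes = obj$max_nodes, train_metrics = NULL,
             test_metrics = NULL, seed = obj$seed),
        class = "tree_model")
    },
    confidence_map = {
      pts <- do.call(rbind, lapply(obj$points, as.data.frame))
      fit_confidence_map(pts, kernel = obj$kernel, smoothing = obj$smoothing)
    },
    stop_invalid("unknown model type '%s' in %s", obj$type, path)
  )
}
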