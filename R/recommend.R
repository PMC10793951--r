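# Two-nearest-neighbor ligand recommendation in substrate feature space.

#' Top-performing ligands for one product
#'
#' @param reactions Reaction rows for a single product (`ligand_id`,
#'   `yield_percent`).
#' @param top_n Number of ligands to return (highest yield first; ties by
#'   lexicographic ligand id). Fewer tested ligands than `top_n` returns all
#'   with a warning.
#' @return Character vector of ligand ids.
#' @export
top_ligands <- function(reactions, top_n = 3) {
  need_cols(reactions, c("ligand_id", "yield_percent"), "reactions")
  if (length(unique(reactions$product_id)) > 1L) {
    stop_invalid("top_ligands expects reactions for a single product")
  }
  if (nrow(reactions) < top_n) {
    warning(sprintf("only %d tested ligand(s) < top_n = %d; returning all",
                    nrow(reactions), top_n), call. = FALSE)
  }
  ord <- order(-reactions$yield_percent, reactions$ligand_id)
  utils::head(reactions$ligand_id[ord], top_n)
}

#' Nearest dataset products to a query point
#'
#' Euclidean distance in the standardized (n_charge, vbur) plane — the same
#' space as the confidence map; standardization statistics come from the
#' candidate pool. Ties are broken by lexicographic product id.
#'
#' @param query Numeric `c(n_charge, vbur)` pair.
#' @param coords data.frame `product_id`, `n_charge`, `vbur` (the candidate
#'   pool; exclude the query's own product before calling, or use
#'   `exclude_id`).
#' @param k Number of neighbors.
#' @param exclude_id Optional product id removed from the pool (leave-self-out).
#' @return data.frame `product_id`, `distance`, ordered nearest first.
#' @export
nearest_products <- function(query, coords, k = 2, exclude_id = NULL) {
  need_cols(coords, c("product_id", "n_charge", "vbur"), "coords")
  if (length(query) != 2L || any(!is.finite(query))) {
    stop_invalid("query must be a finite (n_charge, vbur) pair")
  }
  # standardize over the full pool (the map's feature space), then drop self
  std <- standardize_cols(coords[, c("n_charge", "vbur")])
  keep <- rep(TRUE, nrow(coords))
  if (!is.null(exclude_id)) keep <- coords$product_id != exclude_id
  coords <- coords[keep, , drop = FALSE]
  z <- std$z[keep, , drop = FALSE]
  if (k < 1L || k > nrow(coords)) {
    stop_invalid("k = %s exceeds the %d available products", k, nrow(coords))
  }
  zq <- (as.numeric(query) - std$center) / std$scale
  dist <- sqrt(colSums((t(z) - zq)^2))
  ord <- order(dist, coords$product_id)
  data.frame(
    product_id = coords$product_id[ord[seq_len(k)]],
    distance = dist[ord[seq_len(k)]],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Recommend ligands from the two nearest neighbors
#'
#' Finds the query's `k` nearest dataset products in substrate feature space
#' and pools each neighbor's `top_n` best-yielding ligands: the first
#' neighbor's list, then the second's novelties, deduplicated. Ligands
#' recommended by more than one neighbor are flagged `shared` (the "**"
#' ligands). This narrows an 18-ligand search space to at most
#' `k * top_n` candidates.
#'
#' @param query Either a product id present in `coords` (leave-self-out
#'   lookup) or a numeric `c(n_charge, vbur)` pair.
#' @param reactions Full reaction table.
#' @param coords Product coordinate table (see [product_feature_coords()]).
#' @param k Neighbors to consult.
#' @param top_n Ligands per neighbor.
#' @return A `recommendation`: `query_id`, `neighbor_ids`, `ligand_ids`,
#'   `shared` (logical per ligand), `provenance` (ligand, neighbor, yield).
#' @export
recommend_ligands <- function(query, reactions, coords, k = 2, top_n = 3) {
  need_cols(reactions, c("product_id", "ligand_id", "yield_percent"), "reactions")
  if (is.character(query) && length(query) == 1L) {
    row <- coords[coords$product_id == query, , drop = FALSE]
    if (nrow(row) != 1L) stop_invalid("query product '%s' not found", query)
    qid <- query
    qxy <- c(row$n_charge, row$vbur)
    nn <- nearest_products(qxy, coords, k = k, exclude_id = qid)
  } else {
    qid <- NA_character_
    qxy <- as.numeric(query)
    nn <- nearest_products(qxy, coords, k = k)
  }
  tops <- lapply(nn$product_id, function(pid) {
    top_ligands(reactions[reactions$product_id == pid, , drop = FALSE], top_n)
  })
  ligs <- character(0)
  for (tl in tops) ligs <- c(ligs, setdiff(tl, ligs))
  shared <- vapply(ligs, function(l) {
    sum(vapply(tops, function(tl) l %in% tl, TRUE)) > 1L
  }, TRUE)
  prov <- do.call(rbind, lapply(seq_along(tops), function(i) {
    pid <- nn$product_id[i]
    rx <- reactions[reactions$product_id == pid, , drop = FALSE]
    data.frame(ligand_id = tops[[i]], neighbor_id = pid,
               yield_percent = rx$yield_percent[match(tops[[i]], rx$ligand_id)],
               stringsAsFactors = FALSE)
  }))
  structure(
    list(query_id = qid, query_coords = qxy, neighbor_ids = nn$product_id,
         neighbor_distance = nn$distance, ligand_ids = ligs,
         shared = unname(shared), provenance = prov),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  marks <- ifelse(x$shared, "**", "*")
  cat(sprintf("neighbors: %s\n", paste(x$neighbor_ids, collapse = ", ")))
  cat(sprintf("recommended ligands: %s\n",
              paste0(x$ligand_ids, marks, collapse = ", ")))
  invisible(x)
}

#' Leave-self-out neighbor hit rate
#'
#' For every product in the dataset: recommend ligands from its `k` nearest
#' neighbors (itself excluded) and score a hit when the product's own top
#' `top_n` ligands intersect the recommendation. The fraction of hits
#' measures how transferable good ligands are between nearby substrate
#' combinations.
#'
#' @param reactions Full reaction table.
#' @param coords Product coordinate table; only products with reactions are
#'   scored.
#' @param k,top_n As in [recommend_ligands()].
#' @return Fraction of products with at least one shared top ligand.
#' @export
neighbor_hit_rate <- function(reactions, coords, k = 2, top_n = 3) {
  pids <- intersect(coords$product_id, unique(reactions$product_id))
  if (length(pids) < k + 1L) {
    stop_invalid("need at least k + 1 = %d products with reactions", k + 1L)
  }
  coords <- coords[coords$product_id %in% pids, , drop = FALSE]
  hits <- vapply(pids, function(pid) {
    rec <- recommend_ligands(pid, reactions, coords, k = k, top_n = top_n)
    own <- top_ligands(reactions[reactions$product_id == pid, , drop = FALSE],
                       top_n)
    length(intersect(own, rec$ligand_ids)) > 0L
  }, TRUE)
  mean(hits)
}
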