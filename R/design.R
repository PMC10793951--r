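# Training-set design: property filtering, chemical-space embedding, Ward
# clustering, representative picking, and cross-cluster product pairing.

#' Filter a candidate library on drug-likeness bounds
#'
#' Retains candidates with `logp < logp_max` and `mol_weight < mw_max` (both
#' strict, matching the "<4.0" / "<400 u" curation convention). Input order
#' is preserved.
#'
#' @param candidates data.frame with `candidate_id`, `logp`, `mol_weight`.
#' @param logp_max,mw_max Strict upper bounds.
#' @return The retained rows.
#' @export
filter_library <- function(candidates, logp_max = 4.0, mw_max = 400) {
  need_cols(candidates, c("candidate_id", "logp", "mol_weight"), "candidates")
  bad <- !is.finite(candidates$logp) | !is.finite(candidates$mol_weight)
  if (any(bad)) {
    stop_invalid("non-finite logp/mol_weight for candidate(s): %s",
                 paste(candidates$candidate_id[bad], collapse = ", "))
  }
  candidates[candidates$logp < logp_max & candidates$mol_weight < mw_max, ,
             drop = FALSE]
}

#' Embed a descriptor matrix into 2-D chemical space
#'
#' Columns are standardized (zero mean, unit variance; constant columns are
#' dropped with a warning) and the first two principal components are
#' returned. PCA is used as the embedding backend: it is deterministic,
#' dependency-free, and preserves the properties the downstream pipeline
#' relies on (identical descriptor rows map to identical coordinates;
#' repeated calls are bitwise identical). The `n_neighbors`/`min_dist`
#' hyperparameters of manifold embeddings are accepted and recorded in
#' `params` for interface compatibility but do not affect PCA.
#'
#' @param descriptor_matrix Numeric matrix or data.frame, n >= 4 rows,
#'   >= 2 non-constant columns, no missing values.
#' @param n_neighbors,min_dist Recorded embedding hyperparameters.
#' @param seed Integer; recorded (PCA itself is deterministic).
#' @param candidate_ids Optional ids; default rownames or `V1..Vn`.
#' @return A `space_embedding`: `candidate_ids`, n x 2 `coords`, `params`,
#'   `seed`.
#' @export
embed_space <- function(descriptor_matrix, n_neighbors = 15, min_dist = 0.1,
                        seed = 42, candidate_ids = NULL) {
  x <- as.matrix(descriptor_matrix)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid("descriptor matrix must be numeric with no missing values")
  }
  if (nrow(x) < 4L) stop_invalid("need at least 4 rows to embed, got %d", nrow(x))
  if (ncol(x) < 2L) stop_invalid("need at least 2 descriptor columns, got %d", ncol(x))
  if (is.null(candidate_ids)) {
    candidate_ids <- rownames(x)
    if (is.null(candidate_ids)) candidate_ids <- paste0("V", seq_len(nrow(x)))
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant descriptor column(s)", sum(sds == 0)),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2L) stop_invalid("fewer than 2 non-constant descriptor columns")
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  # canonical sign: the loading with the largest magnitude is positive
  for (j in 1:2) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(candidate_ids, c("x", "y"))
  structure(
    list(candidate_ids = candidate_ids, coords = coords,
         params = list(method = "pca", n_neighbors = n_neighbors,
                       min_dist = min_dist),
         seed = as.integer(seed)),
    class = "space_embedding"
  )
}

#' Ward clustering of candidates in descriptor space
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance on standardized
#' features). Cluster labels are canonicalized: clusters are numbered
#' `1..k` by decreasing size, ties broken by the smallest member index.
#'
#' @param features Numeric matrix/data.frame (rows = candidates).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param candidate_ids Optional ids.
#' @return A `clustering`: `candidate_ids`, integer `labels` (1..k), `k`.
#' @export
cluster_ward <- function(features, k, candidate_ids = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (k < 1L || k > n) stop_invalid("k must be in [1, %d], got %s", n, k)
  if (is.null(candidate_ids)) {
    candidate_ids <- rownames(x)
    if (is.null(candidate_ids)) candidate_ids <- paste0("V", seq_len(n))
  }
  z <- standardize_cols(x)$z
  labels <- if (k == n) {
    seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    as.integer(stats::cutree(hc, k = k))
  }
  # canonicalize: size descending, ties by smallest member index
  size <- tabulate(labels, nbins = max(labels))
  first <- vapply(seq_along(size), function(l) min(which(labels == l)), 0L)
  ord <- order(-size, first)
  relabel <- integer(length(size))
  relabel[ord] <- seq_along(size)
  structure(
    list(candidate_ids = candidate_ids, labels = relabel[labels], k = as.integer(k)),
    class = "clustering"
  )
}

#' Pick cheap representatives from each cluster
#'
#' From each cluster, the `n_per_cluster` members with the lowest
#' `cost_rank` (price / ease-of-access proxy); ties by lexicographic id.
#' Output ordered by cluster label. Clusters smaller than `n_per_cluster`
#' contribute all members with a warning.
#'
#' @param clustering A `clustering` object.
#' @param cost_rank Named numeric vector (names = candidate ids).
#' @param n_per_cluster Representatives per cluster.
#' @return Character vector of selected candidate ids.
#' @export
pick_representatives <- function(clustering, cost_rank, n_per_cluster = 1) {
  stopifnot(inherits(clustering, "clustering"))
  ids <- clustering$candidate_ids
  missing <- setdiff(ids, names(cost_rank))
  if (length(missing)) {
    stop_invalid("cost_rank missing for candidate(s): %s",
                 paste(missing, collapse = ", "))
  }
  out <- character(0)
  for (cl in seq_len(clustering$k)) {
    members <- ids[clustering$labels == cl]
    if (length(members) < n_per_cluster) {
      warning(sprintf("cluster %d has %d member(s) < n_per_cluster = %d; taking all",
                      cl, length(members), n_per_cluster), call. = FALSE)
    }
    ord <- members[order(cost_rank[members], members)]
    out <- c(out, utils::head(ord, n_per_cluster))
  }
  out
}

#' Pair bromides and amines across chemical-space clusters
#'
#' Greedily selects distinct (bromide, amine) pairs so that the counts of
#' used (bromide-cluster, amine-cluster) combinations stay balanced: no
#' combination is reused before every combination with available pairs has
#' been used as often. Choices among equally covered combinations (and among
#' pairs within a combination) are made by seeded shuffling, so the design is
#' deterministic given the seed.
#'
#' @param bromide_clustering,amine_clustering `clustering` objects whose
#'   `candidate_ids` are bromide/amine ids.
#' @param n_products Number of distinct products to form.
#' @param seed Integer seed.
#' @return Product table: `product_id` (`P001`...), `bromide_id`, `amine_id`.
#' @export
pair_across_clusters <- function(bromide_clustering, amine_clustering,
                                 n_products, seed = 42) {
  stopifnot(inherits(bromide_clustering, "clustering"),
            inherits(amine_clustering, "clustering"))
  bids <- bromide_clustering$candidate_ids
  aids <- amine_clustering$candidate_ids
  total <- length(bids) * length(aids)
  if (n_products < 1L || n_products > total) {
    stop_invalid("n_products must be in [1, %d], got %s", total, n_products)
  }
  pairs <- expand.grid(bi = seq_along(bids), ai = seq_along(aids),
                       KEEP.OUT.ATTRS = FALSE)
  pairs$bc <- bromide_clustering$labels[pairs$bi]
  pairs$ac <- amine_clustering$labels[pairs$ai]
  pairs$combo <- paste(pairs$bc, pairs$ac, sep = ":")
  with_seed(seed, {
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    usage <- integer(0)  # named by combo
    chosen <- integer(0) # row indices into pairs
    avail <- rep(TRUE, nrow(pairs))
    for (step in seq_len(n_products)) {
      combos <- unique(pairs$combo[avail])
      cnt <- vapply(combos, function(cb) {
        u <- usage[cb]; if (is.na(u)) 0L else u
      }, 0L)
      best <- combos[cnt == min(cnt)]
      combo <- if (length(best) == 1L) best else sample(best, 1L)
      idx <- which(avail & pairs$combo == combo)[1L]  # pairs pre-shuffled
      chosen <- c(chosen, idx)
      avail[idx] <- FALSE
      usage[combo] <- if (is.na(usage[combo])) 1L else usage[combo] + 1L
    }
    sel <- pairs[chosen, , drop = FALSE]
    data.frame(
      product_id = sprintf("P%03d", seq_len(n_products)),
      bromide_id = bids[sel$bi],
      amine_id = aids[sel$ai],
      stringsAsFactors = FALSE
    )
  })
}
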