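# Shared fixtures and independent oracles. Everything is generated in code;
# no files ship with the tests.

# per-reaction feature table (d, n_charge, vbur) for a simulated dataset
reaction_features_of <- function(ds) {
  data.frame(
    d = ds$ligands$cu_l_distance[match(ds$reactions$ligand_id,
                                       ds$ligands$ligand_id)],
    n_charge = ds$coords$n_charge[match(ds$reactions$product_id,
                                        ds$coords$product_id)],
    vbur = ds$coords$vbur[match(ds$reactions$product_id,
                                ds$coords$product_id)]
  )
}

# brute-force decision-stump oracle: best achievable accuracy over every
# feature, every midpoint threshold, and both polarities (boundary to the
# "below" side) — independent of fit_stump's search
stump_oracle_accuracy <- function(features, labels) {
  best <- 0
  for (fname in names(features)) {
    x <- features[[fname]]
    v <- sort(unique(x))
    if (length(v) < 2L) next
    for (t in (v[-length(v)] + v[-1L]) / 2) {
      for (pred in list(ifelse(x <= t, "on", "off"),
                        ifelse(x <= t, "off", "on"))) {
        best <- max(best, mean(pred == labels))
      }
    }
  }
  best
}

# exhaustive k-nearest oracle in standardized space (full sort, no shortcuts)
knn_oracle <- function(query, coords, k) {
  mu <- colMeans(coords[, c("n_charge", "vbur")])
  sd <- apply(coords[, c("n_charge", "vbur")], 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(as.matrix(coords[, c("n_charge", "vbur")]), 2, mu), 2, sd, "/")
  zq <- (as.numeric(query) - mu) / sd
  d <- sqrt(rowSums(sweep(z, 2, zq)^2))
  coords$product_id[order(d, coords$product_id)][seq_len(k)]
}

# dense noise-free training set for rule-equivalence checks: feature values
# bracket each planted threshold tightly so recovered midpoints converge
dense_rule_data <- function(n_per_axis = 12, seed = 7) {
  set.seed(seed)
  g <- expand.grid(
    d = c(seq(1.85, 2.06, length.out = n_per_axis), 2.08, 2.09,
          seq(2.1, 2.35, length.out = 4)),
    n_charge = c(seq(-0.9, -0.804, length.out = 6), -0.802,
                 seq(-0.80, -0.72, length.out = 4)),
    vbur = c(seq(29, 33.4, length.out = 6), 33.6, seq(34, 39, length.out = 3))
  )
  g$label <- predict_fixed(g$d, g$n_charge, g$vbur)
  g
}

# uniform-null recommender dataset: yields carry no spatial structure
null_recommender_data <- function(seed, n_products = 30, n_ligands = 50) {
  set.seed(seed)
  coords <- data.frame(
    product_id = sprintf("P%02d", seq_len(n_products)),
    n_charge = runif(n_products, -0.92, -0.7),
    vbur = runif(n_products, 28, 40)
  )
  rx <- expand.grid(product_id = coords$product_id,
                    ligand_id = sprintf("L%02d", seq_len(n_ligands)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rx$yield_percent <- runif(nrow(rx), 0, 100)
  list(reactions = rx, coords = coords)
}

quiet_sim <- function(...) suppressMessages(simulate_dataset(sim_config(...)))
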