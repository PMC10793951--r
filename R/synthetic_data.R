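# Seeded generator of HTE-style Ullmann coupling datasets: a planted
# three-feature rule, label noise, SNAr control backgrounds, and the staged
# screening design (initial panel, active-learning reselection, extension).

#' Simulation configuration
#'
#' Defaults emulate the structure of the staged campaign: 24 initial ligands
#' of which a quarter are active, 12 reselected (all active) ligands, 12
#' initial + 16 extension products that survive controls, 9 products with a
#' planted SNAr background (37 assayed in total), 13% label noise, and the
#' published three-threshold rule as ground truth.
#'
#' @param seed Integer master seed; every generator derives its stream from it.
#' @param n_ligands_initial,n_ligands_reselect Ligand counts per stage.
#' @param n_products_initial,n_products_extension,n_background_products
#'   Product counts: control-passing initial and extension products, and
#'   products with a planted catalysis-free background.
#' @param n_bromides,n_amines Substrate pool sizes.
#' @param frac_active_ligands Fraction of initial ligands drawn active.
#' @param label_noise Probability that a reaction's observed on/off state
#'   contradicts the planted rule.
#' @param rule The planted `fixed_rule`.
#' @param on_yield_range,off_yield_range Yield draw bounds (percent) for
#'   on- and off-labeled reactions.
#' @return A validated `sim_config`.
#' @export
sim_config <- function(seed = 42,
                       n_ligands_initial = 24, n_ligands_reselect = 12,
                       n_products_initial = 12, n_products_extension = 16,
                       n_background_products = 9,
                       n_bromides = 24, n_amines = 12,
                       frac_active_ligands = 0.25, label_noise = 0.13,
                       rule = fixed_rule(),
                       on_yield_range = c(25, 95), off_yield_range = c(0, 18)) {
  counts <- c(n_ligands_initial = n_ligands_initial,
              n_ligands_reselect = n_ligands_reselect,
              n_products_initial = n_products_initial,
              n_products_extension = n_products_extension,
              n_background_products = n_background_products,
              n_bromides = n_bromides, n_amines = n_amines)
  if (any(counts < 0)) stop_invalid("all counts must be >= 0")
  for (fr in c(frac_active_ligands, label_noise)) {
    if (!is.finite(fr) || fr < 0 || fr > 1) {
      stop_invalid("fractions must be in [0, 1]")
    }
  }
  stopifnot(inherits(rule, "fixed_rule"))
  structure(
    c(as.list(counts),
      list(seed = as.integer(seed), frac_active_ligands = frac_active_ligands,
           label_noise = label_noise, rule = rule,
           on_yield_range = on_yield_range, off_yield_range = off_yield_range)),
    class = "sim_config"
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1L, mean, sd)
      if (v > lower && v < upper) { out[i] <- v; break }
    }
  }
  out
}

#' Generate the ligand table
#'
#' Active ligands draw their Cu-L distance from Normal(1.95, 0.04) truncated
#' to (1.8, 2.07) and are tagged anionic (diketone / oxalamide /
#' anilino(oxo)acetic acid classes); inactive ligands draw from
#' Normal(2.18, 0.05) truncated to (2.07, 2.4) and are neutral. The initial
#' cohort contains `round(frac_active_ligands * n_ligands_initial)` active
#' ligands; the reselected cohort is entirely active (the active-learning
#' premise).
#'
#' @param config A `sim_config`.
#' @return Ligand table: `ligand_id`, `cu_l_distance`, `ligand_class`,
#'   `charge_state`, `cohort`.
#' @export
gen_ligands <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n_init <- config$n_ligands_initial
    n_act <- round(config$frac_active_ligands * n_init)
    n_res <- config$n_ligands_reselect
    active_classes <- c("diketone", "oxalamide", "anilino_oxo_acetic_acid")
    d_inact <- rtruncnorm1(n_init - n_act, 2.18, 0.05, 2.07, 2.40)
    d_act <- rtruncnorm1(n_act + n_res, 1.95, 0.04, 1.80, 2.07)
    # initial cohort: inactive ligands first (L01..), active last — the
    # late-plate layout of the screen
    df <- data.frame(
      ligand_id = sprintf("L%02d", seq_len(n_init + n_res)),
      cu_l_distance = c(d_inact, d_act),
      ligand_class = c(sample(c("neutral", "other"), n_init - n_act, TRUE),
                       sample(active_classes, n_act + n_res, TRUE)),
      charge_state = rep(c("neutral", "anionic"), c(n_init - n_act, n_act + n_res)),
      cohort = rep(c("initial", "reselect"), c(n_init, n_res)),
      stringsAsFactors = FALSE
    )
    df
  })
}

#' Generate the substrate pools
#'
#' Bromide buried volumes are Uniform(28, 40) percent and amine nitrogen
#' charges Uniform(-0.92, -0.70) au, so both pools straddle their rule
#' thresholds (33.5%, -0.803 au). With n >= 4 a straddle is guaranteed by
#' resampling one record onto any empty side.
#'
#' @param config A `sim_config`.
#' @return List of `bromides` and `amines` tables.
#' @export
gen_substrates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    vbur <- stats::runif(config$n_bromides, 28, 40)
    nchg <- stats::runif(config$n_amines, -0.92, -0.70)
    vmax <- config$rule$vbur_max
    cmax <- config$rule$n_charge_max
    if (config$n_bromides >= 4L) {
      if (!any(vbur <= vmax)) vbur[1L] <- stats::runif(1L, 28, vmax)
      if (!any(vbur > vmax)) vbur[2L] <- stats::runif(1L, vmax, 40)
    }
    if (config$n_amines >= 4L) {
      if (!any(nchg <= cmax)) nchg[1L] <- stats::runif(1L, -0.92, cmax)
      if (!any(nchg > cmax)) nchg[2L] <- stats::runif(1L, cmax, -0.70)
    }
    list(
      bromides = data.frame(bromide_id = sprintf("B%02d", seq_along(vbur)),
                            vbur = vbur, stringsAsFactors = FALSE),
      amines = data.frame(amine_id = sprintf("A%02d", seq_along(nchg)),
                          n_charge = nchg, stringsAsFactors = FALSE)
    )
  })
}

#' Generate products by cross-cluster pairing
#'
#' Clusters each substrate pool (Ward, on its single node feature, heuristic
#' `k = round(sqrt(n/2))`) and pairs across clusters for balanced coverage.
#' Products are staged: `n_background_products` carry a planted SNAr
#' background (ids `P001`...), then the control-passing initial products
#' (`P100`...) and extension products (`P201`...).
#'
#' @param config A `sim_config`.
#' @param bromides,amines Substrate tables.
#' @return Product table: `product_id`, `bromide_id`, `amine_id`, `stage`
#'   (`background` / `initial` / `extension`).
#' @export
gen_products <- function(config, bromides, amines) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_background_products + config$n_products_initial +
    config$n_products_extension
  kb <- max(1L, round(sqrt(nrow(bromides) / 2)))
  ka <- max(1L, round(sqrt(nrow(amines) / 2)))
  bc <- cluster_ward(bromides["vbur"], kb, candidate_ids = bromides$bromide_id)
  ac <- cluster_ward(amines["n_charge"], ka, candidate_ids = amines$amine_id)
  prod <- pair_across_clusters(bc, ac, n_total, seed = config$seed + 3L)
  stage <- rep(c("background", "initial", "extension"),
               c(config$n_background_products, config$n_products_initial,
                 config$n_products_extension))
  # assign stages to a seeded shuffle of the pairs, then rename by stage
  ord <- with_seed(config$seed + 3L, sample.int(n_total))
  prod <- prod[ord, , drop = FALSE]
  prod$stage <- stage
  prod$product_id <- c(sprintf("P%03d", seq_len(config$n_background_products)),
                       sprintf("P%03d", 99 + seq_len(config$n_products_initial)),
                       sprintf("P%03d", 200 + seq_len(config$n_products_extension)))
  rownames(prod) <- NULL
  prod
}

#' Generate the staged screening plan
#'
#' Stage 1: initial products x initial ligands. Stage 2 (after reselection):
#' initial products x reselected ligands. Stage 3: extension products x the
#' 18-ligand refined panel (active initial ligands + all reselected). With
#' the default counts this is 12x24 + 12x12 + 16x18 = 720 reactions.
#'
#' @param config A `sim_config`.
#' @param products Product table with a `stage` column (background products
#'   are excluded from the plan).
#' @param ligands Ligand table with `cohort` and `cu_l_distance`.
#' @return Plan table: `product_id`, `ligand_id`, `stage` (1-3), no
#'   duplicate pairs.
#' @export
gen_design <- function(config, products, ligands) {
  stopifnot(inherits(config, "sim_config"))
  need_cols(products, c("product_id", "stage"), "products")
  need_cols(ligands, c("ligand_id", "cohort", "cu_l_distance"), "ligands")
  p_init <- products$product_id[products$stage == "initial"]
  p_ext <- products$product_id[products$stage == "extension"]
  l_init <- ligands$ligand_id[ligands$cohort == "initial"]
  l_res <- ligands$ligand_id[ligands$cohort == "reselect"]
  l_act_init <- ligands$ligand_id[ligands$cohort == "initial" &
                                    ligands$cu_l_distance <= config$rule$d_max]
  if (length(p_init) != config$n_products_initial ||
      length(p_ext) != config$n_products_extension ||
      length(l_init) != config$n_ligands_initial ||
      length(l_res) != config$n_ligands_reselect) {
    stop_invalid("product/ligand tables inconsistent with the configuration")
  }
  stage_grid <- function(pids, lids, stage) {
    if (!length(pids) || !length(lids)) return(NULL)
    cbind(expand.grid(product_id = pids, ligand_id = lids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
          stage = stage)
  }
  plan <- rbind(stage_grid(p_init, l_init, 1L),
                stage_grid(p_init, l_res, 2L),
                stage_grid(p_ext, c(l_act_init, l_res), 3L))
  if (is.null(plan)) stop_invalid("screening plan is empty")
  key <- paste(plan$product_id, plan$ligand_id)
  if (anyDuplicated(key)) {
    stop_invalid("screening plan contains duplicate product x ligand pairs")
  }
  rownames(plan) <- NULL
  plan
}

# smooth per-ligand quality in [0.3, 1] over standardized substrate space:
# each ligand gets a random direction and phase, so rankings vary smoothly
# and transfer between nearby products
ligand_quality <- function(ligand_ids, z_nc, z_vb, seed) {
  pars <- with_seed(seed, {
    u <- sort(unique(ligand_ids))
    data.frame(ligand_id = u,
               w1 = stats::runif(length(u), -1, 1),
               w2 = stats::runif(length(u), -1, 1),
               phase = stats::runif(length(u), 0, 2 * pi),
               stringsAsFactors = FALSE)
  })
  i <- match(ligand_ids, pars$ligand_id)
  s <- sin(pars$w1[i] * z_nc + pars$w2[i] * z_vb + pars$phase[i])
  0.3 + 0.7 * (0.5 + 0.5 * s)
}

#' Generate reaction yields from the planted rule
#'
#' The noise-free label of each planned reaction is the planted rule applied
#' to (ligand distance, amine charge, bromide buried volume). Observed labels
#' flip at an overall rate of `label_noise`, but the flips are chemically
#' systematic rather than iid: a rule-off reaction flips to "on"
#' preferentially when its ligand's quality factor is high at that product,
#' and a rule-on reaction flips to "off" preferentially when it is low (the
#' per-class flip probabilities are proportional to quality and rescaled so
#' their class mean equals `label_noise`). On-labeled yields are
#' `20 + (max(on_yield_range) - 20) * q * u` with the per-ligand quality
#' `q in [0.3, 1]` varying smoothly over substrate space and a mild
#' per-reaction jitter `u ~ U(0.85, 1)`, so ligand rankings transfer between
#' neighboring products (the recommender's signal) and an on yield never
#' drops below the 20% cut; off-labeled yields are U(0, 18).
#'
#' @param config A `sim_config`.
#' @param plan Screening plan from [gen_design()].
#' @param ligands,bromides,amines,products Feature tables.
#' @return List: `reactions` (`product_id`, `ligand_id`, `yield_percent`)
#'   and `truth` (adds `label_true`, `label_observed`, `flipped`).
#' @export
gen_yields <- function(config, plan, ligands, bromides, amines, products) {
  stopifnot(inherits(config, "sim_config"))
  coords <- product_feature_coords(products, bromides, amines)
  ip <- match(plan$product_id, coords$product_id)
  il <- match(plan$ligand_id, ligands$ligand_id)
  if (anyNA(ip) || anyNA(il)) stop_invalid("plan references unknown ids")
  d <- ligands$cu_l_distance[il]
  nc <- coords$n_charge[ip]
  vb <- coords$vbur[ip]
  label_true <- predict_fixed(d, nc, vb, config$rule)
  with_seed(config$seed + 4L, {
    n <- nrow(plan)
    zs <- standardize_cols(coords[, c("n_charge", "vbur")])
    q <- ligand_quality(plan$ligand_id, zs$z[ip, 1L], zs$z[ip, 2L],
                        seed = config$seed + 6L)
    # quality-weighted flips, class-rescaled so the mean rate is label_noise
    p_flip <- numeric(n)
    off_t <- label_true == "off"
    if (any(off_t)) {
      w <- q[off_t]^6  # concentrate rescue-flips on the best ligands
      p_flip[off_t] <- config$label_noise * w / mean(w)
    }
    if (any(!off_t)) {
      w <- (1.3 - q[!off_t])^6
      p_flip[!off_t] <- config$label_noise * w / mean(w)
    }
    flip <- stats::runif(n) < pmin(p_flip, 1)
    label_obs <- ifelse(flip, ifelse(label_true == "on", "off", "on"), label_true)
    on_hi <- max(config$on_yield_range)
    u <- stats::runif(n, 0.9, 1)
    y_on <- pmax(20 + (on_hi - 20) * q * u, min(config$on_yield_range))
    y_off <- stats::runif(n, config$off_yield_range[1L],
                          config$off_yield_range[2L])
    yield <- ifelse(label_obs == "on", y_on, y_off)
    reactions <- data.frame(product_id = plan$product_id,
                            ligand_id = plan$ligand_id,
                            yield_percent = yield, stringsAsFactors = FALSE)
    truth <- cbind(reactions,
                   data.frame(label_true = label_true,
                              label_observed = label_obs, flipped = flip,
                              stringsAsFactors = FALSE))
    list(reactions = reactions, truth = truth)
  })
}

#' Generate control experiments
#'
#' Every product gets both controls. Products staged `background` (or, when
#' no `stage` column is present, a seeded sample of
#' `n_background_products`) receive a ligand-free control yield of
#' U(25, 60) — a catalysis-independent SNAr pathway; all other ligand-free
#' controls are <= 5 and the no-ligand-no-copper control is always <= 2.
#'
#' @param config A `sim_config`.
#' @param products Product table.
#' @return Control table: `product_id`, `control_type`, `yield_percent`.
#' @export
gen_controls <- function(config, products) {
  stopifnot(inherits(config, "sim_config"))
  need_cols(products, "product_id", "products")
  n <- nrow(products)
  if (config$n_background_products > n) {
    stop_invalid("n_background_products = %d exceeds %d products",
                 config$n_background_products, n)
  }
  with_seed(config$seed + 5L, {
    bg <- if ("stage" %in% names(products)) {
      products$product_id[products$stage == "background"]
    } else {
      sample(products$product_id, config$n_background_products)
    }
    is_bg <- products$product_id %in% bg
    no_ligand <- ifelse(is_bg, stats::runif(n, 25, 60), stats::runif(n, 0, 5))
    no_both <- stats::runif(n, 0, 2)
    data.frame(
      product_id = rep(products$product_id, 2L),
      control_type = rep(c("no_ligand", "no_ligand_no_cu"), each = n),
      yield_percent = c(no_ligand, no_both),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic campaign
#'
#' Runs the full generator chain and returns every table plus the per-reaction
#' ground truth. Regeneration with an identical configuration is identical.
#'
#' @param config A `sim_config`.
#' @return A `sim_dataset`: `ligands`, `bromides`, `amines`, `products`,
#'   `plan`, `reactions`, `controls`, `truth`, `coords`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ligands <- gen_ligands(config)
  subs <- gen_substrates(config)
  products <- gen_products(config, subs$bromides, subs$amines)
  plan <- gen_design(config, products, ligands)
  yields <- gen_yields(config, plan, ligands, subs$bromides, subs$amines,
                       products)
  controls <- gen_controls(config, products)
  structure(
    list(ligands = ligands, bromides = subs$bromides, amines = subs$amines,
         products = products, plan = plan, reactions = yields$reactions,
         controls = controls, truth = yields$truth,
         coords = product_feature_coords(products, subs$bromides, subs$amines),
         config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("synthetic campaign: %d ligands, %d products (%d background), %d reactions\n",
              nrow(x$ligands), nrow(x$products),
              sum(x$products$stage == "background"), nrow(x$reactions)))
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(ligands = dataset$ligands, bromides = dataset$bromides,
                 amines = dataset$amines, products = dataset$products,
                 reactions = dataset$reactions, controls = dataset$controls,
                 truth = dataset$truth)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table(tables[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
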