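test_that("gen_ligands plants the bimodal distance structure", {
  cfg <- sim_config(seed = 14)
  lig <- gen_ligands(cfg)
  expect_equal(nrow(lig), 36)
  init <- lig[lig$cohort == "initial", ]
  expect_equal(sum(init$cu_l_distance < 2.07), 6)  # frac_active 0.25 of 24
  expect_true(all(lig$cu_l_distance > 1.8 & lig$cu_l_distance < 2.4))
  active <- lig$cu_l_distance < 2.07
  expect_true(all(lig$charge_state[active] == "anionic"))
  expect_true(all(lig$cohort[lig$cohort == "reselect"] == "reselect" &
                    lig$cu_l_distance[lig$cohort == "reselect"] < 2.07))
  expect_identical(gen_ligands(cfg), lig)  # seed determinism
  none <- gen_ligands(sim_config(seed = 14, frac_active_ligands = 0,
                                 n_ligands_reselect = 0))
  expect_true(all(none$cu_l_distance > 2.07))
})

test_that("gen_substrates straddles both thresholds", {
  for (s in 1:5) {
    subs <- gen_substrates(sim_config(seed = s, n_bromides = 4, n_amines = 4))
    expect_true(any(subs$bromides$vbur <= 33.5) && any(subs$bromides$vbur > 33.5))
    expect_true(any(subs$amines$n_charge <= -0.803) &&
                  any(subs$amines$n_charge > -0.803))
  }
  one <- gen_substrates(sim_config(seed = 1, n_bromides = 1, n_amines = 1))
  expect_equal(nrow(one$bromides), 1)
})

test_that("the staged design reproduces the 720-reaction arithmetic", {
  cfg <- sim_config(seed = 2)
  ds <- quiet_sim(seed = 2)
  plan <- ds$plan
  expect_equal(nrow(plan), 720)  # 12x24 + 12x12 + 16x18
  expect_equal(as.vector(table(plan$stage)), c(288L, 144L, 288L))
  expect_equal(anyDuplicated(paste(plan$product_id, plan$ligand_id)), 0L)
  # stage 3 uses the 18-ligand refined panel
  s3 <- unique(plan$ligand_id[plan$stage == 3])
  expect_length(s3, 18)
  d3 <- ds$ligands$cu_l_distance[match(s3, ds$ligands$ligand_id)]
  expect_true(all(d3 <= 2.07))

  no_ext <- quiet_sim(seed = 2, n_products_extension = 0)
  expect_equal(nrow(no_ext$plan), 432)  # stages 1-2 only

  expect_error(gen_design(cfg, ds$products[1:3, ], ds$ligands),
               class = "cuhte_validation_error")
})

test_that("yields obey the planted rule, noise level, and yield bands", {
  ds0 <- quiet_sim(seed = 8, label_noise = 0)
  labels <- label_outcome(ds0$reactions$yield_percent)
  feats <- reaction_features_of(ds0)
  expect_identical(labels, predict_fixed(feats$d, feats$n_charge, feats$vbur))
  expect_identical(labels, ds0$truth$label_true)

  for (s in 1:5) {
    ds <- quiet_sim(seed = s)
    fl <- mean(ds$truth$flipped)
    expect_gte(fl, 0.10)
    expect_lte(fl, 0.16)
    on <- ds$truth$label_observed == "on"
    expect_true(all(ds$reactions$yield_percent[on] > 20))
    expect_true(all(ds$reactions$yield_percent[!on] <= 18))
  }

  # all-unfavorable substrates -> everything off at zero noise
  cfg <- sim_config(seed = 3, label_noise = 0)
  subs <- gen_substrates(cfg)
  subs$amines$n_charge <- abs(subs$amines$n_charge) * 0 - 0.70  # unfavorable
  lig <- gen_ligands(cfg)
  prod <- gen_products(cfg, subs$bromides, subs$amines)
  plan <- gen_design(cfg, prod, lig)
  y <- gen_yields(cfg, plan, lig, subs$bromides, subs$amines, prod)
  expect_true(all(y$truth$label_observed == "off"))
})

test_that("controls plant exactly the background products", {
  ds <- quiet_sim(seed = 10)
  expect_equal(nrow(ds$controls), 2 * nrow(ds$products))
  res <- suppressMessages(apply_control_filter(ds$products, ds$controls))
  expect_equal(nrow(res$passing), 28)  # 37 - 9
  expect_setequal(res$failed$product_id,
                  ds$products$product_id[ds$products$stage == "background"])
  nlnc <- ds$controls$yield_percent[ds$controls$control_type == "no_ligand_no_cu"]
  expect_true(all(nlnc <= 2))

  zero <- quiet_sim(seed = 10, n_background_products = 0)
  res0 <- apply_control_filter(zero$products, zero$controls)
  expect_equal(nrow(res0$failed), 0)

  cfg_bad <- sim_config(seed = 1, n_background_products = 5)
  expect_error(gen_controls(cfg_bad, data.frame(product_id = c("P1", "P2"))),
               class = "cuhte_validation_error")
})

test_that("full dataset regeneration is byte-identical", {
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(quiet_sim(seed = 20), d1)
  write_dataset(quiet_sim(seed = 20), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(quiet_sim(seed = 99))
  expect_identical(.Random.seed, before)
})
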