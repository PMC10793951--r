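test_that("ligand activity is the max-yield rule", {
  rx <- data.frame(
    product_id = rep(c("P1", "P2"), each = 3),
    ligand_id = rep(c("L1", "L2", "L3"), 2),
    yield_percent = c(5, 0, 40, 12, 19.9, 31)
  )
  act <- ligand_activity_labels(rx)
  expect_identical(act$label[act$ligand_id == "L1"], "off")  # max 12
  expect_identical(act$label[act$ligand_id == "L2"], "off")  # max 19.9
  expect_identical(act$label[act$ligand_id == "L3"], "on")
})

test_that("only planted-active ligands exceed the cut at zero noise", {
  ds <- quiet_sim(seed = 9, label_noise = 0)
  act <- ligand_activity_labels(ds$reactions)
  planted <- ds$ligands$ligand_id[ds$ligands$cu_l_distance <= 2.07]
  # an active ligand is on only if some tested product also has favorable
  # substrates; inactive ligands can never be on
  expect_true(all(act$ligand_id[act$label == "on"] %in% planted))
  expect_equal(sum(!act$ligand_id %in% planted & act$label == "on"), 0)
})

test_that("fit_stump finds the exact separator with midpoint threshold", {
  feats <- data.frame(d = c(1.9, 2.0, 2.1, 2.2))
  st <- fit_stump(feats, c("on", "on", "off", "off"))
  expect_equal(st$threshold, 2.05)
  expect_identical(st$polarity, "on_if_below")
  expect_equal(st$train_metrics$accuracy, 1)
  expect_error(fit_stump(feats, rep("on", 4)), class = "cuhte_validation_error")
})

test_that("stump search equals the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    feats <- as.data.frame(matrix(rnorm(n * 3), n, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
    labels <- sample(c("on", "off"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("on", "off")
    st <- fit_stump(feats, labels)
    expect_equal(st$train_metrics$accuracy, stump_oracle_accuracy(feats, labels),
                 info = sprintf("table %d", i))
  }
})

test_that("noisy majority data never drops below the majority bound", {
  set.seed(13)
  feats <- data.frame(x = rnorm(20))
  labels <- rep(c("on", "off"), 10)
  st <- fit_stump(feats, labels)
  expect_gte(st$train_metrics$accuracy, 0.5)
})

test_that("a 24-ligand table with one planted overlap reproduces 0.96/0.95", {
  # 6 active ligands below 2.07 plus one inactive ligand planted below the
  # cut (the misclassified case): best stump gets 23/24
  set.seed(4)
  d <- c(runif(6, 1.88, 2.02), 1.98, runif(17, 2.09, 2.35))
  labels <- rep(c("on", "off"), c(6, 18))
  st <- fit_stump(data.frame(d = d), labels)
  expect_identical(st$feature_name, "d")
  expect_equal(st$train_metrics$accuracy, 23 / 24)
  expect_equal(round(st$train_metrics$accuracy, 2), 0.96)
  expect_equal(round(st$train_metrics$f1, 2), 0.92)
  expect_equal(sum(predict_stump(st, data.frame(d = d)) != labels), 1)
})

test_that("planted-threshold recovery is within half the gap", {
  set.seed(21)
  for (gap in c(0.04, 0.1)) {
    lo <- runif(8, 1.9, 2.07 - gap / 2)
    hi <- runif(8, 2.07 + gap / 2, 2.3)
    st <- fit_stump(data.frame(d = c(lo, hi)), rep(c("on", "off"), each = 8))
    expect_lte(abs(st$threshold - 2.07), gap / 2 + 1e-12)
  }
})

test_that("predict_stump applies the 2.07 A rule with boundary below", {
  st <- structure(list(feature_name = "d", threshold = 2.07,
                       polarity = "on_if_below", margin = 0.01),
                  class = "stump")
  expect_identical(predict_stump(st, data.frame(d = c(1.95, 2.30, 2.07))),
                   c("on", "off", "on"))
  expect_error(predict_stump(st, data.frame(x = 1)),
               class = "cuhte_validation_error")
})

test_that("select_candidates returns predicted-active sorted by margin", {
  st <- structure(list(feature_name = "cu_l_distance", threshold = 2.07,
                       polarity = "on_if_below", margin = 0.01),
                  class = "stump")
  set.seed(31)
  cand <- data.frame(ligand_id = sprintf("L%02d", 1:30),
                     cu_l_distance = c(runif(12, 1.85, 2.05),
                                       runif(18, 2.10, 2.35)))
  sel <- select_candidates(cand, st)
  expect_equal(nrow(sel), 12)
  expect_true(all(sel$cu_l_distance <= 2.07))
  margins <- abs(sel$cu_l_distance - 2.07)
  expect_true(all(diff(margins) <= 0))  # nearest-to-cut last
  # re-screening the selected set returns all of them
  expect_equal(nrow(select_candidates(sel, st)), nrow(sel))
  none <- data.frame(ligand_id = "L1", cu_l_distance = 2.3)
  expect_equal(nrow(select_candidates(none, st)), 0)
  all_in <- data.frame(ligand_id = c("L1", "L2"), cu_l_distance = c(1.9, 2.0))
  expect_equal(nrow(select_candidates(all_in, st)), 2)
})
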