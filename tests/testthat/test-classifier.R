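test_that("predict_fixed matches the 8-corner truth table", {
  eps <- 1e-6
  corners <- expand.grid(
    d = c(2.07 - eps, 2.07 + eps),
    n_charge = c(-0.803 - eps, -0.803 + eps),
    vbur = c(33.5 - eps, 33.5 + eps)
  )
  pred <- predict_fixed(corners$d, corners$n_charge, corners$vbur)
  favorable <- corners$d < 2.07 & corners$n_charge < -0.803 & corners$vbur < 33.5
  expect_identical(pred, ifelse(favorable, "on", "off"))
  expect_equal(sum(pred == "on"), 1L)  # only the all-favorable corner
})

test_that("equality at every threshold is on", {
  expect_identical(predict_fixed(2.07, -0.803, 33.5), "on")
  expect_identical(predict_fixed(1.95, -0.85, 30), "on")
  expect_identical(predict_fixed(2.20, -0.85, 30), "off")
  expect_identical(predict_fixed(1.95, -0.75, 30), "off")
  expect_identical(predict_fixed(1.95, -0.85, 35), "off")
  expect_error(predict_fixed(NA_real_, -0.85, 30), "d",
               class = "cuhte_validation_error")
})

test_that("predict_fixed is monotone in each feature", {
  set.seed(17)
  for (i in 1:50) {
    d <- runif(1, 1.8, 2.4); nc <- runif(1, -0.92, -0.7); vb <- runif(1, 28, 40)
    base <- predict_fixed(d, nc, vb)
    if (base == "on") {
      # improving any feature can never switch on -> off
      expect_identical(predict_fixed(d - 0.1, nc, vb), "on")
      expect_identical(predict_fixed(d, nc - 0.05, vb), "on")
      expect_identical(predict_fixed(d, nc, vb - 2), "on")
    }
  }
})

test_that("train_tree recovers the planted rule on dense noise-free data", {
  g <- dense_rule_data()
  model <- train_tree(g[, 1:3], g$label, seed = 11)
  expect_equal(model$test_metrics$accuracy, 1)
  expect_setequal(model$nodes$feature_name, c("d", "n_charge", "vbur"))
  # equivalence oracle on an independent held-out grid
  set.seed(99)
  grid <- data.frame(d = runif(500, 1.85, 2.35),
                     n_charge = runif(500, -0.9, -0.72),
                     vbur = runif(500, 29, 39))
  expect_equal(mean(predict(model, grid) ==
                      predict_fixed(grid$d, grid$n_charge, grid$vbur)), 1)
})

test_that("the node budget caps internal nodes, not depth", {
  g <- dense_rule_data()
  m1 <- train_tree(g[, 1:3], g$label, max_nodes = 1, seed = 1)
  expect_equal(nrow(m1$nodes), 1)
  m3 <- train_tree(g[, 1:3], g$label, max_nodes = 3, seed = 1)
  expect_lte(nrow(m3$nodes), 3)
})

test_that("train_tree validates degenerate inputs", {
  g <- dense_rule_data()
  expect_error(train_tree(g[1:10, 1:3], g$label[1:10]),
               class = "cuhte_validation_error")  # n < 20
  expect_error(train_tree(g[, 1:3], rep("on", nrow(g))),
               class = "cuhte_validation_error")  # constant labels
})

test_that("cross_validate is stratified, deterministic, and exactly averaged", {
  ds <- quiet_sim(seed = 6)
  feats <- reaction_features_of(ds)
  labels <- label_outcome(ds$reactions$yield_percent)
  cv1 <- cross_validate(feats, labels, folds = 4, seed = 2)
  cv2 <- cross_validate(feats, labels, folds = 4, seed = 2)
  expect_identical(cv1, cv2)
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_accuracy), tolerance = 1e-12)
  expect_length(cv1$fold_accuracy, 4)

  # noise-free planted data -> mean accuracy 1
  g <- dense_rule_data()
  expect_equal(cross_validate(g[, 1:3], g$label, folds = 4, seed = 3)$mean_accuracy, 1)
})

test_that("pure-noise labels cross-validate near chance", {
  set.seed(23)
  feats <- data.frame(d = runif(200, 1.8, 2.4),
                      n_charge = runif(200, -0.92, -0.7),
                      vbur = runif(200, 28, 40))
  labels <- rep(c("on", "off"), 100)
  cv <- cross_validate(feats, labels, folds = 4, seed = 5)
  expect_gte(cv$mean_accuracy, 0.40)
  expect_lte(cv$mean_accuracy, 0.60)
})

test_that("leave-one-out runs with denominator n", {
  g <- dense_rule_data()
  idx <- c(which(g$label == "on")[1:8], which(g$label == "off")[1:16])
  sub <- g[idx, ]
  cv <- cross_validate(sub[, 1:3], sub$label, folds = 24, seed = 1)
  expect_length(cv$fold_accuracy, 24)
  expect_true(all(cv$fold_accuracy %in% c(0, 1)))
})

test_that("tree trained on simulator data behaves per the noise level", {
  ds <- quiet_sim(seed = 4, label_noise = 0)
  m <- train_tree(reaction_features_of(ds),
                  label_outcome(ds$reactions$yield_percent), seed = 4)
  expect_equal(m$test_metrics$accuracy, 1)

  ds13 <- quiet_sim(seed = 4)
  m13 <- train_tree(reaction_features_of(ds13),
                    label_outcome(ds13$reactions$yield_percent), seed = 4)
  expect_gte(m13$test_metrics$accuracy, 0.80)
  expect_lte(m13$test_metrics$accuracy, 0.92)
})
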