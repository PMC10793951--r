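test_that("entropy_binary matches the closed form and its symmetry", {
  expect_equal(entropy_binary(0), 0)
  expect_equal(entropy_binary(1), 0)
  expect_equal(entropy_binary(0.5), 2 * 0.5 * log10(2))
  expect_equal(entropy_binary(0.5), 0.30103, tolerance = 1e-5)
  # the 18-ligand worked example: 2/18 on -> 15% uncertainty
  expect_equal(entropy_binary(2 / 18), 0.1515, tolerance = 1e-4)
  expect_equal(round(100 * entropy_binary(2 / 18)), 15)
  for (p in seq(0, 1, 0.1)) {
    expect_equal(entropy_binary(p), entropy_binary(1 - p), tolerance = 1e-12)
  }
  # alternative bases remain available
  expect_equal(entropy_binary(0.5, base = 2), 1)
  expect_error(entropy_binary(1.2), class = "cuhte_validation_error")
})

test_that("product_confidence reproduces the 85% worked example", {
  outcomes <- rep(c("on", "off"), c(2, 16))
  pt <- product_confidence(outcomes, "off", coords = c(-0.78, 31),
                           product_id = "P123")
  expect_equal(pt$n_ligands, 18)
  expect_equal(pt$n_on, 2)
  expect_equal(round(100 * pt$confidence), 85)
  expect_equal(round(100 * pt$uncertainty), 15)
  expect_equal(pt$signed_score, -pt$confidence)  # predicted off
  expect_equal(pt$confidence, 1 - pt$uncertainty)

  # order invariance
  set.seed(8)
  pt2 <- product_confidence(sample(outcomes), "off", coords = c(-0.78, 31))
  expect_equal(pt2$confidence, pt$confidence)

  expect_equal(product_confidence(rep("off", 18), "off", c(0, 0))$confidence, 1)
  expect_equal(product_confidence(rep(c("on", "off"), 9), "on",
                                  c(0, 0))$confidence,
               1 - log10(2), tolerance = 1e-12)
  expect_error(product_confidence(rep("off", 5), "off", c(0, 0)),
               "min_ligands", class = "cuhte_validation_error")
})

test_that("confidence floor holds on a full panel grid", {
  for (n_on in 0:18) {
    pt <- product_confidence(rep(c("on", "off"), c(n_on, 18 - n_on)),
                             "on", c(0, 0))
    expect_gte(pt$confidence, 1 - log10(2) - 1e-12)
    expect_lte(pt$confidence, 1)
  }
})

test_that("RBF interpolation is exact at the data with zero smoothing", {
  set.seed(42)
  pts <- data.frame(n_charge = runif(10, -0.9, -0.7), vbur = runif(10, 28, 40),
                    signed_score = runif(10, -1, 1))
  for (kern in c("thin_plate", "multiquadric", "gaussian")) {
    map <- fit_confidence_map(pts, kernel = kern)
    got <- query_confidence_map(map, pts$n_charge, pts$vbur)
    expect_lt(max(abs(got$raw_score - pts$signed_score)), 1e-6)
  }
})

test_that("thin-plate map reproduces constants everywhere", {
  set.seed(5)
  pts <- data.frame(n_charge = runif(12, -0.9, -0.7), vbur = runif(12, 28, 40),
                    signed_score = 0.7)
  map <- fit_confidence_map(pts)
  g <- expand.grid(n_charge = seq(-0.9, -0.7, length.out = 20),
                   vbur = seq(28, 40, length.out = 20))
  got <- query_confidence_map(map, g$n_charge, g$vbur)
  expect_lt(max(abs(got$raw_score - 0.7)), 1e-6)
})

test_that("sign mixing attenuates the interpolated score between points", {
  pts <- data.frame(n_charge = c(-0.85, -0.75, -0.80, -0.80),
                    vbur = c(30, 30, 28, 32),
                    signed_score = c(0.9, -0.9, 0.2, -0.2))
  map <- fit_confidence_map(pts)
  mid <- query_confidence_map(map, -0.80, 30)
  expect_lt(abs(mid$raw_score), 0.9)
})

test_that("map validates inputs and flags extrapolation", {
  pts <- data.frame(n_charge = c(-0.85, -0.75), vbur = c(30, 31),
                    signed_score = c(0.9, -0.9))
  expect_error(fit_confidence_map(pts), class = "cuhte_validation_error")

  set.seed(2)
  pts <- data.frame(n_charge = runif(8, -0.9, -0.7), vbur = runif(8, 28, 40),
                    signed_score = runif(8, -1, 1))
  map <- fit_confidence_map(pts)
  expect_warning(res <- query_confidence_map(map, -0.8, 400), "3 sd")
  expect_true(res$extrapolated)
  expect_lte(res$confidence, 1)  # clipping

  dup <- rbind(pts, pts[1, ])
  expect_warning(fit_confidence_map(dup), "duplicate")

  # collinear points fall back to multiquadric
  lin <- data.frame(n_charge = seq(-0.9, -0.7, length.out = 5), vbur = 30,
                    signed_score = c(0.1, 0.5, -0.2, 0.3, 0.9))
  expect_warning(m2 <- fit_confidence_map(lin), "multiquadric")
  expect_identical(m2$kernel, "multiquadric")
})

test_that("confidence_points builds the refined-panel table from a dataset", {
  ds <- quiet_sim(seed = 12)
  pts <- suppressWarnings(suppressMessages(
    confidence_points(ds$reactions, ds$products, ds$bromides, ds$amines,
                      ds$ligands)
  ))
  expect_equal(pts$n_ligands, rep(18, nrow(pts)))  # refined active panels
  expect_true(all(pts$confidence >= 1 - log10(2) - 1e-12))
  expect_true(all(sign(pts$signed_score) ==
                    ifelse(pts$predicted == "on", 1, -1)))
  expect_equal(pts$confidence, 1 - pts$uncertainty, tolerance = 1e-12)
  # map over the dataset interpolates its own points exactly
  map <- fit_confidence_map(pts)
  got <- query_confidence_map(map, pts$n_charge, pts$vbur)
  expect_lt(max(abs(got$raw_score - pts$signed_score)), 1e-6)
})
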