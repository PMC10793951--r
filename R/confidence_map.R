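# Prediction confidence from the information entropy of per-product ligand
# outcomes, and its RBF-interpolated map over substrate feature space.

#' Binary information entropy
#'
#' `-p*log(p, base) - (1-p)*log(1-p, base)` with `0*log(0) = 0`. Base 10 is
#' the default: it places the maximum (p = 1/2) at `log10(2) ~ 0.301`, so
#' confidence `1 - entropy` lives in `[1 - log10(2), 1] ~ [0.699, 1]` and an
#' 18-ligand panel with 2 unexpected outcomes gives the 15%/85%
#' uncertainty/confidence worked example.
#'
#' @param p Fraction(s) in `[0, 1]`.
#' @param base Logarithm base (10 default; 2 and e are common alternatives).
#' @return Entropy value(s).
#' @examples
#' entropy_binary(0.5)     # 0.30103
#' entropy_binary(2 / 18)  # 0.1515 -> uncertainty "15%"
#' @export
entropy_binary <- function(p, base = 10) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("p must be in [0, 1]")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log(q, base = base))
  term(p) + term(1 - p)
}

#' Prediction confidence for one product
#'
#' Treats the on/off outcomes of the ligands tested against a product as a
#' Bernoulli sample; the uncertainty is the (base-10) information entropy of
#' the on-fraction and the confidence its complement. The signed score is
#' `+confidence` when the model predicts the product "on" and `-confidence`
#' when "off" — the quantity the confidence map interpolates.
#'
#' @param outcomes Character vector of `"on"`/`"off"`, one per tested ligand.
#' @param predicted Model prediction for the product (`"on"`/`"off"`).
#' @param coords Numeric `c(n_charge, vbur)` pair locating the product in
#'   substrate feature space.
#' @param product_id Identifier.
#' @param min_ligands Minimum panel size for a meaningful entropy estimate.
#' @param base Entropy base.
#' @return A `confidence_point`: `product_id`, `coords`, `predicted`,
#'   `n_ligands`, `n_on`, `uncertainty`, `confidence`, `signed_score`.
#' @examples
#' pt <- product_confidence(rep(c("on", "off"), c(2, 16)), "off",
#'                          coords = c(-0.78, 31))
#' round(100 * pt$confidence)  # 85
#' @export
product_confidence <- function(outcomes, predicted, coords,
                               product_id = NA_character_, min_ligands = 6,
                               base = 10) {
  outcomes <- check_labels(outcomes, "outcomes")
  predicted <- check_labels(predicted, "predicted")
  stopifnot(length(predicted) == 1L)
  n <- length(outcomes)
  if (n < min_ligands) {
    stop_invalid("need at least min_ligands = %d tested ligands, got %d",
                 min_ligands, n)
  }
  if (length(coords) != 2L || any(!is.finite(coords))) {
    stop_invalid("coords must be a finite (n_charge, vbur) pair")
  }
  n_on <- sum(outcomes == "on")
  u <- entropy_binary(n_on / n, base = base)
  conf <- 1 - u
  structure(
    list(product_id = product_id,
         coords = stats::setNames(as.numeric(coords), c("n_charge", "vbur")),
         predicted = predicted, n_ligands = n, n_on = n_on,
         uncertainty = u, confidence = conf,
         signed_score = if (predicted == "on") conf else -conf),
    class = "confidence_point"
  )
}

#' @export
print.confidence_point <- function(x, ...) {
  cat(sprintf("%s: predicted %s, %d/%d ligands on, confidence %.0f%% (uncertainty %.0f%%)\n",
              x$product_id, x$predicted, x$n_on, x$n_ligands,
              100 * x$confidence, 100 * x$uncertainty))
  invisible(x)
}

#' Confidence points for every product in a dataset
#'
#' For each product with at least `min_ligands` tested ligands, labels its
#' reactions at `threshold`, takes the model (or fixed-rule) prediction at
#' the product's median ligand — here: the rule applied with each tested
#' ligand's distance, majority vote — and computes the confidence point.
#'
#' @param reactions,products,bromides,amines,ligands Validated tables.
#' @param rule A `fixed_rule` or `tree_model` used for the per-product
#'   prediction (majority over the product's tested ligands).
#' @param threshold On/off yield cut.
#' @param min_ligands Minimum panel size; smaller products are skipped with a
#'   warning.
#' @param base Entropy base.
#' @param active_d_max If non-`NULL`, restrict each product's panel to
#'   ligands with `cu_l_distance <= active_d_max` before counting outcomes —
#'   the refined favorable-ligand panel. With all panel distances favorable,
#'   the product-level prediction reduces to the two substrate features, the
#'   axes of the map. Default 2.07.
#' @return data.frame: `product_id`, `n_charge`, `vbur`, `predicted`,
#'   `n_ligands`, `n_on`, `uncertainty`, `confidence`, `signed_score`.
#' @export
confidence_points <- function(reactions, products, bromides, amines, ligands,
                              rule = fixed_rule(), threshold = 20,
                              min_ligands = 6, base = 10, active_d_max = 2.07) {
  need_cols(reactions, c("product_id", "ligand_id", "yield_percent"), "reactions")
  need_cols(ligands, c("ligand_id", "cu_l_distance"), "ligands")
  coords <- product_feature_coords(products, bromides, amines)
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(coords))) {
    pid <- coords$product_id[i]
    rx <- reactions[reactions$product_id == pid, , drop = FALSE]
    d <- ligands$cu_l_distance[match(rx$ligand_id, ligands$ligand_id)]
    if (anyNA(d)) stop_invalid("unresolvable ligand_id for product %s", pid)
    if (!is.null(active_d_max)) {
      keep <- d <= active_d_max
      rx <- rx[keep, , drop = FALSE]
      d <- d[keep]
    }
    if (nrow(rx) < min_ligands) {
      if (nrow(rx) > 0L) skipped <- c(skipped, pid)
      next
    }
    feats <- data.frame(d = d, n_charge = coords$n_charge[i],
                        vbur = coords$vbur[i])
    pred <- if (inherits(rule, "tree_model")) {
      predict(rule, feats)
    } else {
      predict_fixed(feats$d, feats$n_charge, feats$vbur, rule)
    }
    pred_prod <- if (sum(pred == "on") > length(pred) / 2) "on" else "off"
    pt <- product_confidence(label_outcome(rx$yield_percent, threshold),
                             pred_prod,
                             coords = c(coords$n_charge[i], coords$vbur[i]),
                             product_id = pid, min_ligands = min_ligands,
                             base = base)
    rows[[length(rows) + 1L]] <- data.frame(
      product_id = pid, n_charge = pt$coords[["n_charge"]],
      vbur = pt$coords[["vbur"]], predicted = pt$predicted,
      n_ligands = pt$n_ligands, n_on = pt$n_on, uncertainty = pt$uncertainty,
      confidence = pt$confidence, signed_score = pt$signed_score,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d product(s) with fewer than %d tested ligands: %s",
                    length(skipped), min_ligands,
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  do.call(rbind, rows)
}

# RBF kernels on pairwise distance matrices ----------------------------------

rbf_phi <- function(r, kernel, eps = 1) {
  switch(kernel,
    thin_plate = {
      out <- r
      pos <- r > 0
      out[pos] <- r[pos]^2 * log(r[pos])
      out[!pos] <- 0
      out
    },
    multiquadric = sqrt(r^2 + eps^2),
    gaussian = exp(-(r / eps)^2),
    stop_invalid("unknown RBF kernel '%s'", kernel)
  )
}

cross_dist <- function(a, b) {
  # Euclidean distances between rows of a (n x 2) and b (m x 2)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit an RBF-interpolated confidence map
#'
#' Interpolates per-product signed confidence scores over the standardized
#' (n_charge, vbur) plane with radial basis functions — the natural choice
#' for scattered data with no mesh. The default thin-plate kernel carries a
#' linear polynomial tail, so with zero smoothing the interpolant reproduces
#' every data point exactly and is exact on constants. Duplicate standardized
#' coordinates are averaged with a warning; a singular thin-plate system
#' (e.g. collinear points) falls back to the multiquadric kernel with a
#' warning.
#'
#' @param points data.frame with `n_charge`, `vbur`, `signed_score` (as from
#'   [confidence_points()]), or a list of `confidence_point` objects.
#' @param kernel `"thin_plate"`, `"multiquadric"`, or `"gaussian"`.
#' @param smoothing Nonnegative ridge added to the kernel diagonal; 0 gives
#'   exact interpolation.
#' @return A `confidence_map`: `points`, `kernel`, `smoothing`,
#'   `axis_scaling`, and solved weights.
#' @export
fit_confidence_map <- function(points, kernel = c("thin_plate", "multiquadric",
                                                  "gaussian"), smoothing = 0) {
  kernel <- match.arg(kernel)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, TRUE, "confidence_point"))) {
    points <- do.call(rbind, lapply(points, function(p) {
      data.frame(product_id = p$product_id, n_charge = p$coords[["n_charge"]],
                 vbur = p$coords[["vbur"]], signed_score = p$signed_score,
                 stringsAsFactors = FALSE)
    }))
  }
  need_cols(points, c("n_charge", "vbur", "signed_score"), "points")
  if (nrow(points) < 3L) {
    stop_invalid("need at least 3 confidence points, got %d", nrow(points))
  }
  if (smoothing < 0) stop_invalid("smoothing must be >= 0")
  std <- standardize_cols(points[, c("n_charge", "vbur")])
  z <- std$z
  f <- points$signed_score
  key <- paste(signif(z[, 1], 12), signif(z[, 2], 12))
  if (anyDuplicated(key)) {
    warning("duplicate coordinates; averaging their signed scores", call. = FALSE)
    agg <- lapply(split(seq_len(nrow(z)), key), function(ix) {
      list(z = z[ix[1L], , drop = FALSE], f = mean(f[ix]))
    })
    z <- do.call(rbind, lapply(agg, `[[`, "z"))
    f <- vapply(agg, `[[`, 0, "f")
  }
  fit <- tryCatch(
    rbf_solve(z, f, kernel, smoothing),
    error = function(e) {
      if (kernel == "multiquadric") stop(e)
      warning(sprintf("singular %s system; falling back to multiquadric", kernel),
              call. = FALSE)
      rbf_solve(z, f, "multiquadric", smoothing)
    }
  )
  structure(
    list(points = points, kernel = fit$kernel, smoothing = smoothing,
         axis_scaling = list(center = std$center, scale = std$scale),
         centers = z, weights = fit$w, poly = fit$c, eps = fit$eps),
    class = "confidence_map"
  )
}

rbf_solve <- function(z, f, kernel, smoothing) {
  n <- nrow(z)
  eps <- 1
  if (kernel %in% c("multiquadric", "gaussian") && n > 1L) {
    d <- cross_dist(z, z)
    eps <- mean(apply(d + diag(Inf, n), 1L, min))  # mean nearest-neighbor dist
    if (!is.finite(eps) || eps <= 0) eps <- 1
  }
  K <- rbf_phi(cross_dist(z, z), kernel, eps) + diag(smoothing, n)
  if (kernel == "thin_plate") {
    P <- cbind(1, z)  # linear tail: exact on constants and planes
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
    sol <- solve(A, c(f, numeric(3L)))
    list(kernel = kernel, w = sol[seq_len(n)], c = sol[n + 1:3], eps = eps)
  } else {
    list(kernel = kernel, w = solve(K, f), c = NULL, eps = eps)
  }
}

#' Query the confidence map at substrate coordinates
#'
#' Evaluates the interpolant at (n_charge, vbur), standardized with the map's
#' axis scaling. The magnitude is clipped to `[0, 1]`; the class is "on" for
#' a positive score and "off" for a negative one, with `|score| < 1e-9`
#' flagged ambiguous. Queries more than 3 standard deviations outside the
#' training cloud on either axis are flagged `extrapolated`.
#'
#' @param map A `confidence_map`.
#' @param n_charge,vbur Query coordinates (vectors of equal length).
#' @return data.frame: `n_charge`, `vbur`, `signed_score` (clipped),
#'   `raw_score`, `predicted` (`NA` when ambiguous), `confidence`,
#'   `extrapolated`, `ambiguous`.
#' @export
query_confidence_map <- function(map, n_charge, vbur) {
  stopifnot(inherits(map, "confidence_map"))
  if (length(n_charge) != length(vbur)) stop_invalid("coordinate length mismatch")
  check_numeric_finite(n_charge, "n_charge")
  check_numeric_finite(vbur, "vbur")
  q <- cbind(n_charge, vbur)
  zq <- sweep(sweep(q, 2L, map$axis_scaling$center, "-"),
              2L, map$axis_scaling$scale, "/")
  Kq <- rbf_phi(cross_dist(zq, map$centers), map$kernel, map$eps)
  raw <- drop(Kq %*% map$weights)
  if (!is.null(map$poly)) raw <- raw + drop(cbind(1, zq) %*% map$poly)
  clipped <- pmax(pmin(raw, 1), -1)
  ambiguous <- abs(raw) < 1e-9
  extrapolated <- abs(zq[, 1]) > 3 | abs(zq[, 2]) > 3
  if (any(extrapolated)) {
    warning(sprintf("%d query point(s) lie > 3 sd outside the training cloud",
                    sum(extrapolated)), call. = FALSE)
  }
  data.frame(
    n_charge = n_charge, vbur = vbur,
    signed_score = clipped, raw_score = raw,
    predicted = ifelse(ambiguous, NA_character_,
                       ifelse(raw > 0, "on", "off")),
    confidence = pmin(abs(raw), 1),
    extrapolated = extrapolated, ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("confidence map: %d points, %s kernel, smoothing %g\n",
              nrow(x$points), x$kernel, x$smoothing))
  invisible(x)
}
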