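#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

# Validation failures get their own condition class so the CLI can map them to
# exit status 1 while genuine bugs still surface as ordinary errors.
stop_invalid <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("cuhte_validation_error", "error")))
}

stop_usage <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("cuhte_usage_error", "error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library functions never
#' clobber the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("seed must be a single finite number, got %s", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Label helpers ---------------------------------------------------------------

LABELS <- c("on", "off")

check_labels <- function(x, what = "labels") {
  x <- as.character(x)
  bad <- !(x %in% LABELS)
  if (any(bad)) {
    stop_invalid(
      "%s must be 'on' or 'off'; offending values: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    )
  }
  x
}

check_numeric_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("%s must be finite numeric", what)
  }
  x
}

# z-score standardization that tolerates constant columns (sd -> 1)
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(
    z = sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/"),
    center = mu, scale = sd
  )
}
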