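# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform
#' @importFrom stats quantile rnorm dnorm pt cor sd
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Separable Gaussian blur with edge replication. `stats::filter` applies the
# kernel column-wise, so we pad rows, filter, transpose, and repeat.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(mm) {
    top <- mm[rep(1L, r), , drop = FALSE]
    bot <- mm[rep(nrow(mm), r), , drop = FALSE]
    padded <- rbind(top, mm, bot)
    out <- stats::filter(padded, k, sides = 2)
    out <- as.matrix(out)
    out[(r + 1L):(r + nrow(mm)), , drop = FALSE]
  }
  t(blur_cols(t(blur_cols(m))))
}

# Shoelace area of a closed or open polygon ring, in squared map units.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3L) rlang::abort("polygon needs at least 3 distinct vertices")
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
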