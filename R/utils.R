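# Shared numeric helpers.

#' Clip values to an interval
#'
#' @param x Numeric vector.
#' @param lo,hi Interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Reporting convention for percentages: 0.5 always rounds away from zero
#' (186.8 -> 187, 17.5 -> 18, -4.5 -> -5), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Trapezoidal integral of y over x.
trapz_ <- function(x, y) pracma::trapz(x, y)

# Central-difference derivative on a (possibly non-uniform) grid.
grad_ <- function(y, x) {
  n <- length(y)
  stopifnot(n >= 2L, length(x) == n)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

# Local extrema with plateau handling: a plateau that is a strict local
# min/max contributes its midpoint index.
local_extrema_ <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(minima = integer(), maxima = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  minima <- integer()
  maxima <- integer()
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      mid <- as.integer(floor((starts[j] + ends[j]) / 2))
      if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
        minima <- c(minima, mid)
      } else if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
        maxima <- c(maxima, mid)
      }
    }
  }
  list(minima = minima, maxima = maxima)
}

assert_finite_ <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# Seed scoping: run `expr` under `seed` without disturbing the caller's RNG.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
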