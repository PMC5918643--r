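#' Triangular linguistic-variable term parameters
#'
#' Constructs and validates the `(b, c, d)` constants of a three-term
#' triangular linguistic variable. `b` is the end of the Low shoulder,
#' `c` the peak of Medium, and `d` the start of the High shoulder, all in
#' the units of the base variable. The membership functions divide by
#' `c - b` and `d - c`, so the ordering `0 < b < c < d` is strict.
#'
#' @param b Positive real; upper end of the Low shoulder.
#' @param c Positive real; peak of the Medium term.
#' @param d Positive real; lower end of the High shoulder.
#'
#' @return An object of class `term_params`: a named list with elements
#'   `b`, `c`, `d`, stored unmodified.
#' @examples
#' term_params(2, 5, 8)
#' @export
term_params <- function(b, c, d) {
  for (v in list(b = b, c = c, d = d)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("term constants must be finite numeric scalars", call. = FALSE)
    }
  }
  if (b <= 0) stop("invalid term constants: b > 0 violated (b = ", b, ")", call. = FALSE)
  if (b >= c) stop("invalid term constants: b < c violated (b = ", b, ", c = ", c, ")", call. = FALSE)
  if (c >= d) stop("invalid term constants: c < d violated (c = ", c, ", d = ", d, ")", call. = FALSE)
  structure(list(b = b, c = c, d = d), class = "term_params")
}

#' @export
print.term_params <- function(x, ...) {
  cat(sprintf("<term_params> b = %g, c = %g, d = %g\n", x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate triangular Low/Medium/High memberships
#'
#' Piecewise-linear membership of a nonnegative base value in the three
#' linguistic terms. Low is 1 on `[0, b]`, falls linearly to 0 at `c`;
#' Medium rises from `b` to a peak at `c` and falls to 0 at `d`; High
#' rises from `c` and is 1 on `[d, Inf)`. Because the three terms share
#' their breakpoints, the degrees sum to 1 for every `x >= 0` (partition
#' of unity).
#'
#' @param x Numeric vector of nonnegative base-variable values.
#' @param params A [term_params()] object, or a list/data frame with
#'   elements `b`, `c`, `d` (recycled against `x` if length-1).
#'
#' @return A tibble with columns `low`, `medium`, `high`, one row per
#'   element of `x`; each entry in `[0, 1]` and each row summing to 1.
#' @examples
#' fz_membership(c(1, 3.5, 5, 9), term_params(2, 5, 8))
#' @export
fz_membership <- function(x, params) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("base value x must be finite and >= 0", call. = FALSE)
  }
  b <- params$b
  c <- params$c
  d <- params$d
  n <- max(length(x), length(b))
  x <- rep_len(x, n)
  b <- rep_len(b, n)
  c <- rep_len(c, n)
  d <- rep_len(d, n)

  low <- ifelse(x <= b, 1, ifelse(x < c, (c - x) / (c - b), 0))
  medium <- ifelse(x <= b | x >= d, 0,
    ifelse(x <= c, (x - b) / (c - b), (d - x) / (d - c))
  )
  high <- ifelse(x >= d, 1, ifelse(x > c, (x - c) / (d - c), 0))
  tibble::tibble(low = low, medium = medium, high = high)
}

#' Specify the population distribution of term constants
#'
#' In a heterogeneous population each agent draws its own `(b, c, d)`
#' constants from independent normal distributions
#' `B ~ N(b_mean, b_sd^2)`, `C ~ N(c_mean, c_sd^2)`, `D ~ N(d_mean, d_sd^2)`.
#' The means must already satisfy the strict ordering `b < c < d`.
#'
#' @param b_mean,c_mean,d_mean Means of the three constants (base-variable
#'   units), with `0 < b_mean < c_mean < d_mean`.
#' @param b_sd,c_sd,d_sd Nonnegative standard deviations.
#'
#' @return An object of class `constant_spec`.
#' @examples
#' constant_spec(2, 5, 8, sd = 0.3)
#' @param sd Convenience: a single standard deviation applied to all three
#'   constants when the individual `*_sd` arguments are not given.
#' @export
constant_spec <- function(b_mean, c_mean, d_mean, b_sd = sd, c_sd = sd, d_sd = sd, sd = 0) {
  term_params(b_mean, c_mean, d_mean) # reuse ordering validation on the means
  sds <- c(b_sd = b_sd, c_sd = c_sd, d_sd = d_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(
      b_mean = b_mean, c_mean = c_mean, d_mean = d_mean,
      b_sd = b_sd, c_sd = c_sd, d_sd = d_sd
    ),
    class = "constant_spec"
  )
}

#' @export
print.constant_spec <- function(x, ...) {
  cat(sprintf(
    "<constant_spec> B ~ N(%g, %g^2), C ~ N(%g, %g^2), D ~ N(%g, %g^2)\n",
    x$b_mean, x$b_sd, x$c_mean, x$c_sd, x$d_mean, x$d_sd
  ))
  invisible(x)
}

#' Sample term constants for a population of agents
#'
#' Draws `n` independent `(b, c, d)` triples from the normal distributions
#' of a [constant_spec()]. Because the membership functions require the
#' strict ordering `0 < b < c < d`, each full triple is rejection-sampled:
#' a draw violating the ordering (or `b <= 0`) is discarded and the whole
#' triple redrawn, so each accepted marginal stays normal conditional on
#' acceptance. Sorting the draws instead would distort the marginals more
#' aggressively.
#'
#' Randomness comes from R's global RNG; call `set.seed()` for
#' reproducible populations.
#'
#' @param spec A [constant_spec()].
#' @param n Number of agents (`n >= 1`).
#' @param max_tries Retry budget per triple (default 1000).
#'
#' @return A tibble with `n` rows and columns `b`, `c`, `d`, each row a
#'   valid ordered triple.
#' @examples
#' set.seed(1)
#' sample_term_params(constant_spec(2, 5, 8, sd = 0.3), n = 5)
#' @export
sample_term_params <- function(spec, n, max_tries = 1000L) {
  stopifnot(inherits(spec, "constant_spec"), n >= 1)
  out_b <- numeric(n)
  out_c <- numeric(n)
  out_d <- numeric(n)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0L) {
    if (tries >= max_tries) {
      stop(
        "failed to sample ordered (b, c, d) triples within ", max_tries,
        " attempts for spec with means (", spec$b_mean, ", ", spec$c_mean,
        ", ", spec$d_mean, ")",
        call. = FALSE
      )
    }
    m <- length(todo)
    b <- stats::rnorm(m, spec$b_mean, spec$b_sd)
    c <- stats::rnorm(m, spec$c_mean, spec$c_sd)
    d <- stats::rnorm(m, spec$d_mean, spec$d_sd)
    ok <- b > 0 & b < c & c < d
    idx <- todo[ok]
    out_b[idx] <- b[ok]
    out_c[idx] <- c[ok]
    out_d[idx] <- d[ok]
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  tibble::tibble(b = out_b, c = out_c, d = out_d)
}
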