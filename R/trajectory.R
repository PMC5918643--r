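#' Specify a decreasing base-variable trajectory
#'
#' Two worked trajectory families describe how a base variable decays over
#' time when an intervention is withdrawn or its effect wears off:
#' a linear path `f(t) = -alpha * t + beta` and an exponential path
#' `g(t) = exp(beta - alpha * t)`, both with `alpha, beta > 0` so the path
#' is strictly decreasing. The closed-form membership trajectories along
#' these paths serve both as an analysis tool and as the oracle against
#' which the simulator's membership dynamics are validated.
#'
#' Increasing paths (`alpha <= 0`) are outside the model and rejected.
#'
#' @param kind `"linear"` or `"exponential"`.
#' @param alpha Positive decay rate (per time unit).
#' @param beta Positive intercept (linear) or log-scale level (exponential).
#' @param t4 Positive simulation horizon.
#'
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec("linear", alpha = 1, beta = 10, t4 = 10)
#' @export
trajectory_spec <- function(kind = c("linear", "exponential"), alpha, beta, t4) {
  kind <- match.arg(kind)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!is.finite(t4) || t4 <= 0) stop("horizon t4 must be > 0", call. = FALSE)
  structure(list(kind = kind, alpha = alpha, beta = beta, t4 = t4),
    class = "trajectory_spec"
  )
}

#' Evaluate the base-variable path
#'
#' @param t Numeric vector of times in `[0, t4]`.
#' @param spec A [trajectory_spec()].
#'
#' @return Numeric vector `f(t)` or `g(t)`. For the linear kind the path
#'   must remain nonnegative over the requested times (memberships are
#'   undefined for negative base values).
#' @examples
#' base_value(0:3, trajectory_spec("linear", 1, 10, 10))
#' @export
base_value <- function(t, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (any(t < 0) || any(t > spec$t4)) {
    stop("t must lie in [0, t4]", call. = FALSE)
  }
  out <- switch(spec$kind,
    linear = -spec$alpha * t + spec$beta,
    exponential = exp(spec$beta - spec$alpha * t)
  )
  if (spec$kind == "linear" && any(out < 0)) {
    stop("linear path is negative at some requested t; membership undefined for x < 0",
      call. = FALSE
    )
  }
  out
}

#' Times at which a decreasing path crosses the term breakpoints
#'
#' For a strictly decreasing path, `t1`, `t2`, `t3` are the times at which
#' the base value falls through `d`, `c`, and `b`. They split `[0, t4]`
#' into the four membership regimes: High is 1 on `[t0, t1]`, High falls
#' and Medium rises on `[t1, t2]`, Medium falls and Low rises on
#' `[t2, t3]`, and Low is 1 on `[t3, t4]` (`t0 = 0` by convention).
#' Crossings are solved in closed form: linearly `beta - alpha*t = v`, or
#' `t = (beta - log v)/alpha` for the exponential path. A crossing time
#' outside `[0, t4]` is reported but flagged as uncrossed.
#'
#' @param spec A [trajectory_spec()].
#' @param params A [term_params()].
#'
#' @return A tibble with columns `breakpoint` (`"t1"`, `"t2"`, `"t3"`),
#'   `threshold` (`"d"`, `"c"`, `"b"`), `value` (the threshold), `t`
#'   (crossing time), and `crossed` (logical, inside `[0, t4]`).
#' @examples
#' trajectory_breakpoints(
#'   trajectory_spec("linear", 1, 10, 10),
#'   term_params(2, 5, 8)
#' )
#' @export
trajectory_breakpoints <- function(spec, params) {
  stopifnot(inherits(spec, "trajectory_spec"), inherits(params, "term_params"))
  thresholds <- c(d = params$d, c = params$c, b = params$b)
  t_cross <- switch(spec$kind,
    linear = (spec$beta - thresholds) / spec$alpha,
    exponential = (spec$beta - log(thresholds)) / spec$alpha
  )
  tibble::tibble(
    breakpoint = c("t1", "t2", "t3"),
    threshold = names(thresholds),
    value = unname(thresholds),
    t = unname(t_cross),
    crossed = unname(t_cross >= 0 & t_cross <= spec$t4)
  )
}

# Crossing times as a plain named vector c(t1, t2, t3); internal helper.
breakpoint_times <- function(spec, params) {
  bp <- trajectory_breakpoints(spec, params)
  stats::setNames(bp$t, bp$breakpoint)
}

#' Closed-form membership trajectory along a decreasing path
#'
#' Evaluates the Low/Medium/High memberships as explicit functions of time
#' by substituting the base path into the triangular membership functions.
#' On `[t2, t3]`, for example, the Low degree is
#' `(c - beta + alpha*t)/(c - b)` for the linear path and
#' `(c - exp(beta - alpha*t))/(c - b)` for the exponential path. The
#' result is identical (to machine precision) to
#' `fz_membership(base_value(t, spec), params)`; that equality is the core
#' oracle property used to validate membership dynamics.
#'
#' @param t Numeric vector of times in `[0, t4]`.
#' @inheritParams trajectory_breakpoints
#'
#' @return A tibble with columns `t`, `x` (base value), `low`, `medium`,
#'   `high`.
#' @examples
#' membership_trajectory(seq(0, 10, 0.5),
#'   trajectory_spec("linear", 1, 10, 10), term_params(2, 5, 8)
#' )
#' @export
membership_trajectory <- function(t, spec, params) {
  stopifnot(inherits(spec, "trajectory_spec"), inherits(params, "term_params"))
  if (any(t < 0) || any(t > spec$t4)) stop("t must lie in [0, t4]", call. = FALSE)
  bp <- breakpoint_times(spec, params)
  b <- params$b
  c <- params$c
  d <- params$d
  x <- base_value(t, spec)

  low <- numeric(length(t))
  medium <- numeric(length(t))
  high <- numeric(length(t))

  seg <- function(lo, hi) t >= lo & t <= hi
  # regime [t3, t4]: path at or below b
  low[t >= bp["t3"]] <- 1
  # regime [t2, t3]: path between b and c
  i <- seg(bp["t2"], bp["t3"])
  low[i] <- (c - x[i]) / (c - b)
  medium[i] <- (x[i] - b) / (c - b)
  # regime [t1, t2]: path between c and d
  i <- seg(bp["t1"], bp["t2"])
  medium[i] <- (d - x[i]) / (d - c)
  high[i] <- (x[i] - c) / (d - c)
  # regime [t0, t1]: path at or above d
  high[t <= bp["t1"]] <- 1

  tibble::tibble(t = t, x = x, low = low, medium = medium, high = high)
}

#' Analytic derivative signs of a membership trajectory within one regime
#'
#' Reports the signs of the first and second time derivatives of one
#' linguistic term's membership on an open interval that lies inside a
#' single regime of the breakpoints. Along the linear path every active
#' branch is affine in `t`, so second derivatives vanish; along the
#' exponential path the surviving exponential makes Low rise concave-down
#' on `(t2, t3)` and High fall concave-up on `(t1, t2)`, with Medium
#' switching sign across `t2`. At the breakpoints themselves the
#' trajectory has kinks, so signs are only defined on open intervals.
#'
#' @inheritParams trajectory_breakpoints
#' @param term One of `"low"`, `"medium"`, `"high"`.
#' @param interval Numeric length-2 open interval `(from, to)` contained
#'   in one regime.
#'
#' @return A list with `first` and `second`, each one of `-1`, `0`, `1`
#'   (sign of the derivative throughout the interval).
#' @examples
#' derivative_signs(
#'   trajectory_spec("linear", 1, 10, 10), term_params(2, 5, 8),
#'   "low", c(5.5, 7.5)
#' )
#' @export
derivative_signs <- function(spec, params, term = c("low", "medium", "high"),
                             interval) {
  term <- match.arg(term)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  bp <- breakpoint_times(spec, params)
  edges <- sort(c(0, pmin(pmax(bp, 0), spec$t4), spec$t4))
  inside <- function(lo, hi) interval[1] >= lo - 1e-12 && interval[2] <= hi + 1e-12
  regime <- NULL
  for (k in seq_len(length(edges) - 1L)) {
    if (inside(edges[k], edges[k + 1L])) {
      regime <- c(edges[k], edges[k + 1L])
      break
    }
  }
  if (is.null(regime)) {
    stop("interval straddles a regime breakpoint; derivative signs are only defined within one regime",
      call. = FALSE
    )
  }
  mid <- mean(interval)
  # Which branch is active at the interval midpoint?
  phase <- if (mid >= bp["t3"]) {
    "low_plateau"
  } else if (mid >= bp["t2"]) {
    "low_rise"
  } else if (mid >= bp["t1"]) {
    "high_fall"
  } else {
    "high_plateau"
  }
  curved <- spec$kind == "exponential" # surviving e^(beta - alpha t) term
  sgn <- switch(term,
    low = switch(phase,
      low_plateau = c(0, 0),
      low_rise = c(1, if (curved) -1 else 0),
      high_fall = c(0, 0),
      high_plateau = c(0, 0)
    ),
    medium = switch(phase,
      low_plateau = c(0, 0),
      low_rise = c(-1, if (curved) 1 else 0),
      high_fall = c(1, if (curved) -1 else 0),
      high_plateau = c(0, 0)
    ),
    high = switch(phase,
      low_plateau = c(0, 0),
      low_rise = c(0, 0),
      high_fall = c(-1, if (curved) 1 else 0),
      high_plateau = c(0, 0)
    )
  )
  list(first = sgn[1], second = sgn[2])
}
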