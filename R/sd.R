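#' Parameters of the institutional stock-flow model
#'
#' The institution maintains two capacity stocks — COASF (safe outdoor
#' activity space and facilities) and CSSHF (stores serving healthy food)
#' — fed by investment inflows `phi_1 = omega * p`,
#' `phi_2 = omega * (1 - p)` and drained by capacity decay
#' `lambda_k = s_k / d_k`. The investment outflow
#' `omega(t) = z_COG * rho(t) / d3` spends a fixed initial fund `C`
#' (`rho(0) = C`, never replenished) at a rate set by the Mamdani
#' controller's defuzzified impact `z_COG` and the investment delay `d3`.
#' Integration is explicit Euler with step `dt`; the guard
#' `dt <= min(d1, d2, d3) / 4` keeps the decay terms from overshooting.
#'
#' @param C Initial fund (currency units), `> 0`.
#' @param d1,d2 Life years of the built capacities (time units), `> 0`.
#' @param d3 Investment delay (time units), `> 0`.
#' @param p Default allocation fraction to COASF, in (0, 1).
#' @param dt Integration step (time units), `> 0` and
#'   `<= min(d1, d2, d3) / 4`.
#' @param coasf_terms,csshf_terms [term_params()] of the institution's
#'   perception of each stock.
#'
#' @return An object of class `sd_params`.
#' @examples
#' sd_params(
#'   C = 200, d1 = 20, d2 = 20, d3 = 5, p = 0.5, dt = 1 / 16,
#'   coasf_terms = term_params(2, 5, 8), csshf_terms = term_params(2, 5, 8)
#' )
#' @export
sd_params <- function(C, d1, d2, d3, p = 0.5, dt = 1 / 16,
                      coasf_terms, csshf_terms) {
  if (C <= 0) stop("initial fund C must be > 0", call. = FALSE)
  if (d1 <= 0 || d2 <= 0 || d3 <= 0) stop("d1, d2, d3 must be > 0", call. = FALSE)
  if (p <= 0 || p >= 1) stop("allocation fraction p must lie in (0, 1)", call. = FALSE)
  if (dt <= 0 || dt > min(d1, d2, d3) / 4) {
    stop("dt must satisfy 0 < dt <= min(d1, d2, d3)/4 (integration stability guard)",
      call. = FALSE
    )
  }
  stopifnot(inherits(coasf_terms, "term_params"), inherits(csshf_terms, "term_params"))
  structure(
    list(
      C = C, d1 = d1, d2 = d2, d3 = d3, p = p, dt = dt,
      coasf_terms = coasf_terms, csshf_terms = csshf_terms
    ),
    class = "sd_params"
  )
}

#' Initial state of the stock-flow model
#'
#' @param params An [sd_params()].
#' @param s1,s2 Initial capacities (default 0).
#'
#' @return An object of class `sd_state`: time, stocks `s1`, `s2`,
#'   remaining fund `rho`, cumulative spend `invested`, and the last
#'   flows/controller values for tracing.
#' @export
sd_init <- function(params, s1 = 0, s2 = 0) {
  stopifnot(inherits(params, "sd_params"), s1 >= 0, s2 >= 0)
  structure(
    list(
      t = 0, s1 = s1, s2 = s2, rho = params$C, invested = 0,
      omega = 0, z_cog = 0, p = params$p,
      phi1 = 0, phi2 = 0, lambda1 = s1 / params$d1, lambda2 = s2 / params$d2
    ),
    class = "sd_state"
  )
}

#' The nine-rule Mamdani rule base
#'
#' The controller maps the institution's perceived COASF and CSSHF
#' (each fuzzified into Low/Medium/High) to a perceived impact on
#' investment. All 3 x 3 antecedent combinations are covered exactly
#' once: broadly, low perceived capacity keeps investment impact low
#' early on, while high perceived COASF drives it high.
#'
#' @return A tibble with 9 rows and columns `rule`, `coasf`, `csshf`,
#'   `impact`.
#' @examples
#' rule_base()
#' @export
rule_base <- function() {
  tibble::tribble(
    ~rule, ~coasf, ~csshf, ~impact,
    1L, "low", "low", "low",
    2L, "low", "medium", "low",
    3L, "low", "high", "medium",
    4L, "medium", "low", "low",
    5L, "medium", "medium", "medium",
    6L, "medium", "high", "medium",
    7L, "high", "low", "high",
    8L, "high", "medium", "high",
    9L, "high", "high", "high"
  )
}

# Consequent term membership over the impact universe z in [0, 1]:
# Low = triangle(0, 0, 0.5), Medium = triangle(0, 0.5, 1),
# High = triangle(0.5, 1, 1) — a symmetric partition-of-unity cover.
impact_term_mf <- function(z, term) {
  switch(term,
    low = pmax(0, 1 - 2 * z),
    medium = pmax(0, 1 - 2 * abs(z - 0.5)),
    high = pmax(0, 2 * z - 1),
    stop("unknown impact term: ", term, call. = FALSE)
  )
}

#' Firing strengths of the Mamdani rules
#'
#' Standard Mamdani conjunction: each rule fires at the minimum of its
#' two antecedent membership degrees.
#'
#' @param m1,m2 Membership rows (named `low`, `medium`, `high`) of the
#'   perceived COASF and CSSHF.
#' @param rules The rule base tibble (default [rule_base()]).
#'
#' @return The rule base with an added `strength` column in `[0, 1]`.
#' @examples
#' m <- fz_membership(1, term_params(2, 5, 8))
#' rule_strengths(m, m)
#' @export
rule_strengths <- function(m1, m2, rules = rule_base()) {
  s1 <- unlist(m1[1, c("low", "medium", "high")])
  s2 <- unlist(m2[1, c("low", "medium", "high")])
  dplyr::mutate(rules, strength = unname(pmin(s1[.data$coasf], s2[.data$csshf])))
}

#' Aggregate clipped rule consequents over the impact universe
#'
#' Mamdani implication clips (min) each fired rule's consequent term at
#' the rule's strength; the fuzzy outputs are aggregated across rules by
#' pointwise maximum on a uniform grid over `[0, 1]`.
#'
#' @param strengths Output of [rule_strengths()].
#' @param grid_n Number of grid points (default 1001).
#'
#' @return A tibble with columns `z` and `mu` (aggregated membership).
#' @export
aggregate_consequent <- function(strengths, grid_n = 1001L) {
  z <- seq(0, 1, length.out = grid_n)
  mu <- rep(0, grid_n)
  fired <- strengths[strengths$strength > 0, ]
  for (k in seq_len(nrow(fired))) {
    mu <- pmax(mu, pmin(fired$strength[k], impact_term_mf(z, fired$impact[k])))
  }
  tibble::tibble(z = z, mu = mu)
}

#' Centre-of-gravity defuzzification
#'
#' `z_COG = integral(z mu(z) dz) / integral(mu(z) dz)` over the impact
#' universe, computed by the trapezoidal rule on the aggregate grid. The
#' ratio is undefined for an identically zero aggregate (no rule fired);
#' in that case the supplied fallback (the previous defuzzified value, or
#' 0 at the start of a run) is returned with a warning.
#'
#' @param agg Output of [aggregate_consequent()].
#' @param fallback Value returned when no rule fired (default 0).
#'
#' @return The crisp impact `z_COG` in `[0, 1]`.
#' @examples
#' s <- rule_strengths(
#'   fz_membership(5, term_params(2, 5, 8)),
#'   fz_membership(5, term_params(2, 5, 8))
#' )
#' cog_defuzzify(aggregate_consequent(s)) # symmetric Medium -> 0.5
#' @export
cog_defuzzify <- function(agg, fallback = 0) {
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  denom <- trapz(agg$z, agg$mu)
  if (denom <= 0) {
    warning("no rule fired; centre-of-gravity undefined, returning fallback", call. = FALSE)
    return(fallback)
  }
  trapz(agg$z, agg$z * agg$mu) / denom
}

#' Fuzzify the current stocks through the institution's perception
#'
#' The institution perceives each capacity stock through its own
#' triangular membership constants; perception is instantaneous (the
#' investment delay `d3` already enters the outflow equation).
#'
#' @param state An `sd_state`.
#' @param params An [sd_params()].
#'
#' @return A list of two membership tibbles, `coasf` and `csshf`.
#' @export
perceived_memberships <- function(state, params) {
  list(
    coasf = fz_membership(state$s1, params$coasf_terms),
    csshf = fz_membership(state$s2, params$csshf_terms)
  )
}

#' One explicit-Euler step of the stock-flow model
#'
#' Updates the state over `dt`: `omega = z_cog * rho / d3` (truncated so
#' the fund never goes negative), `phi_1 = omega * p`,
#' `phi_2 = omega * (1 - p)`, `lambda_k = s_k / d_k`,
#' `s_k <- s_k + (phi_k - lambda_k) * dt`, `rho <- rho - omega * dt`.
#' The running total `invested` makes fund conservation
#' `rho + invested = C` checkable at every step.
#'
#' @param state An `sd_state`.
#' @param params An [sd_params()].
#' @param p Allocation fraction for this step, in `[0, 1]`.
#' @param z_cog Crisp controller output, in `[0, 1]`.
#'
#' @return The state advanced by `dt`.
#' @export
sd_step <- function(state, params, p, z_cog) {
  stopifnot(inherits(state, "sd_state"), inherits(params, "sd_params"))
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (z_cog < 0 || z_cog > 1) stop("z_cog must lie in [0, 1]", call. = FALSE)
  dt <- params$dt
  omega <- z_cog * state$rho / params$d3
  omega <- min(omega, state$rho / dt) # fund cannot go negative
  phi1 <- omega * p
  phi2 <- omega * (1 - p)
  lambda1 <- state$s1 / params$d1
  lambda2 <- state$s2 / params$d2
  state$s1 <- max(0, state$s1 + (phi1 - lambda1) * dt)
  state$s2 <- max(0, state$s2 + (phi2 - lambda2) * dt)
  state$rho <- state$rho - omega * dt
  state$invested <- state$invested + omega * dt
  state$t <- state$t + dt
  state$omega <- omega
  state$z_cog <- z_cog
  state$p <- p
  state$phi1 <- phi1
  state$phi2 <- phi2
  state$lambda1 <- lambda1
  state$lambda2 <- lambda2
  state
}

# One controller-driven SD sub-step: fuzzify stocks, fire the rules,
# defuzzify (falling back to the previous z_cog), then integrate dt.
sd_controller_step <- function(state, params, p, rules = rule_base(), grid_n = 1001L) {
  m <- perceived_memberships(state, params)
  agg <- aggregate_consequent(rule_strengths(m$coasf, m$csshf, rules), grid_n)
  z <- cog_defuzzify(agg, fallback = state$z_cog)
  sd_step(state, params, p, z)
}

#' @export
print.sd_state <- function(x, ...) {
  cat(sprintf(
    "<sd_state> t = %.3f  s1 = %.3f  s2 = %.3f  rho = %.3f  z_cog = %.3f\n",
    x$t, x$s1, x$s2, x$rho, x$z_cog
  ))
  invisible(x)
}
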