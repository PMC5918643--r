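#' Bin a Low membership into the eleven clustering intervals
#'
#' Agents are clustered per variable by their Low-term membership into
#' the intervals `0, (0, 0.1], (0.1, 0.2], ..., (0.9, 1.0]`. Bin 0 holds
#' agents with exactly zero membership — no need for resources — and bin
#' `m` (1..10) holds memberships in `((m-1)/10, m/10]` (half-open lower,
#' closed upper endpoints). Zero is detected with an absolute tolerance
#' of 1e-12 so floating-point round-off does not create spurious demand.
#'
#' @param mu Numeric vector of memberships in `[0, 1]`.
#'
#' @return Integer vector of bin indices in 0..10.
#' @examples
#' assign_bin(c(0, 0.05, 0.1, 0.11, 1))
#' @export
assign_bin <- function(mu) {
  if (any(!is.finite(mu)) || any(mu < -1e-12) || any(mu > 1 + 1e-12)) {
    stop("membership must lie in [0, 1]", call. = FALSE)
  }
  bin <- pmin(ceiling(pmax(mu, 0) * 10), 10L)
  bin[abs(mu) <= 1e-12] <- 0L
  as.integer(bin)
}

#' Cluster agents in per-variable subspaces
#'
#' Assigns every (agent, variable) pair to a membership bin using the
#' current socially updated Low value. The clustering is virtual — an
#' agent is "located" simultaneously in one subspace per linguistic
#' variable — and deterministic given the population.
#'
#' @param population A population tibble.
#'
#' @return A tibble with columns `agent_id`, `variable`, `mu_low_social`,
#'   `bin`, one row per (agent, variable).
#' @export
cluster_subspaces <- function(population) {
  tibble::tibble(
    agent_id = population$agent_id,
    variable = population$variable,
    mu_low_social = population$mu_low_social,
    bin = assign_bin(population$mu_low_social)
  )
}

#' Discrepancy signal fed back to the institutional model
#'
#' Aggregates the clustering into one unmet-need figure per variable:
#' `need_j` is the mean Low membership over the agents outside bin 0 for
#' variable `j` (0 if every agent sits in bin 0). The allocation fraction
#' returned for the next stage is the normalized relative need of
#' variable 1, `p = need_1 / (need_1 + need_2)`, falling back to the
#' configured default when no agent needs resources.
#'
#' @param assignments Output of [cluster_subspaces()].
#' @param default_p Allocation fraction used when total need is zero.
#'
#' @return A list with `needs` (tibble: `variable`, `need`, `n_in_need`),
#'   `p` (allocation fraction for the first variable's stock), and
#'   `homogenized` (share of (agent, variable) pairs in bin 0).
#' @examples
#' pop <- tibble::tibble(
#'   agent_id = 1:2, variable = 1L,
#'   mu_low_social = c(0, 0.6)
#' )
#' discrepancy(cluster_subspaces(pop), default_p = 0.5)
#' @export
discrepancy <- function(assignments, default_p = 0.5) {
  needs <- dplyr::summarise(
    dplyr::group_by(assignments, .data$variable),
    need = ifelse(any(.data$bin > 0),
      mean(.data$mu_low_social[.data$bin > 0]), 0
    ),
    n_in_need = sum(.data$bin > 0),
    .groups = "drop"
  )
  total <- sum(needs$need[1:2], na.rm = TRUE)
  p <- if (nrow(needs) >= 2 && total > 0) needs$need[1] / total else default_p
  list(
    needs = needs,
    p = p,
    homogenized = mean(assignments$bin == 0L)
  )
}
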