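#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-stage summary of a simulation run
#'
#' @param x A `hybrid_sim` from [run_simulation()].
#' @param ... Unused.
#'
#' @return A tibble with one row per stage: `stage`, `p_used` (allocation
#'   fraction during the stage), `need_coasf`, `need_csshf` (mean Low
#'   membership of the agents still in need per variable), `p_next`
#'   (feedback allocation for the following stage), and `homogenized`
#'   (share of (agent, variable) pairs in bin 0 at stage end).
#' @export
tidy.hybrid_sim <- function(x, ...) {
  x$stages
}

#' One-row summary of a simulation run
#'
#' @param x A `hybrid_sim`.
#' @param ... Unused.
#'
#' @return A one-row tibble: `n_agents`, `stages_run`,
#'   `final_homogenized`, `total_invested`, `final_rho`, `final_s1`,
#'   `final_s2`, `seed`.
#' @export
glance.hybrid_sim <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_agents = x$config$population$n,
    stages_run = s$stages_run,
    final_homogenized = s$final_homogenized,
    total_invested = s$total_invested,
    final_rho = s$final_rho,
    final_s1 = s$final_s1,
    final_s2 = s$final_s2,
    seed = s$seed
  )
}
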