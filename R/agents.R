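#' Initialise a population of fuzzy agents
#'
#' Builds `n` agents, each carrying its own `(b, c, d)` membership
#' constants for every linguistic variable, sampled from the per-variable
#' [constant_spec()]s. Memberships are initialised from the supplied base
#' values; the socially updated Low degree (`mu_low_social`) starts equal
#' to the geometric Low degree.
#'
#' The population is an ordinary tibble with one row per
#' (agent, variable): columns `agent_id`, `variable`, `b`, `c`, `d`, `x`,
#' `mu_low`, `mu_medium`, `mu_high`, `mu_low_social`. All population
#' operations take and return this shape, so runs compose with dplyr.
#'
#' @param n Number of agents (`n >= 2`).
#' @param var_specs A list of [constant_spec()], one per linguistic
#'   variable.
#' @param init_x Numeric vector of initial base values, one per variable
#'   (recycled if length 1); `>= 0`.
#'
#' @return A population tibble with `n * length(var_specs)` rows.
#' @examples
#' set.seed(1)
#' pop <- init_agents(4, list(constant_spec(2, 5, 8, sd = 0.3)), init_x = 0)
#' @export
init_agents <- function(n, var_specs, init_x = 0) {
  stopifnot(n >= 2, length(var_specs) >= 1)
  if (!all(vapply(var_specs, inherits, logical(1), "constant_spec"))) {
    stop("var_specs must be a list of constant_spec objects", call. = FALSE)
  }
  q <- length(var_specs)
  init_x <- rep_len(init_x, q)
  if (any(init_x < 0)) stop("initial base values must be >= 0", call. = FALSE)
  pop <- purrr::map_dfr(seq_len(q), function(j) {
    dplyr::mutate(
      sample_term_params(var_specs[[j]], n),
      agent_id = seq_len(n), variable = j, x = init_x[j],
      .before = 1
    )
  })
  mu <- fz_membership(pop$x, pop[c("b", "c", "d")])
  pop$mu_low <- mu$low
  pop$mu_medium <- mu$medium
  pop$mu_high <- mu$high
  pop$mu_low_social <- mu$low
  dplyr::arrange(pop, .data$agent_id, .data$variable)
}

#' Specify the contact model
#'
#' Contacts per time unit are either drawn uniformly at random (each agent
#' initiates `k` contacts with distinct partners) or taken from a fixed
#' scale-free network whose degree distribution follows a power law
#' `P(k) ~ k^-q` with exponent `q` in (2, 3), as observed in social
#' contact networks where a few hubs hold most connections.
#'
#' @param mode `"random"` or `"scale_free"`.
#' @param k Contacts initiated per agent per time unit; `1 <= k <= 5`
#'   (default 3).
#' @param q_exponent Power-law exponent for scale-free mode, in (2, 3).
#'
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(mode = c("random", "scale_free"), k = 3L, q_exponent = 2.5) {
  mode <- match.arg(mode)
  if (k < 1 || k > 5) stop("k must satisfy 1 <= k <= 5", call. = FALSE)
  if (mode == "scale_free" && (q_exponent <= 2 || q_exponent >= 3)) {
    stop("q_exponent must lie strictly in (2, 3)", call. = FALSE)
  }
  structure(list(mode = mode, k = as.integer(k), q_exponent = q_exponent),
    class = "contact_spec"
  )
}

# Build the fixed scale-free contact graph: configuration model on a
# truncated discrete power-law degree sequence (min degree 1), collapsed
# to a simple graph. Returns an igraph object.
scale_free_graph <- function(n, q_exponent) {
  k_max <- max(3L, floor(sqrt(n)))
  ks <- seq_len(k_max)
  pk <- ks^(-q_exponent)
  deg <- sample(ks, n, replace = TRUE, prob = pk / sum(pk))
  if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
  g <- igraph::sample_degseq(deg, method = "configuration")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Draw the contact pairs for one time unit
#'
#' Random mode: each agent initiates `k` contacts with partners drawn
#' uniformly without replacement (never itself). Scale-free mode: the
#' pairs are the edges incident to each agent in a fixed generated graph,
#' subsampled to at most `k` per initiating agent per time unit. The pair
#' list is returned in randomized order; interaction rounds process it
#' sequentially, so the order matters and is reproducible under a seed.
#'
#' @param n Number of agents.
#' @param spec A [contact_spec()].
#' @param graph For scale-free mode, the fixed contact graph (an igraph
#'   object from a previous call via attribute, or built once by the
#'   engine). Ignored in random mode.
#'
#' @return A tibble with integer columns `i` (initiator) and `r` (peer).
#' @examples
#' set.seed(1)
#' contact_pairs(5, contact_spec("random", k = 2))
#' @export
contact_pairs <- function(n, spec, graph = NULL) {
  stopifnot(inherits(spec, "contact_spec"))
  if (spec$k >= n) stop("k must be smaller than the number of agents", call. = FALSE)
  if (spec$mode == "random") {
    pairs <- purrr::map_dfr(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      tibble::tibble(i = i, r = others[sample.int(length(others), spec$k)])
    })
  } else {
    if (is.null(graph)) graph <- scale_free_graph(n, spec$q_exponent)
    el <- igraph::as_edgelist(graph, names = FALSE)
    # each edge is a contact initiated by its first endpoint; cap at k per agent
    pairs <- tibble::tibble(i = as.integer(el[, 1]), r = as.integer(el[, 2]))
    pairs <- dplyr::slice_sample(dplyr::group_by(pairs, .data$i), n = spec$k)
    pairs <- dplyr::ungroup(pairs)
  }
  dplyr::slice_sample(pairs, n = nrow(pairs)) # randomize processing order
}

#' Pairwise Low-membership update rules
#'
#' The three peer-inference rules act on the Low-term memberships of an
#' interacting pair. Pessimistic: both take the minimum (bad news
#' spreads). Optimistic: both take the maximum. Realistic: each takes a
#' convex combination weighted by the pair's `b` constants,
#' `mu_i' = phi_i * mu_i + omega_i * mu_r` with
#' `omega_i = b_r / (b_i + b_r)` and `phi_i = 1 - omega_i`, so an agent
#' with smaller constants (more sensitive to interventions) defers more
#' to a peer with larger constants (`phi_i < omega_i` iff `b_r > b_i`),
#' and equal constants give equal weights 1/2. The peer's weights are
#' derived the same way from its own perspective.
#'
#' @param mu_i,mu_r Low memberships of the initiating agent and peer,
#'   in `[0, 1]` (vectorized).
#' @param b_i,b_r The agents' `b` constants (realistic rule only).
#'
#' @return A list with updated `mu_i` and `mu_r`.
#' @examples
#' update_pessimistic(0.3, 0.7)
#' update_realistic(0.2, 0.6, b_i = 2, b_r = 2)
#' @export
update_pessimistic <- function(mu_i, mu_r) {
  m <- pmin(mu_i, mu_r)
  list(mu_i = m, mu_r = m)
}

#' @rdname update_pessimistic
#' @export
update_optimistic <- function(mu_i, mu_r) {
  m <- pmax(mu_i, mu_r)
  list(mu_i = m, mu_r = m)
}

#' @rdname update_pessimistic
#' @export
update_realistic <- function(mu_i, mu_r, b_i, b_r) {
  omega_i <- b_r / (b_i + b_r)
  omega_r <- b_r / (b_i + b_r) # peer's weight on its own value
  list(
    mu_i = (1 - omega_i) * mu_i + omega_i * mu_r,
    mu_r = (1 - omega_r) * mu_i + omega_r * mu_r
  )
}

#' Run one interaction round over a pair list
#'
#' Applies the chosen inference rule to every contact pair, sequentially
#' in the given order (later pairs see earlier updates, matching the
#' update equations that reference already-updated values). Only the Low
#' term is socially updated — resources target the worst-off, so the
#' operations are restricted to the Low linguistic term — and the update
#' acts on the shadow value `mu_low_social` of every linguistic variable;
#' the geometry-derived `mu_low`, `mu_medium`, `mu_high` stay tied to the
#' base value.
#'
#' @param population A population tibble from [init_agents()].
#' @param pairs A pair tibble from [contact_pairs()].
#' @param rule `"pessimistic"`, `"optimistic"`, or `"realistic"`.
#'
#' @return The population with updated `mu_low_social`.
#' @export
interaction_round <- function(population, pairs,
                              rule = c("pessimistic", "optimistic", "realistic")) {
  rule <- match.arg(rule)
  if (nrow(pairs) == 0L) {
    return(population)
  }
  ids <- sort(unique(population$agent_id))
  vars <- sort(unique(population$variable))
  # matrix view (agents x variables) for the sequential pair loop
  mu <- matrix(population$mu_low_social[order(population$agent_id, population$variable)],
    nrow = length(ids), byrow = TRUE
  )
  bmat <- matrix(population$b[order(population$agent_id, population$variable)],
    nrow = length(ids), byrow = TRUE
  )
  ii <- match(pairs$i, ids)
  rr <- match(pairs$r, ids)
  for (p in seq_along(ii)) {
    a <- ii[p]
    z <- rr[p]
    upd <- switch(rule,
      pessimistic = update_pessimistic(mu[a, ], mu[z, ]),
      optimistic = update_optimistic(mu[a, ], mu[z, ]),
      realistic = update_realistic(mu[a, ], mu[z, ], bmat[a, ], bmat[z, ])
    )
    mu[a, ] <- upd$mu_i
    mu[z, ] <- upd$mu_r
  }
  ord <- order(population$agent_id, population$variable)
  population$mu_low_social[ord] <- as.vector(t(mu))
  population
}

#' Expose agents to the current intervention signal
#'
#' The first dynamic: interventions re-determine perceptions each time
#' unit. Every agent's base value for variable `j` is set to the shared
#' signal (the corresponding capacity stock of the institutional model)
#' and all three memberships are recomputed from the agent's own
#' constants; heterogeneity enters only through the constants. The
#' socially updated Low value is replaced by the fresh geometric value —
#' perception overwrites the previous round's social influence.
#'
#' @param population A population tibble.
#' @param signals Numeric vector of nonnegative base values, one per
#'   variable.
#'
#' @return The population with updated `x` and memberships.
#' @export
perceive <- function(population, signals) {
  vars <- sort(unique(population$variable))
  stopifnot(length(signals) == length(vars))
  if (any(signals < 0)) stop("base signals must be >= 0", call. = FALSE)
  population$x <- signals[match(population$variable, vars)]
  mu <- fz_membership(population$x, population[c("b", "c", "d")])
  population$mu_low <- mu$low
  population$mu_medium <- mu$medium
  population$mu_high <- mu$high
  population$mu_low_social <- mu$low
  population
}
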