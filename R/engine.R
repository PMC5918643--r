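#' Build and validate a full scenario configuration
#'
#' A scenario is a nested, plain-value list with five sections —
#' `population`, `contact`, `interaction`, `sd`, `engine` — mirroring the
#' model's parts. Exactly two linguistic variables are supported, mapping
#' onto the two capacity stocks (COASF and CSSHF); other counts are
#' rejected. The configuration is pure data (numbers and strings), so it
#' round-trips losslessly through YAML via [read_config()] /
#' [write_config()].
#'
#' @param n Number of agents (`>= 2`).
#' @param var_specs List of two per-variable constant distributions; each
#'   a [constant_spec()] or a list with fields `b_mean`, `c_mean`,
#'   `d_mean`, `b_sd`, `c_sd`, `d_sd`.
#' @param init_x Initial base values per variable (default 0).
#' @param contact List with `mode` (`"random"`/`"scale_free"`), `k`, and
#'   (scale-free only) `q_exponent`.
#' @param rule Interaction rule: `"pessimistic"`, `"optimistic"`, or
#'   `"realistic"`.
#' @param sd List with `C`, `d1`, `d2`, `d3`, `p`, `dt`, and institutional
#'   term constants `coasf_terms`, `csshf_terms` (each `c(b, c, d)` or a
#'   [term_params()]).
#' @param adaptive_p Should the next stage's allocation fraction come from
#'   the previous stage's discrepancy signal (default `TRUE`), rather than
#'   staying fixed at `sd$p`?
#' @param tau_len Time units per stage.
#' @param max_stages Maximum number of stages.
#' @param homog_threshold Stop once this fraction of (agent, variable)
#'   pairs sits in bin 0, in `[0, 1]`.
#' @param seed Nonnegative integer seed; all randomness in a run flows
#'   from it.
#' @param grid_n Defuzzification grid size (default 1001).
#' @param thinning Keep every `thinning`-th SD sub-step row in the trace
#'   (default 1 = all).
#'
#' @return An object of class `engine_config` (a validated nested list).
#' @export
engine_config <- function(n, var_specs, init_x = c(0, 0),
                          contact = list(mode = "random", k = 3, q_exponent = 2.5),
                          rule = "realistic",
                          sd, adaptive_p = TRUE,
                          tau_len = 5, max_stages = 3, homog_threshold = 0.9,
                          seed = 0, grid_n = 1001, thinning = 1) {
  as_spec_list <- function(s) {
    if (inherits(s, "constant_spec")) {
      unclass(s)
    } else {
      s[c("b_mean", "c_mean", "d_mean", "b_sd", "c_sd", "d_sd")]
    }
  }
  as_terms_list <- function(tp) {
    if (inherits(tp, "term_params")) {
      unclass(tp)
    } else if (is.numeric(tp) && length(tp) == 3) {
      list(b = tp[[1]], c = tp[[2]], d = tp[[3]])
    } else {
      tp[c("b", "c", "d")]
    }
  }
  config <- structure(
    list(
      population = list(
        n = as.integer(n),
        var_specs = lapply(var_specs, as_spec_list),
        init_x = as.numeric(rep_len(init_x, length(var_specs)))
      ),
      contact = list(
        mode = contact$mode,
        k = as.integer(contact$k),
        q_exponent = if (is.null(contact$q_exponent)) 2.5 else contact$q_exponent
      ),
      interaction = list(rule = rule),
      sd = list(
        C = sd$C, d1 = sd$d1, d2 = sd$d2, d3 = sd$d3,
        p = sd$p, dt = sd$dt,
        coasf_terms = as_terms_list(sd$coasf_terms),
        csshf_terms = as_terms_list(sd$csshf_terms),
        adaptive_p = isTRUE(adaptive_p)
      ),
      engine = list(
        tau_len = as.integer(tau_len),
        max_stages = as.integer(max_stages),
        homog_threshold = homog_threshold,
        seed = as.integer(seed),
        grid_n = as.integer(grid_n),
        thinning = as.integer(thinning)
      )
    ),
    class = "engine_config"
  )
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n", paste0("  - ", problems, collapse = "\n"),
      call. = FALSE
    )
  }
  config
}

# Rebuild the typed component objects from the plain config.
cfg_var_specs <- function(config) {
  lapply(config$population$var_specs, function(s) {
    constant_spec(s$b_mean, s$c_mean, s$d_mean, s$b_sd, s$c_sd, s$d_sd)
  })
}

cfg_contact_spec <- function(config) {
  contact_spec(config$contact$mode, config$contact$k, config$contact$q_exponent)
}

cfg_sd_params <- function(config) {
  s <- config$sd
  sd_params(
    C = s$C, d1 = s$d1, d2 = s$d2, d3 = s$d3, p = s$p, dt = s$dt,
    coasf_terms = term_params(s$coasf_terms$b, s$coasf_terms$c, s$coasf_terms$d),
    csshf_terms = term_params(s$csshf_terms$b, s$csshf_terms$c, s$csshf_terms$d)
  )
}

#' Validate a configuration (object or YAML file)
#'
#' Checks every structural and numerical invariant of a scenario and
#' returns an itemized character vector of problems, empty when the
#' configuration is valid. Accepts either an in-memory configuration or
#' the path to a YAML file.
#'
#' @param config An `engine_config`, a plain nested list with the same
#'   shape, or a file path.
#'
#' @return Character vector of problem descriptions (length 0 if valid).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      return(paste0("configuration file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))
  need <- function(section, keys) {
    missing <- setdiff(keys, names(config[[section]]))
    for (k in missing) note(section, ".", k, ": missing")
    length(missing) == 0L
  }
  for (section in c("population", "contact", "interaction", "sd", "engine")) {
    if (is.null(config[[section]])) note(section, ": section missing")
  }
  if (length(problems) > 0) {
    return(problems)
  }

  if (need("population", c("n", "var_specs", "init_x"))) {
    p <- config$population
    if (p$n < 2) note("population.n: need at least 2 agents")
    q <- length(p$var_specs)
    if (q != 2) {
      note(
        "population.var_specs: exactly 2 linguistic variables are supported ",
        "(they map onto the COASF and CSSHF stocks); got ", q
      )
    }
    for (j in seq_along(p$var_specs)) {
      s <- p$var_specs[[j]]
      ok <- tryCatch(
        {
          constant_spec(s$b_mean, s$c_mean, s$d_mean, s$b_sd, s$c_sd, s$d_sd)
          TRUE
        },
        error = function(e) {
          note("population.var_specs[", j, "]: ", conditionMessage(e))
          FALSE
        }
      )
    }
    if (any(p$init_x < 0)) note("population.init_x: must be >= 0")
  }
  if (need("contact", c("mode", "k"))) {
    ok <- tryCatch(
      {
        cfg_contact_spec(config)
        TRUE
      },
      error = function(e) {
        note("contact: ", conditionMessage(e))
        FALSE
      }
    )
    if (ok && config$contact$k >= config$population$n) {
      note("contact.k: must be smaller than population.n")
    }
  }
  if (need("interaction", "rule") &&
    !config$interaction$rule %in% c("pessimistic", "optimistic", "realistic")) {
    note("interaction.rule: must be pessimistic, optimistic, or realistic")
  }
  if (need("sd", c("C", "d1", "d2", "d3", "p", "dt", "coasf_terms", "csshf_terms"))) {
    tryCatch(cfg_sd_params(config), error = function(e) {
      note("sd: ", conditionMessage(e))
    })
    steps <- 1 / config$sd$dt
    if (!is.finite(steps) || abs(steps - round(steps)) > 1e-9) {
      note("sd.dt: one time unit must be an integer number of dt steps")
    }
  }
  if (need("engine", c("tau_len", "max_stages", "homog_threshold", "seed"))) {
    e <- config$engine
    if (e$tau_len < 1) note("engine.tau_len: must be >= 1")
    if (e$max_stages < 1) note("engine.max_stages: must be >= 1")
    if (e$homog_threshold < 0 || e$homog_threshold > 1) {
      note("engine.homog_threshold: must lie in [0, 1]")
    }
    if (e$seed < 0) note("engine.seed: must be a nonnegative integer")
  }
  problems
}

#' Read and write scenario configurations as YAML
#'
#' @param path File path.
#' @param config An `engine_config`.
#' @return `read_config()` returns a validated `engine_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  problems <- validate_config(raw)
  if (length(problems) > 0) {
    stop("invalid configuration file ", path, ":\n",
      paste0("  - ", problems, collapse = "\n"),
      call. = FALSE
    )
  }
  engine_config(
    n = raw$population$n,
    var_specs = raw$population$var_specs,
    init_x = raw$population$init_x,
    contact = raw$contact,
    rule = raw$interaction$rule,
    sd = raw$sd,
    adaptive_p = raw$sd$adaptive_p,
    tau_len = raw$engine$tau_len,
    max_stages = raw$engine$max_stages,
    homog_threshold = raw$engine$homog_threshold,
    seed = raw$engine$seed,
    grid_n = if (is.null(raw$engine$grid_n)) 1001 else raw$engine$grid_n,
    thinning = if (is.null(raw$engine$thinning)) 1 else raw$engine$thinning
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Ready-made demonstration scenarios
#'
#' `small` is a fast scenario: 50 agents, two linguistic variables with
#' constants around (2, 5, 8), 5 time units per stage, 3 stages, random
#' contacts (k = 3), realistic interaction, and a fund sized so the
#' capacities can be built past the agents' upper Low breakpoints.
#' `large` scales the same shape up to 1,000 agents with wider
#' heterogeneity and longer stages, producing growth-then-saturation
#' capacity trajectories with heterogeneous membership fans.
#'
#' @param preset `"small"` or `"large"`.
#' @param seed Seed stored in the configuration.
#'
#' @return An `engine_config`.
#' @examples
#' demo_config("small", seed = 1)
#' @export
demo_config <- function(preset = c("small", "large"), seed = 0) {
  preset <- match.arg(preset)
  base_spec <- function(sd) {
    list(b_mean = 2, c_mean = 5, d_mean = 8, b_sd = sd, c_sd = sd, d_sd = sd)
  }
  if (preset == "small") {
    engine_config(
      n = 50,
      var_specs = list(base_spec(0.3), base_spec(0.3)),
      init_x = c(0, 0),
      contact = list(mode = "random", k = 3),
      rule = "realistic",
      sd = list(
        C = 200, d1 = 20, d2 = 20, d3 = 5, p = 0.5, dt = 1 / 16,
        coasf_terms = c(2, 5, 8), csshf_terms = c(2, 5, 8)
      ),
      adaptive_p = TRUE,
      tau_len = 5, max_stages = 3, homog_threshold = 0.9,
      seed = seed
    )
  } else {
    engine_config(
      n = 1000,
      var_specs = list(base_spec(0.5), base_spec(0.5)),
      init_x = c(0, 0),
      contact = list(mode = "random", k = 3),
      rule = "realistic",
      sd = list(
        C = 1000, d1 = 20, d2 = 20, d3 = 5, p = 0.5, dt = 1 / 16,
        coasf_terms = c(2, 5, 8), csshf_terms = c(2, 5, 8)
      ),
      adaptive_p = TRUE,
      tau_len = 10, max_stages = 5, homog_threshold = 0.9,
      seed = seed
    )
  }
}

#' Run one stage of the hybrid simulation
#'
#' A stage is `tau_len` time units. Within each time unit the three
#' dynamics run in their fixed order: (1) the institutional model
#' integrates one time unit in `dt` sub-steps with the Mamdani controller
#' re-evaluated each sub-step from the perceived stocks; (2) agents
#' perceive the updated stocks (intervention impact); (3) one interaction
#' round runs over freshly drawn contact pairs (peer effects). At stage
#' end agents are clustered and the discrepancy signal computed.
#'
#' @param config An `engine_config`.
#' @param population Population tibble.
#' @param sd_state An `sd_state`.
#' @param p Allocation fraction used throughout the stage.
#' @param stage Stage number (for trace labelling).
#' @param graph Fixed contact graph (scale-free mode), or `NULL`.
#'
#' @return A list: `population`, `sd_state`, `agent_trace`, `sd_trace`,
#'   `discrepancy`, `homogenized`.
#' @export
run_stage <- function(config, population, sd_state, p, stage = 1L, graph = NULL) {
  params <- cfg_sd_params(config)
  cspec <- cfg_contact_spec(config)
  rules <- rule_base()
  steps_per_unit <- round(1 / params$dt)
  grid_n <- config$engine$grid_n
  thinning <- max(1L, config$engine$thinning)

  sd_rows <- vector("list", config$engine$tau_len * steps_per_unit)
  agent_rows <- vector("list", config$engine$tau_len)
  row_i <- 0L

  for (u in seq_len(config$engine$tau_len)) {
    for (s in seq_len(steps_per_unit)) {
      sd_state <- sd_controller_step(sd_state, params, p, rules, grid_n)
      row_i <- row_i + 1L
      if ((row_i - 1L) %% thinning == 0L) {
        sd_rows[[row_i]] <- tibble::tibble(
          stage = stage, t = sd_state$t,
          s1 = sd_state$s1, s2 = sd_state$s2, rho = sd_state$rho,
          omega = sd_state$omega, z_cog = sd_state$z_cog, p = sd_state$p,
          phi1 = sd_state$phi1, phi2 = sd_state$phi2,
          lambda1 = sd_state$lambda1, lambda2 = sd_state$lambda2
        )
      }
    }
    if (!is.finite(sd_state$s1) || !is.finite(sd_state$s2) || !is.finite(sd_state$rho)) {
      stop("numeric failure: non-finite state at t = ", sd_state$t, call. = FALSE)
    }
    population <- perceive(population, c(sd_state$s1, sd_state$s2))
    pairs <- contact_pairs(config$population$n, cspec, graph)
    population <- interaction_round(population, pairs, config$interaction$rule)
    agent_rows[[u]] <- tibble::tibble(
      stage = stage, t = sd_state$t,
      agent_id = population$agent_id, variable = population$variable,
      x = population$x,
      mu_low_geometric = population$mu_low,
      mu_low_social = population$mu_low_social,
      mu_medium = population$mu_medium, mu_high = population$mu_high,
      bin = assign_bin(population$mu_low_social)
    )
  }
  assignments <- cluster_subspaces(population)
  disc <- discrepancy(assignments, default_p = config$sd$p)
  list(
    population = population,
    sd_state = sd_state,
    agent_trace = dplyr::bind_rows(agent_rows),
    sd_trace = dplyr::bind_rows(sd_rows),
    discrepancy = disc,
    homogenized = disc$homogenized
  )
}

#' Run the staged hybrid simulation
#'
#' Repeats [run_stage()], feeding each stage's discrepancy signal into
#' the next stage's allocation fraction (when `adaptive_p` is set), until
#' the homogenization fraction — the share of (agent, variable) pairs in
#' membership bin 0 — reaches the configured threshold or the stage
#' budget is exhausted. All randomness derives from `engine$seed`, so a
#' given configuration reproduces bit-identical traces.
#'
#' @param config An `engine_config`.
#'
#' @return An object of class `hybrid_sim`: the configuration, the bound
#'   `agent_trace` and `sd_trace` tibbles, per-stage summaries (`stages`
#'   tibble), the final population and SD state, and a `summary` list
#'   (stages run, final homogenized fraction, total invested, final
#'   stocks and fund).
#' @examples
#' \donttest{
#' sim <- run_simulation(demo_config("small", seed = 1))
#' glance(sim)
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "engine_config"))
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n", paste0("  - ", problems, collapse = "\n"),
      call. = FALSE
    )
  }
  set.seed(config$engine$seed)
  population <- init_agents(
    config$population$n, cfg_var_specs(config),
    config$population$init_x
  )
  graph <- NULL
  if (config$contact$mode == "scale_free") {
    graph <- scale_free_graph(config$population$n, config$contact$q_exponent)
  }
  sd_state <- sd_init(cfg_sd_params(config))
  p <- config$sd$p

  agent_traces <- list()
  sd_traces <- list()
  stage_rows <- list()
  n_stages <- 0L
  for (stage in seq_len(config$engine$max_stages)) {
    res <- run_stage(config, population, sd_state, p, stage = stage, graph = graph)
    population <- res$population
    sd_state <- res$sd_state
    agent_traces[[stage]] <- res$agent_trace
    sd_traces[[stage]] <- res$sd_trace
    needs <- res$discrepancy$needs
    stage_rows[[stage]] <- tibble::tibble(
      stage = stage,
      p_used = p,
      need_coasf = needs$need[needs$variable == 1],
      need_csshf = needs$need[needs$variable == 2],
      p_next = res$discrepancy$p,
      homogenized = res$homogenized
    )
    n_stages <- stage
    if (config$sd$adaptive_p) p <- res$discrepancy$p
    if (res$homogenized >= config$engine$homog_threshold) break
  }
  stages <- dplyr::bind_rows(stage_rows)
  structure(
    list(
      config = config,
      agent_trace = dplyr::bind_rows(agent_traces),
      sd_trace = dplyr::bind_rows(sd_traces),
      stages = stages,
      population = population,
      sd_state = sd_state,
      summary = list(
        stages_run = n_stages,
        final_homogenized = stages$homogenized[n_stages],
        total_invested = sd_state$invested,
        final_s1 = sd_state$s1,
        final_s2 = sd_state$s2,
        final_rho = sd_state$rho,
        seed = config$engine$seed
      )
    ),
    class = "hybrid_sim"
  )
}

#' @export
print.hybrid_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<hybrid_sim> %d agents, %d stage(s) run\n",
      "  final homogenized fraction: %.3f\n",
      "  total invested: %.2f (fund left: %.2f)\n",
      "  final stocks: COASF = %.2f, CSSHF = %.2f\n"
    ),
    x$config$population$n, s$stages_run, s$final_homogenized,
    s$total_invested, s$final_rho, s$final_s1, s$final_s2
  ))
  invisible(x)
}

#' Write the run's trajectory tables and summary to a directory
#'
#' Emits `agents.csv` (one row per agent, variable, and time unit),
#' `sd_trace.csv` (one row per retained integration sub-step), and
#' `summary.json`.
#'
#' @param sim A `hybrid_sim`.
#' @param dir Output directory (created if missing).
#'
#' @return The directory path, invisibly.
#' @export
write_traces <- function(sim, dir) {
  stopifnot(inherits(sim, "hybrid_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$agent_trace, file.path(dir, "agents.csv"))
  readr::write_csv(sim$sd_trace, file.path(dir, "sd_trace.csv"))
  jsonlite::write_json(sim$summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
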