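tiny_config <- function(seed = 1, max_stages = 2, homog_threshold = 0.99, ...) {
  engine_config(
    n = 12,
    var_specs = list(
      list(b_mean = 2, c_mean = 5, d_mean = 8, b_sd = 0.3, c_sd = 0.3, d_sd = 0.3),
      list(b_mean = 2, c_mean = 5, d_mean = 8, b_sd = 0.3, c_sd = 0.3, d_sd = 0.3)
    ),
    contact = list(mode = "random", k = 2),
    sd = list(
      C = 200, d1 = 20, d2 = 20, d3 = 5, p = 0.5, dt = 1 / 16,
      coasf_terms = c(2, 5, 8), csshf_terms = c(2, 5, 8)
    ),
    tau_len = 2, max_stages = max_stages, homog_threshold = homog_threshold,
    seed = seed, ...
  )
}

test_that("demo presets build valid, reproducible configurations", {
  small <- demo_config("small", seed = 7)
  expect_length(validate_config(small), 0)
  expect_equal(small$population$n, 50)
  expect_equal(small$engine$tau_len, 5)
  expect_equal(small$engine$max_stages, 3)

  big1 <- demo_config("large", seed = 3)
  big2 <- demo_config("large", seed = 3)
  expect_identical(big1, big2)
  expect_equal(big1$population$n, 1000)
})

test_that("configuration validation itemizes every problem", {
  cfg <- demo_config("small")
  broken <- unclass(cfg)
  broken$sd$p <- 1.5
  problems <- validate_config(broken)
  expect_true(any(grepl("sd", problems) & grepl("allocation fraction", problems)))

  broken$contact$k <- 60
  problems <- validate_config(broken)
  expect_true(any(grepl("k", problems)))

  no_section <- broken[setdiff(names(broken), "engine")]
  expect_true(any(grepl("engine: section missing", validate_config(no_section))))

  expect_match(validate_config("/nonexistent/file.yaml"), "not found")
  expect_error(
    engine_config(
      n = 10,
      var_specs = list(list(b_mean = 2, c_mean = 5, d_mean = 8, b_sd = 0, c_sd = 0, d_sd = 0)),
      sd = cfg$sd, seed = 0
    ),
    "exactly 2 linguistic variables"
  )
})

test_that("configurations round-trip through YAML", {
  cfg <- demo_config("small", seed = 11)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  expect_length(validate_config(path), 0)
})

test_that("identical seeds give bit-identical traces and CSV output", {
  sim1 <- run_simulation(tiny_config(seed = 5))
  sim2 <- run_simulation(tiny_config(seed = 5))
  expect_identical(sim1$agent_trace, sim2$agent_trace)
  expect_identical(sim1$sd_trace, sim2$sd_trace)
  expect_identical(sim1$summary, sim2$summary)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_traces(sim1, d1)
  write_traces(sim2, d2)
  for (f in c("agents.csv", "sd_trace.csv", "summary.json")) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }

  sim3 <- run_simulation(tiny_config(seed = 6))
  expect_false(identical(sim1$agent_trace, sim3$agent_trace))
})

test_that("trace CSVs round-trip the in-memory tables", {
  sim <- run_simulation(tiny_config(seed = 2))
  dir <- withr::local_tempdir()
  write_traces(sim, dir)
  agents <- readr::read_csv(file.path(dir, "agents.csv"), show_col_types = FALSE)
  expect_equal(nrow(agents), nrow(sim$agent_trace))
  num <- vapply(sim$agent_trace, is.numeric, logical(1))
  for (col in names(sim$agent_trace)[num]) {
    expect_lt(max(abs(agents[[col]] - sim$agent_trace[[col]]), 0), 1e-12)
  }
  sdt <- readr::read_csv(file.path(dir, "sd_trace.csv"), show_col_types = FALSE)
  expect_equal(max(abs(sdt$rho - sim$sd_trace$rho)), 0)
})

test_that("stage accounting and stopping rules behave as configured", {
  one <- run_simulation(tiny_config(seed = 3, max_stages = 1, homog_threshold = 1))
  expect_equal(one$summary$stages_run, 1)
  expect_equal(dplyr::n_distinct(one$agent_trace$stage), 1)

  eager <- run_simulation(tiny_config(seed = 3, homog_threshold = 0))
  expect_equal(eager$summary$stages_run, 1) # threshold 0 stops after one stage

  sim <- run_simulation(tiny_config(seed = 4))
  cfg <- tiny_config(seed = 4)
  expect_equal(
    nrow(sim$agent_trace),
    sim$summary$stages_run * cfg$engine$tau_len * 12 * 2
  )
  expect_equal(
    nrow(sim$sd_trace),
    sim$summary$stages_run * cfg$engine$tau_len * round(1 / cfg$sd$dt)
  )
  # time advances contiguously across stage boundaries
  expect_true(all(diff(sim$sd_trace$t) > 0))
  # fund conservation across stages
  expect_lt(
    abs(sim$sd_state$rho + sim$sd_state$invested - cfg$sd$C), 1e-9
  )
})

test_that("heterogeneous constants produce membership fans", {
  sim <- run_simulation(tiny_config(seed = 9))
  first_unit <- sim$agent_trace[sim$agent_trace$t == min(sim$agent_trace$t), ]
  per_var <- tapply(
    first_unit$mu_low_geometric, first_unit$variable,
    function(v) length(unique(v))
  )
  expect_true(all(per_var > 1))
})

test_that("a decaying capacity signal reproduces the exponential closed form", {
  # Euler decay from s0 = 10 with no inflow is exactly exp(beta - alpha t)
  # at the step times, with alpha = -log(1 - dt/d1)/dt and beta = log(10)
  params <- sd_params(
    C = 1, d1 = 10, d2 = 10, d3 = 5, p = 0.5, dt = 1 / 16,
    coasf_terms = term_params(2, 5, 8), csshf_terms = term_params(2, 5, 8)
  )
  state <- sd_init(params, s1 = 10, s2 = 10)
  alpha <- -log(1 - params$dt / params$d1) / params$dt
  spec <- trajectory_spec("exponential", alpha = alpha, beta = log(10), t4 = 40)

  set.seed(1)
  pop <- init_agents(
    5, list(constant_spec(2, 5, 8), constant_spec(2, 5, 8)),
    init_x = 10
  )
  worst <- 0
  for (k in seq_len(30 / params$dt)) {
    state <- sd_step(state, params, p = 0.5, z_cog = 0) # decay only
    pop <- perceive(pop, c(state$s1, state$s2))
    expected <- membership_trajectory(state$t, spec, term_params(2, 5, 8))
    worst <- max(worst, abs(pop$mu_low - expected$low))
  }
  expect_lt(worst, 1e-9)
})

test_that("the command-line interface validates, runs, and reports failures", {
  cli <- system.file("cli", "hybridsim.R", package = "fuzzyhybrid")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_config(tiny_config(seed = 1), cfg_path)
  ok <- system2(rscript, c(cli, "validate", "--config", cfg_path))
  expect_equal(ok, 0L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  raw <- yaml::read_yaml(cfg_path)
  raw$sd$p <- 1.5
  yaml::write_yaml(raw, bad)
  expect_equal(
    system2(rscript, c(cli, "validate", "--config", bad), stdout = FALSE), 2L
  )

  out <- withr::local_tempdir()
  code <- system2(rscript, c(cli, "run", "--config", cfg_path, "--out", out),
    stdout = FALSE
  )
  expect_equal(code, 0L)
  expect_true(all(file.exists(file.path(out, c("agents.csv", "sd_trace.csv", "summary.json")))))
})
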