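# Shared fixtures, all generated in code.

std_params <- function() term_params(2, 5, 8)

linear_spec <- function() trajectory_spec("linear", alpha = 1, beta = 10, t4 = 9.5)

exp_spec <- function() trajectory_spec("exponential", alpha = 1, beta = log(10), t4 = 2)

# Random valid (x, term_params) pairs for property tests.
random_cases <- function(n, seed = 7) {
  withr::with_seed(seed, {
    b <- runif(n, 0.1, 5)
    c <- b + runif(n, 0.1, 5)
    d <- c + runif(n, 0.1, 5)
    x <- runif(n, 0, 15)
    tibble::tibble(x = x, b = b, c = c, d = d)
  })
}

# A population tibble with prescribed social Low values (one variable),
# bypassing sampling; enough structure for interaction/clustering tests.
toy_population <- function(mu_low, b = rep(2, length(mu_low)), variable = 1L) {
  n <- length(mu_low)
  tibble::tibble(
    agent_id = seq_len(n), variable = variable,
    b = b, c = b + 3, d = b + 6,
    x = 0, mu_low = mu_low, mu_medium = 0, mu_high = 0,
    mu_low_social = mu_low
  )
}

# All permutations of 1..n as a list of integer vectors (n small).
combinat_perms <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Central finite differences of a scalar function on a time grid.
fd_first <- function(f, t, h = 1e-5) (f(t + h) - f(t - h)) / (2 * h)
fd_second <- function(f, t, h = 1e-3) (f(t + h) - 2 * f(t) + f(t - h)) / h^2

low_traj_fun <- function(spec, params) {
  function(t) membership_trajectory(t, spec, params)$low
}
term_traj_fun <- function(spec, params, term) {
  function(t) membership_trajectory(t, spec, params)[[term]]
}
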