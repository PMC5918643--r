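two_var_specs <- function(sd = 0.3) {
  list(constant_spec(2, 5, 8, sd = sd), constant_spec(2, 5, 8, sd = sd))
}

test_that("population initialisation is structured, heterogeneous, and seeded", {
  set.seed(1)
  degenerate <- init_agents(2, two_var_specs(sd = 0), init_x = 0)
  expect_equal(nrow(degenerate), 4) # 2 agents x 2 variables
  by_agent <- split(degenerate[c("b", "c", "d")], degenerate$agent_id)
  expect_identical(by_agent[[1]], by_agent[[2]], ignore_attr = TRUE)

  set.seed(42)
  a <- init_agents(100, two_var_specs(), init_x = c(0, 1))
  set.seed(42)
  b <- init_agents(100, two_var_specs(), init_x = c(0, 1))
  expect_identical(a, b)

  set.seed(3)
  big <- init_agents(1000, two_var_specs(), init_x = 0)
  expect_equal(nrow(big), 2000)
  expect_equal(dplyr::n_distinct(big$agent_id), 1000)
  # memberships initialised from the base value
  expect_equal(big$mu_low, fz_membership(big$x, big[c("b", "c", "d")])$low)
  expect_equal(big$mu_low_social, big$mu_low)
})

test_that("random contacts have no self-pairs and each agent initiates k", {
  set.seed(1)
  spec <- contact_spec("random", k = 1)
  p2 <- contact_pairs(2, spec)
  expect_true(all(p2$i != p2$r))
  expect_true(all(sort(unique(c(p2$i, p2$r))) == 1:2)) # the only possible pair

  spec3 <- contact_spec("random", k = 3)
  many <- dplyr::bind_rows(lapply(1:100, function(i) contact_pairs(10, spec3)))
  expect_true(all(many$i != many$r))
  expect_equal(unname(c(table(many$i))), rep(300L, 10)) # k draws per initiator
  per_round <- dplyr::count(contact_pairs(10, spec3), i, r)
  expect_true(all(per_round$n == 1)) # partners drawn without replacement

  expect_error(contact_pairs(3, contact_spec("random", k = 3)), "smaller")
  expect_error(contact_spec("random", k = 6), "k must satisfy")
  expect_error(contact_spec("scale_free", q_exponent = 3.5), "q_exponent")
})

test_that("random contact frequencies are uniform over ordered pairs", {
  set.seed(8)
  spec <- contact_spec("random", k = 1)
  n <- 4
  rounds <- 3000
  counts <- matrix(0, n, n)
  for (r in seq_len(rounds)) {
    p <- contact_pairs(n, spec)
    for (j in seq_len(nrow(p))) counts[p$i[j], p$r[j]] <- counts[p$i[j], p$r[j]] + 1
  }
  off <- counts[row(counts) != col(counts)]
  expected <- rounds / (n - 1)
  sigma <- sqrt(rounds * (1 / (n - 1)) * (1 - 1 / (n - 1)))
  expect_true(all(abs(off - expected) < 5 * sigma))
})

test_that("scale-free contacts follow a power-law degree distribution", {
  set.seed(21)
  g <- fuzzyhybrid:::scale_free_graph(5000, 2.5)
  deg <- igraph::degree(g)
  fit <- igraph::fit_power_law(deg[deg > 0], xmin = 1)
  expect_gt(fit$alpha, 2)
  expect_lt(fit$alpha, 3)

  pairs <- contact_pairs(5000, contact_spec("scale_free", k = 3), graph = g)
  expect_true(all(pairs$i != pairs$r))
  expect_lte(max(table(pairs$i)), 3) # capped at k per initiating agent
  # pairs are edges of the fixed graph
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(el[, 1], el[, 2])
  expect_true(all(paste(pairs$i, pairs$r) %in% key))
})

test_that("pairwise update rules implement min, max, and b-weighted averaging", {
  expect_equal(update_pessimistic(0.3, 0.7), list(mu_i = 0.3, mu_r = 0.3))
  expect_equal(update_optimistic(0.3, 0.7), list(mu_i = 0.7, mu_r = 0.7))
  expect_equal(update_pessimistic(0.4, 0.4), list(mu_i = 0.4, mu_r = 0.4))

  # equal constants: plain average
  expect_equal(update_realistic(0.2, 0.6, 2, 2), list(mu_i = 0.4, mu_r = 0.4))
  # equal memberships are a fixed point for any weights
  expect_equal(update_realistic(0.5, 0.5, 1, 9), list(mu_i = 0.5, mu_r = 0.5))
  # the agent with smaller b defers more to its peer: phi_i < omega_i iff b_r > b_i
  b_i <- 1.5
  b_r <- 4
  omega_i <- b_r / (b_i + b_r)
  expect_gt(omega_i, 1 - omega_i)
  upd <- update_realistic(0, 1, b_i, b_r)
  expect_equal(upd$mu_i, omega_i) # pulled mostly toward the peer
  expect_equal(upd$mu_r, b_r / (b_i + b_r)) # peer keeps most of its own value
})

test_that("interaction rounds are monotone and keep the population envelope", {
  pop <- toy_population(c(0.1, 0.3, 0.5, 0.7, 0.9), b = c(1, 2, 3, 4, 5))
  pairs <- tibble::tibble(i = c(1L, 2L, 4L), r = c(3L, 5L, 1L))

  pess <- interaction_round(pop, pairs, "pessimistic")
  expect_true(all(pess$mu_low_social <= pop$mu_low_social))
  expect_equal(min(pess$mu_low_social), min(pop$mu_low_social))

  opt <- interaction_round(pop, pairs, "optimistic")
  expect_true(all(opt$mu_low_social >= pop$mu_low_social))
  expect_equal(max(opt$mu_low_social), max(pop$mu_low_social))

  real <- interaction_round(pop, pairs, "realistic")
  expect_true(all(real$mu_low_social >= min(pop$mu_low_social) - 1e-12))
  expect_true(all(real$mu_low_social <= max(pop$mu_low_social) + 1e-12))

  expect_identical(interaction_round(pop, pairs[0, ], "pessimistic"), pop)
  expect_error(interaction_round(pop, pairs, "nonsense"))
})

test_that("repeated all-pairs rounds drive the population to its extreme value", {
  pop <- toy_population(c(0.1, 0.5, 0.9))
  all_pairs <- tibble::tibble(i = c(1L, 1L, 2L), r = c(2L, 3L, 3L))
  pess <- pop
  opt <- pop
  for (k in 1:3) {
    pess <- interaction_round(pess, all_pairs, "pessimistic")
    opt <- interaction_round(opt, all_pairs, "optimistic")
  }
  expect_equal(pess$mu_low_social, rep(0.1, 3))
  expect_equal(opt$mu_low_social, rep(0.9, 3))
})

test_that("perceiving the intervention signal resets memberships from geometry", {
  set.seed(2)
  pop <- init_agents(10, two_var_specs(sd = 0.2), init_x = 0)
  lo <- perceive(pop, c(0.1, 0.1)) # below every agent's b
  expect_true(all(lo$mu_low == 1))
  hi <- perceive(pop, c(50, 50)) # above every agent's d
  expect_true(all(hi$mu_high == 1))
  expect_true(all(hi$mu_low_social == 0)) # social value overwritten by perception

  mid <- perceive(pop, c(5, 5))
  spread <- tapply(mid$mu_low, mid$variable, function(v) length(unique(v)))
  expect_true(all(spread > 1)) # heterogeneous constants, same signal
  expect_error(perceive(pop, c(-1, 0)), ">= 0")
})
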