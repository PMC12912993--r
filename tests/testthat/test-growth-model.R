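test_that("innovation probability follows p = min(1, p0 / sum(k^theta))", {
  expect_equal(innovation_probability(function_tally(rep(1, 4)),
                                      quiet_params(p0 = 1, theta = 0)), 0.25)
  # theta = 1 depends only on N
  expect_equal(innovation_probability(function_tally(c(60, 30, 10)),
                                      quiet_params(p0 = 1, theta = 1)), 0.01)
  expect_equal(innovation_probability(function_tally(c(4, 1)),
                                      quiet_params(p0 = 1, theta = 0.5)),
               1 / 3)
  # p0 / sum can exceed 1 for small systems; clamped to a probability
  expect_equal(innovation_probability(function_tally(10),
                                      quiet_params(p0 = 2, theta = 0)), 1)
})

test_that("limit reductions p0/D (theta=0) and p0/N (theta=1) are exact", {
  set.seed(41)
  for (i in 1:25) {
    tal <- rand_tally()
    p0 <- runif(1, 0.1, 0.9)
    expect_identical(
      innovation_probability(tal, quiet_params(p0 = p0, theta = 0)),
      p0 / diversity(tal))
    expect_identical(
      innovation_probability(tal, quiet_params(p0 = p0, theta = 1)),
      p0 / system_size(tal))
  }
})

test_that("innovation probability rejects numeric overflow with a named error", {
  tal <- function_tally(c(1000, 1))
  expect_error(innovation_probability(tal, quiet_params(theta = 200)),
               "non-finite weight.*1000.*200")
})

test_that("attachment distribution matches k^gamma / sum(k^gamma)", {
  expect_equal(attachment_distribution(function_tally(c(3, 1)), gamma = 1),
               c(0.75, 0.25))
  expect_equal(attachment_distribution(function_tally(c(5, 2, 1)), gamma = 0),
               rep(1 / 3, 3))
  expect_equal(attachment_distribution(function_tally(c(4, 1)), gamma = 0.5),
               c(2 / 3, 1 / 3))
  # symmetry: equal counts share probability regardless of gamma
  for (g in c(0, 0.37, 1, 1.4)) {
    expect_equal(attachment_distribution(function_tally(c(2, 2)), gamma = g),
                 c(0.5, 0.5))
  }
  set.seed(42)
  for (i in 1:25) {
    q <- attachment_distribution(rand_tally(), gamma = runif(1, 0, 1.5))
    expect_lt(abs(sum(q) - 1), 1e-12)
    expect_true(all(q > 0))
  }
})

test_that("a single arrival conserves N and changes D by 0 or +1", {
  # forced innovation: p = p0/D = 1 from a single function
  res <- advance_one_arrival(function_tally(1L), quiet_params(p0 = 1, theta = 0))
  expect_identical(res$event$type, "innovated")
  expect_identical(res$state$counts, c(1L, 1L))

  set.seed(7)
  state <- function_tally(c(3, 1))
  params <- quiet_params(p0 = 0.5, theta = 0.3, gamma = 0.8)
  for (i in 1:200) {
    n_before <- system_size(state)
    d_before <- diversity(state)
    res <- advance_one_arrival(state, params)
    state <- res$state
    expect_identical(system_size(state), n_before + 1L)
    expect_true(diversity(state) %in% c(d_before, d_before + 1L))
  }
})

test_that("advance_one_arrival attachment frequencies match the kernel", {
  # p0 = 0 forces the join branch; compare Monte-Carlo frequencies to
  # the analytic kernel within 3-sigma binomial bounds
  set.seed(11)
  params <- quiet_params(p0 = 0, theta = 0, gamma = 1)
  base <- function_tally(c(3, 1))
  n_draws <- 20000
  hits <- 0L
  for (i in seq_len(n_draws)) {
    res <- advance_one_arrival(base, params)
    if (res$event$index == 1L) hits <- hits + 1L
  }
  p_hat <- hits / n_draws
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / n_draws))
})

test_that("the compiled sampler draws from the attachment kernel", {
  # same weight-tree code path as the growth loop, fixed state
  set.seed(12)
  counts <- c(5L, 2L, 1L)
  gamma <- 0.5
  q <- attachment_distribution(function_tally(counts), gamma)
  draws <- funcdiv:::rcpp_draw_attachments(counts, gamma, 1e5)
  freq <- tabulate(draws, nbins = 3) / 1e5
  expect_true(all(abs(freq - q) < 3 * sqrt(q * (1 - q) / 1e5)))

  # gamma = 1 is equivalent to copying a uniformly chosen individual:
  # q_i = k_i / N; chi-square GOF on the draw counts
  set.seed(13)
  draws1 <- funcdiv:::rcpp_draw_attachments(counts, 1, 1e5)
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(draws1, nbins = 3), p = counts / sum(counts)))
  expect_gt(gof$p.value, 0.001)
})

test_that("growth without innovation keeps a single growing function", {
  tr <- simulate_growth(function_tally(1L), quiet_params(p0 = 0, gamma = 1),
                        n_final = 100, checkpoints = 100, seed = 5)
  expect_identical(tr$final_state$counts, 100L)
  expect_identical(diversity(tr$final_state), 1L)
})

test_that("trajectories are deterministic given the seed and record valid checkpoints", {
  params <- quiet_params(p0 = 1, theta = 0.5, gamma = 0.8)
  a <- simulate_growth(params = params, n_final = 5000, seed = 99)
  b <- simulate_growth(params = params, n_final = 5000, seed = 99)
  expect_identical(a$checkpoints, b$checkpoints)
  expect_identical(a$final_state$counts, b$final_state$counts)

  expect_true(all(diff(a$checkpoints$N) > 0))
  expect_true(all(diff(a$checkpoints$D) >= 0))
  expect_identical(system_size(a$final_state), 5000L)
  expect_identical(utils::tail(a$checkpoints$N, 1), 5000)

  expect_error(simulate_growth(function_tally(c(5, 5)), params, n_final = 10),
               "exceed")
})

test_that("incremental running sums agree with full recomputation after 1e5 arrivals", {
  # rebuild disabled so the returned sums carry the full incremental drift
  params <- quiet_params(p0 = 1, theta = 0.7, gamma = 0.8)
  tr <- simulate_growth(params = params, n_final = 1e5 + 1, seed = 17,
                        checkpoints = 1e5 + 1, rebuild_every = 0)
  k <- as.numeric(tr$final_state$counts)
  expect_lt(abs(tr$running_sums["sum_theta"] - sum(k^0.7)) / sum(k^0.7), 1e-9)
  expect_lt(abs(tr$running_sums["sum_gamma"] - sum(k^0.8)) / sum(k^0.8), 1e-9)
})

test_that("ensembles use deterministic child seeds and summarize checkpoints", {
  params <- quiet_params(p0 = 1, theta = 0, gamma = 0.8)
  one <- simulate_ensemble(params = params, n_final = 2000, replicates = 1,
                           master_seed = 3)
  expect_identical(one$summary$mean_D,
                   as.numeric(one$trajectories[[1]]$checkpoints$D))
  expect_true(all(is.na(one$summary$se_D)))

  e1 <- simulate_ensemble(params = params, n_final = 2000, replicates = 5,
                          master_seed = 3)
  e2 <- simulate_ensemble(params = params, n_final = 2000, replicates = 5,
                          master_seed = 3)
  expect_identical(e1$summary, e2$summary)
  for (r in 1:5) {
    expect_identical(e1$trajectories[[r]]$checkpoints,
                     e2$trajectories[[r]]$checkpoints)
  }
})

test_that("with theta = 0 the diversity dynamics are independent of gamma", {
  # p depends only on D when theta = 0, so D(N) has the same law at any gamma
  n_rep <- 40
  d_at <- function(gamma, master) {
    ens <- simulate_ensemble(params = quiet_params(1, 0, gamma),
                             n_final = 3000, replicates = n_rep,
                             master_seed = master, checkpoints = 3000)
    vapply(ens$trajectories, function(tr) diversity(tr$final_state), integer(1))
  }
  ks <- suppressWarnings(stats::ks.test(d_at(0.2, 21), d_at(0.9, 22)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean-field closed forms solve dD/dN = p in both limits", {
  # initial condition honored exactly
  expect_equal(mean_field_diversity(0, p0 = 2, n0 = 50, d0 = 7, n = 50), 7)
  expect_equal(mean_field_diversity(1, p0 = 2, n0 = 50, d0 = 7, n = 50), 7)
  # dD/dN = p0/D  ->  D = sqrt(d0^2 + 2 p0 (n - n0))
  expect_equal(mean_field_diversity(0, 1, 1, 1, 1e4), sqrt(1 + 2 * (1e4 - 1)))
  # dD/dN = p0/N  ->  D = d0 + p0 ln(n/n0)
  expect_equal(mean_field_diversity(1, 1, 1, 1, 1e4), 1 + log(1e4))
  expect_error(mean_field_diversity(0.5, 1, 1, 1, 10), "closed-form")
})

test_that("ensemble mean diversity tracks the analytic limits within 3 SE", {
  n_rep <- 40
  # theta = 0: sqrt growth
  e0 <- simulate_ensemble(params = quiet_params(1, 0, 0.8), n_final = 3000,
                          replicates = n_rep, master_seed = 31,
                          checkpoints = 3000)
  d0 <- vapply(e0$trajectories, function(tr) diversity(tr$final_state),
               integer(1))
  se0 <- sd(d0) / sqrt(n_rep)
  expect_lt(abs(mean(d0) - mean_field_diversity(0, 1, 1, 1, 3000)), 3 * se0)

  # theta = 1: exact Bernoulli-sum mean, any gamma
  e1 <- simulate_ensemble(params = quiet_params(1, 1, 0.4), n_final = 3000,
                          replicates = n_rep, master_seed = 32,
                          checkpoints = 3000)
  d1 <- vapply(e1$trajectories, function(tr) diversity(tr$final_state),
               integer(1))
  se1 <- sd(d1) / sqrt(n_rep)
  expect_lt(abs(mean(d1) - exact_mean_diversity_theta1(3000)), 3 * se1)
})

test_that("unusual parameter regimes warn about their dynamics", {
  expect_warning(model_params(theta = -0.5, gamma = 0.5), "promote")
  expect_warning(model_params(theta = 0, gamma = 1.2), "gelation")
  expect_silent(model_params(theta = -0.5, gamma = 1.2, quiet = TRUE))
})
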