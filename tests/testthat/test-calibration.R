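make_target <- function(theta, gamma, n_final = 2000, seed = 900,
                        n_init = 50) {
  simulate_growth(params = quiet_params(1, theta, gamma), n_final = n_final,
                  checkpoints = n_final, seed = seed,
                  snapshot_sizes = n_init)
}

test_that("the objective is deterministic and zero at its own mean profile", {
  settings <- calibration_settings(replicates = 4, seed = 55)
  gen <- make_target(0.5, 0.8)
  target <- compute_rank_frequency(gen$final_state)
  init <- gen$snapshots[["50"]]

  l1 <- calibration_objective(0.5, 0.8, target, init, 2000, settings)
  l2 <- calibration_objective(0.5, 0.8, target, init, 2000, settings)
  expect_identical(l1, l2)
  expect_gte(l1, 0)

  # target equal to the objective's own ensemble profile, no penalty -> 0
  finals <- lapply(1:4, function(r) {
    simulate_growth(init, quiet_params(1, 0.5, 0.8), 2000,
                    checkpoints = 2000,
                    seed = child_seed(55, r))$final_state
  })
  profile <- ensemble_mean_rank_frequency(finals)
  s0 <- calibration_settings(replicates = 4, seed = 55, penalty_weight = 0)
  expect_equal(calibration_objective(0.5, 0.8, profile, init, 2000, s0), 0)
})

test_that("the objective is lower at the generating parameters than at offsets", {
  # target generated from the same initial state with the objective's own
  # replicate seed: evaluating at the truth replays the generating
  # trajectory exactly, so the loss there is 0
  settings <- calibration_settings(replicates = 1, seed = 77)
  init <- simulate_growth(params = quiet_params(1, 1, 0.8), n_final = 50,
                          checkpoints = 50, seed = 900)$final_state
  gen <- simulate_growth(init, quiet_params(1, 1, 0.8), n_final = 2000,
                         checkpoints = 2000, seed = child_seed(77, 1))
  target <- compute_rank_frequency(gen$final_state)
  at_truth <- calibration_objective(1, 0.8, target, init, 2000, settings)
  expect_identical(at_truth, 0)
  expect_lt(at_truth,
            calibration_objective(1.5, 0.8, target, init, 2000, settings))
  expect_lt(at_truth,
            calibration_objective(1, 1.3, target, init, 2000, settings))
})

test_that("calibrate respects bounds, is reproducible, and its loss re-evaluates", {
  gen <- make_target(0.5, 0.8, n_final = 1000)
  settings <- calibration_settings(replicates = 3, pop_size = 8,
                                   max_generations = 6, seed = 19)
  init <- gen$snapshots[["50"]]
  fit <- calibrate(gen$final_state, init, settings)
  expect_gte(fit$theta_hat, settings$theta_bounds[1])
  expect_lte(fit$theta_hat, settings$theta_bounds[2])
  expect_gte(fit$gamma_hat, settings$gamma_bounds[1])
  expect_lte(fit$gamma_hat, settings$gamma_bounds[2])

  # reported loss reproducible bitwise from (theta_hat, gamma_hat, seed)
  target <- compute_rank_frequency(gen$final_state)
  re <- calibration_objective(fit$theta_hat, fit$gamma_hat, target, init,
                              1000, settings)
  expect_identical(re, fit$loss)

  fit2 <- calibrate(gen$final_state, init, settings)
  expect_identical(fit2$theta_hat, fit$theta_hat)
  expect_identical(fit2$gamma_hat, fit$gamma_hat)
  expect_identical(fit2$loss, fit$loss)
})

test_that("bounds collapsed to a point return that point with its objective", {
  gen <- make_target(0.5, 0.8, n_final = 1000)
  settings <- calibration_settings(theta_bounds = c(0.3, 0.3),
                                   gamma_bounds = c(0.6, 0.6),
                                   replicates = 2, pop_size = 4,
                                   max_generations = 3, seed = 5)
  fit <- calibrate(gen$final_state, gen$snapshots[["50"]], settings)
  expect_identical(fit$theta_hat, 0.3)
  expect_identical(fit$gamma_hat, 0.6)
  target <- compute_rank_frequency(gen$final_state)
  expect_identical(fit$loss,
                   calibration_objective(0.3, 0.6, target,
                                         gen$snapshots[["50"]], 1000,
                                         settings))
})

test_that("the recovery harness is deterministic and reports errors per cell", {
  grid <- data.frame(theta = 0.5, gamma = 0.8)
  settings <- calibration_settings(replicates = 3, pop_size = 8,
                                   max_generations = 8, seed = 23)
  r1 <- recovery_experiment(grid, n_final = 1000, settings = settings,
                            n_init = 50)
  r2 <- recovery_experiment(grid, n_final = 1000, settings = settings,
                            n_init = 50)
  expect_identical(r1$results, r2$results)
  expect_named(r1$aggregate, c("bias", "rmse"))
  expect_equal(r1$results$theta_err,
               r1$results$theta_hat - r1$results$theta)
  expect_true(all(abs(r1$per_cell$theta_err_median) <=
                    diff(settings$theta_bounds)))
})

test_that("measurement noise does not improve parameter recovery", {
  grid <- data.frame(theta = 0.5, gamma = 0.8)
  settings <- calibration_settings(replicates = 4, pop_size = 10,
                                   max_generations = 12, seed = 29)
  clean <- recovery_experiment(grid, n_final = 2000, noise_level = 0,
                               settings = settings, repeats = 3, n_init = 50)
  noisy <- recovery_experiment(grid, n_final = 2000, noise_level = 0.5,
                               settings = settings, repeats = 3, n_init = 50)
  rmse <- function(r) sqrt(mean(c(r$results$theta_err, r$results$gamma_err)^2))
  expect_gte(rmse(noisy), rmse(clean))
})

test_that("log-normal count perturbation preserves positivity and diversity", {
  tal <- function_tally(c(50, 20, 5, 1, 1))
  pert <- perturb_counts(tal, 0.3, seed = 9)
  expect_identical(diversity(pert), diversity(tal))
  expect_true(all(pert$counts >= 1))
  expect_identical(perturb_counts(tal, 0), tal)
  p1 <- perturb_counts(tal, 0.3, seed = 9)
  expect_identical(p1$counts, pert$counts)
})
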