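#' Parameters of the generalized Yule-Simon growth process
#'
#' The process is governed by three parameters.  `p0` is the innovation
#' scale, absorbing environmental effects assumed constant within a class
#' of systems.  `theta` is the diversification exponent: the probability
#' that an arriving individual creates a new function is
#' `p = min(1, p0 / sum(k_i^theta))`, so `theta = 0` gives suppression by
#' richness alone (`p = p0/D`) and `theta = 1` gives suppression by total
#' size (`p = p0/N`).  `gamma` is the specialization exponent: a newcomer
#' that does not innovate joins function `i` with probability proportional
#' to `k_i^gamma` (nonlinear preferential attachment).
#'
#' `theta < 0` (abundant functions *promote* innovation) and `gamma > 1`
#' (superlinear attachment) are permitted but unusual; `gamma > 1` leads to
#' gelation, where a single function absorbs nearly all growth, so both
#' emit a warning unless `quiet = TRUE`.
#'
#' @param p0 Non-negative innovation scale (default 1).  `p0 = 0` gives a
#'   degenerate process with no innovation.
#' @param theta Finite diversification exponent.
#' @param gamma Non-negative specialization exponent.
#' @param quiet Suppress the gelation / negative-theta warnings.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(p0 = 1, theta = 1, gamma = 0.8)
#' @export
model_params <- function(p0 = 1, theta = 0, gamma = 1, quiet = FALSE) {
  stopifnot(is.numeric(p0), length(p0) == 1, is.finite(p0), p0 >= 0,
            is.numeric(theta), length(theta) == 1, is.finite(theta),
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            gamma >= 0)
  if (!quiet) {
    if (theta < 0) {
      warning("theta < 0: abundant functions promote rather than suppress ",
              "new-function creation", call. = FALSE)
    }
    if (gamma > 1) {
      warning("gamma > 1: superlinear attachment leads to gelation ",
              "(one function absorbs nearly all growth)", call. = FALSE)
    }
  }
  structure(list(p0 = as.numeric(p0), theta = as.numeric(theta),
                 gamma = as.numeric(gamma)),
            class = "model_params")
}

#' @rdname model_params
#' @param x A `model_params`.
#' @param ... Ignored.
#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> p0 = %g, theta = %g, gamma = %g\n",
              x$p0, x$theta, x$gamma))
  invisible(x)
}

#' Innovation probability of the next arrival
#'
#' Probability that the next individual to join the system creates a new
#' function rather than entering an existing one:
#' `p = min(1, p0 / sum(k_i^theta))`.  The clamp at 1 only matters for the
#' earliest arrivals of small systems, where `p0 / sum(k_i^theta)` can
#' exceed one.
#'
#' @param state A [function_tally()].
#' @param params A [model_params()].
#' @return A probability in `[0, 1]`.
#' @examples
#' innovation_probability(function_tally(rep(1, 4)),
#'                        model_params(p0 = 1, theta = 0))  # p0 / D = 0.25
#' @export
innovation_probability <- function(state, params) {
  stopifnot(inherits(state, "function_tally"), inherits(params, "model_params"))
  w <- as.numeric(state$counts)^params$theta
  if (any(!is.finite(w))) {
    bad <- which(!is.finite(w))[1]
    stop(sprintf("non-finite weight k^theta for k = %d, theta = %g",
                 state$counts[bad], params$theta))
  }
  if (params$p0 <= 0) return(0)
  min(1, params$p0 / sum(w))
}

#' Attachment distribution over existing functions
#'
#' Probability that a non-innovating newcomer joins each existing function:
#' `q_i = k_i^gamma / sum_j k_j^gamma`.  `gamma = 0` is uniform over
#' functions, `gamma = 1` is classic linear preferential attachment
#' (equivalent to copying the function of a uniformly chosen individual),
#' and `gamma > 1` is superlinear.
#'
#' @param state A [function_tally()].
#' @param gamma Non-negative specialization exponent.
#' @return Numeric probability vector aligned with `state$counts`,
#'   summing to 1.
#' @examples
#' attachment_distribution(function_tally(c(3, 1)), gamma = 1)  # 0.75 0.25
#' @export
attachment_distribution <- function(state, gamma) {
  stopifnot(inherits(state, "function_tally"),
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            gamma >= 0)
  w <- as.numeric(state$counts)^gamma
  if (any(!is.finite(w))) {
    bad <- which(!is.finite(w))[1]
    stop(sprintf("non-finite weight k^gamma for k = %d, gamma = %g",
                 state$counts[bad], gamma))
  }
  w / sum(w)
}

#' Advance the system by a single arrival
#'
#' Draws one arrival event: with probability [innovation_probability()] a
#' new function of abundance 1 is appended; otherwise one existing function
#' is incremented, chosen from [attachment_distribution()].  Uses R's
#' global RNG stream (seed with `set.seed()`).
#'
#' @inheritParams innovation_probability
#' @return A list with `state` (the updated tally, N increased by exactly
#'   1) and `event`, itself a list with `type` (`"innovated"` or
#'   `"joined"`) and `index` (the joined function, or the new one).
#' @export
advance_one_arrival <- function(state, params) {
  p <- innovation_probability(state, params)
  if (runif(1) < p) {
    new_state <- function_tally(c(state$counts, 1L),
                                labels = c(state$labels,
                                           next_label(state$labels)))
    list(state = new_state,
         event = list(type = "innovated", index = diversity(new_state)))
  } else {
    q <- attachment_distribution(state, params$gamma)
    i <- sample.int(length(q), 1L, prob = q)
    counts <- state$counts
    counts[i] <- counts[i] + 1L
    list(state = function_tally(counts, labels = state$labels),
         event = list(type = "joined", index = i))
  }
}

next_label <- function(labels) {
  cand <- paste0("f", length(labels) + 1L)
  while (cand %in% labels) cand <- paste0(cand, "n")
  cand
}

#' Logarithmically spaced checkpoint sizes
#'
#' Default recording schedule for growth simulations: sizes spaced evenly
#' in log10, `per_decade` per decade, within `(n0, n_final]`, always
#' including `n_final`.
#'
#' @param n0 Initial system size (exclusive lower bound).
#' @param n_final Final system size (always included).
#' @param per_decade Checkpoints per decade of size (default 20).
#' @return Strictly increasing integer vector.
#' @export
default_checkpoints <- function(n0, n_final, per_decade = 20) {
  stopifnot(n_final > n0, n0 >= 1)
  lo <- log10(n0)
  hi <- log10(n_final)
  raw <- 10^seq(lo, hi, by = 1 / per_decade)
  sizes <- sort(unique(c(round(raw), n_final)))
  sizes[sizes > n0 & sizes <= n_final]
}

#' Deterministic child seed
#'
#' Derives a reproducible 31-bit child seed from a master seed and a
#' stream index, so that ensemble replicates and calibration repeats each
#' get an independent, reconstructible RNG stream.
#'
#' @param master Integer master seed.
#' @param stream Integer stream index (replicate number).
#' @return A single integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(master, stream) {
  m <- as.double(master) %% 2147483647
  s <- as.double(stream) %% 2147483647
  as.integer((m * 69069 + s * 104729 + 1) %% 2147483647)
}

#' Simulate system growth by sequential arrivals
#'
#' Runs the growth process from an initial abundance state up to
#' `n_final` individuals, recording `(N, D)` at each checkpoint and,
#' optionally, full abundance snapshots at given sizes.  The inner loop is
#' compiled: per-function attachment weights `k_i^gamma` live in a
#' cumulative-weight tree with `O(log D)` updates and inverse-CDF
#' sampling, and the running sums of `k_i^theta` and `k_i^gamma` are
#' refreshed by full recomputation every `rebuild_every` arrivals to bound
#' floating-point drift.
#'
#' @param initial Initial [function_tally()]; defaults to a single
#'   function with one individual.
#' @param params A [model_params()].
#' @param n_final Target system size; must exceed the initial size.
#' @param checkpoints Sizes at which `(N, D)` is recorded; defaults to
#'   [default_checkpoints()] at 20 per decade.
#' @param seed Integer RNG seed; identical seed and inputs give an
#'   identical trajectory.
#' @param snapshot_sizes Optional sizes at which the full abundance state
#'   is copied out (used by the fixture generator, where larger systems
#'   genuinely contain the smaller ones along the same trajectory).
#' @param rebuild_every Arrivals between full weight recomputations
#'   (default 10000; 0 disables).
#'
#' @return A `growth_trajectory`: list with `checkpoints` (data.frame of
#'   `N`, `D`), `final_state`, `params`, `seed`, `snapshots` (named list
#'   of [function_tally()] by size), and `running_sums` (the incrementally
#'   maintained sums of `k_i^theta`, `k_i^gamma` at the end of the run).
#'
#' @examples
#' tr <- simulate_growth(params = model_params(p0 = 1, theta = 0, gamma = 0.8),
#'                       n_final = 1000, seed = 1)
#' tail(tr$checkpoints, 3)
#' @export
simulate_growth <- function(initial = function_tally(1L), params, n_final,
                            checkpoints = NULL, seed = 1L,
                            snapshot_sizes = integer(0),
                            rebuild_every = 10000L) {
  stopifnot(inherits(initial, "function_tally"),
            inherits(params, "model_params"))
  n0 <- system_size(initial)
  if (n_final <= n0) {
    stop(sprintf("n_final (%d) must exceed the initial size (%d)",
                 as.integer(n_final), n0))
  }
  if (is.null(checkpoints)) {
    checkpoints <- default_checkpoints(n0, n_final)
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints <= n0) || any(checkpoints > n_final)) {
    stop("checkpoints must lie within (initial size, n_final]")
  }
  snapshot_sizes <- sort(unique(as.integer(snapshot_sizes)))

  set.seed(as.integer(seed))
  res <- rcpp_simulate_growth(initial$counts, params$p0, params$theta,
                              params$gamma, as.integer(n_final),
                              checkpoints, snapshot_sizes,
                              as.integer(rebuild_every))

  snaps <- list()
  if (length(snapshot_sizes)) {
    snaps <- lapply(res$snapshots, function(k) {
      if (is.null(k)) NULL else function_tally(k)
    })
    names(snaps) <- as.character(snapshot_sizes)
  }
  structure(list(
    checkpoints = data.frame(N = res$checkpoint_N, D = res$checkpoint_D),
    final_state = function_tally(res$final_counts),
    params = params,
    seed = as.integer(seed),
    snapshots = snaps,
    running_sums = c(sum_theta = res$sum_theta_running,
                     sum_gamma = res$sum_gamma_running)
  ), class = "growth_trajectory")
}

#' @rdname simulate_growth
#' @param x A `growth_trajectory`.
#' @param ... Ignored.
#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("<growth_trajectory> p0 = %g, theta = %g, gamma = %g, seed = %d\n",
              x$params$p0, x$params$theta, x$params$gamma, x$seed))
  cat(sprintf("  final N = %d, final D = %d, %d checkpoints\n",
              system_size(x$final_state), diversity(x$final_state),
              nrow(x$checkpoints)))
  invisible(x)
}

#' Simulate an ensemble of growth trajectories
#'
#' Runs `replicates` independent trajectories with the same parameters.
#' Replicate `r` uses the deterministic child seed
#' `child_seed(master_seed, r)`, so the whole ensemble is reproducible
#' from the master seed alone.
#'
#' @inheritParams simulate_growth
#' @param replicates Number of replicate trajectories (>= 1).
#' @param master_seed Integer master seed.
#' @return A `growth_ensemble`: list with `trajectories` (list of
#'   `growth_trajectory`), `summary` (data.frame of `N`, `mean_D`, `se_D`
#'   per checkpoint; `se_D` is `NA` for a single replicate), `params`,
#'   and `master_seed`.
#' @export
simulate_ensemble <- function(initial = function_tally(1L), params, n_final,
                              replicates, master_seed = 1L,
                              checkpoints = NULL, snapshot_sizes = integer(0)) {
  stopifnot(replicates >= 1)
  n0 <- system_size(initial)
  if (is.null(checkpoints)) checkpoints <- default_checkpoints(n0, n_final)
  trajectories <- lapply(seq_len(replicates), function(r) {
    simulate_growth(initial, params, n_final, checkpoints = checkpoints,
                    seed = child_seed(master_seed, r),
                    snapshot_sizes = snapshot_sizes)
  })
  d_mat <- vapply(trajectories, function(tr) tr$checkpoints$D,
                  numeric(nrow(trajectories[[1]]$checkpoints)))
  d_mat <- matrix(d_mat, ncol = replicates)
  summary_df <- data.frame(
    N = trajectories[[1]]$checkpoints$N,
    mean_D = rowMeans(d_mat),
    se_D = if (replicates > 1) {
      apply(d_mat, 1, sd) / sqrt(replicates)
    } else {
      NA_real_
    }
  )
  structure(list(trajectories = trajectories, summary = summary_df,
                 params = params, master_seed = as.integer(master_seed)),
            class = "growth_ensemble")
}

#' Mean-field diversity prediction in the analytic limits
#'
#' The mean-field equation for the growth of diversity is `dD/dN = p`.
#' Two limits of the diversification exponent solve in closed form:
#' `theta = 0` gives `dD/dN = p0/D`, hence
#' `D(n) = sqrt(d0^2 + 2 p0 (n - n0))` — sublinear power-law growth
#' approaching `D ~ N^(1/2)`; `theta = 1` gives `dD/dN = p0/N`, hence
#' `D(n) = d0 + p0 log(n/n0)` — logarithmic growth.  General `theta` has
#' no closed form and is handled by simulation only.
#'
#' @param theta_limit Either 0 or 1.
#' @param p0 Positive innovation scale.
#' @param n0 Initial size (>= 1).
#' @param d0 Initial diversity (>= 1).
#' @param n Size(s) at which to predict, each >= `n0`.
#' @return Predicted mean diversity, same length as `n`.
#' @examples
#' mean_field_diversity(0, p0 = 1, n0 = 1, d0 = 1, n = 1e4)  # ~ 141.4
#' mean_field_diversity(1, p0 = 1, n0 = 1, d0 = 1, n = 1e4)  # ~ 10.2
#' @export
mean_field_diversity <- function(theta_limit, p0, n0, d0, n) {
  stopifnot(is.numeric(p0), p0 > 0, n0 >= 1, d0 >= 1, all(n >= n0))
  if (identical(as.numeric(theta_limit), 0)) {
    sqrt(d0^2 + 2 * p0 * (n - n0))
  } else if (identical(as.numeric(theta_limit), 1)) {
    d0 + p0 * log(n / n0)
  } else {
    stop("no closed-form mean-field solution outside theta in {0, 1}; ",
         "use simulate_growth() for general theta")
  }
}
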