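#' Normalized rank-frequency distribution of function abundance
#'
#' Sorts function abundances in decreasing order (ties broken by input
#' order, i.e. a stable sort) and normalizes by the system size, giving
#' the relative abundance `f_r = k_(r) / N` at each rank `r` (rank 1 =
#' most abundant).  This is the distribution plotted on a log-frequency
#' axis when reading specialization off a system's abundance structure.
#'
#' @param state A [function_tally()].
#' @return A `rank_frequency`: list with `frequencies` (non-increasing,
#'   strictly positive, summing to 1), `n_total`, `d_total`, and `labels`
#'   in rank order.
#' @examples
#' rf <- compute_rank_frequency(function_tally(c(5, 3, 2), c("A", "B", "C")))
#' rf$frequencies  # 0.5 0.3 0.2
#' @export
compute_rank_frequency <- function(state) {
  stopifnot(inherits(state, "function_tally"))
  ord <- order(-state$counts)  # radix sort: stable, preserves input order on ties
  k <- state$counts[ord]
  n <- sum(k)
  structure(list(frequencies = as.numeric(k) / n,
                 n_total = n,
                 d_total = length(k),
                 labels = state$labels[ord]),
            class = "rank_frequency")
}

#' @rdname compute_rank_frequency
#' @param x A `rank_frequency`.
#' @param ... Ignored.
#' @export
print.rank_frequency <- function(x, ...) {
  cat(sprintf("<rank_frequency> N = %d, D = %d; top frequencies: %s\n",
              x$n_total, x$d_total,
              paste(signif(utils::head(x$frequencies, 5), 3), collapse = " ")))
  invisible(x)
}

# Common internal view of rank_frequency / rank_profile objects:
# log10 frequencies at integer ranks plus log10 diversity.
log10_profile <- function(x) {
  if (inherits(x, "rank_frequency")) {
    list(logf = log10(x$frequencies), log10_d = log10(x$d_total))
  } else if (inherits(x, "rank_profile")) {
    list(logf = x$log10_mean, log10_d = x$log10_d)
  } else {
    stop("expected a rank_frequency or rank_profile object")
  }
}

#' Log-space distance between rank-frequency distributions
#'
#' The calibration objective: the root-mean-square difference of
#' `log10` frequencies at matched integer ranks, over the `R = min(D_a,
#' D_b)` common ranks, plus an additive diversity penalty
#' `penalty_weight * (log10 D_a - log10 D_b)^2`.  The penalty prevents a
#' low-diversity simulation from matching a high-diversity target
#' spuriously on the few ranks they share; with `penalty_weight = 0` the
#' distance is a metric on the common-rank truncation.
#'
#' @param a,b [compute_rank_frequency()] results (or
#'   [ensemble_mean_rank_frequency()] profiles).
#' @param penalty_weight Non-negative weight of the diversity penalty
#'   (default 1).
#' @return Non-negative scalar; zero iff the common-rank frequencies are
#'   identical and (when `penalty_weight > 0`) the diversities agree.
#' @examples
#' a <- compute_rank_frequency(function_tally(c(1, 1)))
#' b <- compute_rank_frequency(function_tally(c(9, 1)))
#' log_space_distance(a, b, penalty_weight = 0)
#' @export
log_space_distance <- function(a, b, penalty_weight = 1) {
  pa <- log10_profile(a)
  pb <- log10_profile(b)
  stopifnot(is.numeric(penalty_weight), penalty_weight >= 0)
  if (length(pa$logf) == 0 || length(pb$logf) == 0) {
    stop("rank-frequency distributions must be non-empty")
  }
  r <- min(length(pa$logf), length(pb$logf))
  idx <- seq_len(r)
  rms <- sqrt(mean((pa$logf[idx] - pb$logf[idx])^2))
  rms + penalty_weight * (pa$log10_d - pb$log10_d)^2
}

#' Ensemble-mean rank-frequency profile
#'
#' Averages replicate rank-frequency distributions in `log10`-frequency
#' space at fixed rank (consistent with the log-space calibration
#' objective), truncated to the minimum diversity across replicates.
#' The profile's effective diversity is the geometric mean of the
#' replicate diversities, again matching the log-space diversity penalty.
#'
#' @param states A list of [function_tally()] objects, a
#'   `growth_ensemble`, or a list of `growth_trajectory` objects (their
#'   terminal states are used).
#' @return A `rank_profile`: list with `log10_mean` (per-rank mean of
#'   `log10 f_r`), `log10_spread` (per-rank sd of `log10 f_r`, 0 for a
#'   single replicate), `d_total` (geometric-mean diversity),
#'   `n_replicates`.
#' @export
ensemble_mean_rank_frequency <- function(states) {
  if (inherits(states, "growth_ensemble")) states <- states$trajectories
  if (inherits(states, "function_tally")) states <- list(states)
  states <- lapply(states, function(s) {
    if (inherits(s, "growth_trajectory")) s$final_state else s
  })
  stopifnot(length(states) >= 1,
            all(vapply(states, inherits, logical(1), "function_tally")))
  logf_list <- lapply(states, function(s) {
    log10(compute_rank_frequency(s)$frequencies)
  })
  d_each <- lengths(logf_list)
  r <- min(d_each)
  mat <- vapply(logf_list, function(v) v[seq_len(r)], numeric(r))
  mat <- matrix(mat, nrow = r)
  log10_d <- mean(log10(d_each))
  structure(list(
    log10_mean = rowMeans(mat),
    log10_spread = if (length(states) > 1) apply(mat, 1, sd) else rep(0, r),
    log10_d = log10_d,
    d_total = 10^log10_d,
    n_replicates = length(states)
  ), class = "rank_profile")
}
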