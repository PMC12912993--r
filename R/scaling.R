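#' Validate a diversity-size table
#'
#' A diversity-size table records, for a family of systems, the system
#' size `N` and function diversity `D` of each, with an identifying
#' `system` column.  Used by the scaling fits.
#'
#' @param table A data.frame with columns `system`, `N`, `D`.
#' @param min_records Minimum number of records required (default 3).
#' @return The validated data.frame (invisibly unchanged).
#' @export
as_diversity_size_table <- function(table, min_records = 3) {
  if (!is.data.frame(table) || !all(c("N", "D") %in% names(table))) {
    stop("expected a data.frame with columns N and D (and optionally system)")
  }
  if (!"system" %in% names(table)) {
    table$system <- paste0("sys", seq_len(nrow(table)))
  }
  if (nrow(table) < min_records) {
    stop(sprintf("need at least %d records for a scaling fit, got %d",
                 min_records, nrow(table)))
  }
  with(table, {
    if (any(N < 1) || any(D < 1)) stop("N and D must be >= 1")
    if (any(D > N)) stop("D cannot exceed N (each function needs an individual)")
  })
  table
}

# coefficient of determination without summary.lm's perfect-fit warning
r_squared_lm <- function(fit) {
  y <- fit$model[[1]]
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

new_scaling_fit <- function(model, coef, ci, r_squared, n_obs, fit_object) {
  structure(list(model = model, coef = coef, ci = ci,
                 r_squared = r_squared, n_obs = n_obs, fit = fit_object),
            class = "scaling_fit")
}

#' Fit the power-law (Heaps' law) diversity-size relation
#'
#' Fits `D = D0 * N^beta` by ordinary least squares of `log10 D` on
#' `log10 N`, the standard estimator for Heaps'-law exponents.  `beta` is
#' the slope, `D0 = 10^intercept`; the 95% CI on `beta` comes from the
#' slope's OLS standard error (t distribution), and `R^2` is reported in
#' log-log space.
#'
#' @param table A diversity-size table (see [as_diversity_size_table()]).
#' @return A `scaling_fit` with `coef["beta"]`, `coef["d0"]`, `ci` (95%
#'   CI on beta), `r_squared`, `n_obs`.
#' @examples
#' tab <- data.frame(N = 10^(1:6), D = 2 * (10^(1:6))^0.5)
#' fit_power_law(tab)$coef
#' @export
fit_power_law <- function(table) {
  table <- as_diversity_size_table(table)
  if (length(unique(table$N)) < 2) stop("zero variance in N; cannot fit")
  fit <- lm(log10(D) ~ log10(N), data = table)
  beta <- unname(coef(fit)[2])
  d0 <- unname(10^coef(fit)[1])
  ci <- unname(suppressWarnings(confint(fit, level = 0.95))[2, ])
  new_scaling_fit("power",
                  coef = c(beta = beta, d0 = d0),
                  ci = c(lower = ci[1], upper = ci[2]),
                  r_squared = r_squared_lm(fit),
                  n_obs = nrow(table), fit_object = fit)
}

#' Fit the logarithmic diversity-size relation
#'
#' Fits `D = b * log(N) + c` (natural logarithm) by ordinary least
#' squares of `D` on `log N`.  The natural log is the base under which
#' exponential population growth `N(t) = N0 exp(alpha t)` turns the fit
#' into linear-in-time diversity growth `D(t) = alpha b t + D0` (see
#' [urban_diversity_growth_rate()]).
#'
#' @inheritParams fit_power_law
#' @return A `scaling_fit` with `coef["b"]`, `coef["c"]`, `ci` (95% CI on
#'   b), `r_squared` (semi-log space), `n_obs`.
#' @examples
#' tab <- data.frame(N = 10^(1:6), D = 128 * log(10^(1:6)) + 5)
#' fit_logarithmic(tab)$coef
#' @export
fit_logarithmic <- function(table) {
  table <- as_diversity_size_table(table)
  if (length(unique(table$N)) < 2) stop("zero variance in N; cannot fit")
  fit <- lm(D ~ log(N), data = table)
  b <- unname(coef(fit)[2])
  cc <- unname(coef(fit)[1])
  ci <- unname(suppressWarnings(confint(fit, level = 0.95))[2, ])
  new_scaling_fit("logarithmic",
                  coef = c(b = b, c = cc),
                  ci = c(lower = ci[1], upper = ci[2]),
                  r_squared = r_squared_lm(fit),
                  n_obs = nrow(table), fit_object = fit)
}

#' @rdname fit_power_law
#' @param x A `scaling_fit`.
#' @param ... Ignored.
#' @export
print.scaling_fit <- function(x, ...) {
  if (x$model == "power") {
    cat(sprintf("<scaling_fit> D = %.4g * N^%.4g  (power law)\n",
                x$coef["d0"], x$coef["beta"]))
    cat(sprintf("  beta 95%% CI [%.4g, %.4g], R^2 = %.4f (log-log), n = %d\n",
                x$ci["lower"], x$ci["upper"], x$r_squared, x$n_obs))
  } else {
    cat(sprintf("<scaling_fit> D = %.4g * ln(N) + %.4g  (logarithmic)\n",
                x$coef["b"], x$coef["c"]))
    cat(sprintf("  b 95%% CI [%.4g, %.4g], R^2 = %.4f (semi-log), n = %d\n",
                x$ci["lower"], x$ci["upper"], x$r_squared, x$n_obs))
  }
  invisible(x)
}

#' Compare power-law and logarithmic scaling by AIC
#'
#' `R^2` values from different response transforms (log-log vs semi-log
#' OLS) are incommensurable, so both laws are refit as least squares on
#' the natural `D` scale with Gaussian error — the power law
#' `D = D0 * N^beta` by Levenberg-Marquardt nonlinear least squares
#' (started from the log-log fit), the logarithmic law `D = b log N + c`
#' as a linear model — and compared by AIC.  The lower-AIC model is
#' selected; if either fit fails to converge, selection abstains.
#'
#' @param table A diversity-size table with at least 4 records.
#' @return A `scaling_comparison`: list with `power` and `logarithmic`
#'   (coefficients or `NULL` on non-convergence), `aic` (named vector),
#'   `delta_aic` (`AIC_power - AIC_logarithmic`), and `selected`
#'   (`"power"`, `"logarithmic"`, or `"none"`).
#' @examples
#' tab <- data.frame(N = round(10^seq(1, 5, 0.25)))
#' tab$D <- round(sqrt(2 * tab$N))
#' compare_scaling_models(tab)$selected  # "power"
#' @export
compare_scaling_models <- function(table) {
  table <- as_diversity_size_table(table, min_records = 4)

  log_fit <- tryCatch(lm(D ~ log(N), data = table), error = function(e) NULL)

  pow_fit <- tryCatch({
    start <- fit_power_law(table)$coef
    minpack.lm::nlsLM(D ~ d0 * N^beta, data = table,
                      start = list(d0 = unname(start["d0"]),
                                   beta = unname(start["beta"])),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)

  aic <- c(power = if (!is.null(pow_fit)) AIC(pow_fit) else NA_real_,
           logarithmic = if (!is.null(log_fit)) AIC(log_fit) else NA_real_)
  selected <- if (any(is.na(aic))) {
    "none"
  } else if (aic["power"] < aic["logarithmic"]) {
    "power"
  } else {
    "logarithmic"
  }
  structure(list(
    power = if (!is.null(pow_fit)) coef(pow_fit) else NULL,
    logarithmic = if (!is.null(log_fit)) {
      c(b = unname(coef(log_fit)[2]), c = unname(coef(log_fit)[1]))
    } else {
      NULL
    },
    aic = aic,
    delta_aic = unname(aic["power"] - aic["logarithmic"]),
    selected = selected
  ), class = "scaling_comparison")
}

#' @rdname compare_scaling_models
#' @param x A `scaling_comparison`.
#' @param ... Ignored.
#' @export
print.scaling_comparison <- function(x, ...) {
  cat(sprintf("<scaling_comparison> selected: %s (delta AIC = %.2f)\n",
              x$selected, x$delta_aic))
  invisible(x)
}

#' Predicted growth rate of urban function diversity
#'
#' Under logarithmic diversity-size scaling `D = b log N + c` and
#' exponential population growth `N(t) = N0 exp(alpha t)`, diversity
#' grows linearly in time, `D(t) = alpha b t + D0`, so the diversity
#' growth rate `dD/dt` is simply the product `alpha * b` (e.g. new
#' occupation categories per year for a city).
#'
#' @param alpha Per-year relative population growth rate.
#' @param b Slope of the logarithmic diversity-size fit (natural log).
#' @return The diversity growth rate `alpha * b`, in functions per year.
#' @examples
#' urban_diversity_growth_rate(alpha = 0.0071, b = 128)  # ~ 0.9/year
#' @export
urban_diversity_growth_rate <- function(alpha, b) {
  stopifnot(is.numeric(alpha), is.numeric(b), all(is.finite(b)))
  alpha * b
}

#' @rdname urban_diversity_growth_rate
#' @param c Intercept of the logarithmic fit.
#' @param n0 Population at time 0.
#' @return For `urban_diversity_projection()`: a list with `rate`
#'   (`alpha * b`), `d0` (`b * log(n0) + c`, the diversity at time 0) and
#'   `predict(t)`, the linear-in-time diversity projection.
#' @export
urban_diversity_projection <- function(alpha, b, c, n0) {
  rate <- urban_diversity_growth_rate(alpha, b)
  d0 <- b * log(n0) + c
  list(rate = rate, d0 = d0,
       predict = function(t) rate * t + d0)
}
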