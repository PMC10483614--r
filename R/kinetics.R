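#' Fit a sigmoid to an object-count series
#'
#' Least-squares fit of the four-parameter decreasing logistic
#' `n(t) = b + (n0 - b) / (1 + exp((t - t_m) / s))` to an object-count
#' time series: `n0` is the fitted initial count, `b` the plateau count at
#' assay end, `t_m` the inflection time and `s` the slope scale. The fit is
#' bounded (`b >= 0`, `n0 >= b`, `s > 0`, via the reparameterisation
#' `n0 = b + delta`, `delta >= 0`) and run with a Levenberg-Marquardt
#' optimiser. Derived quantities — halving time, lag time and density
#' fraction — are attached to the result.
#'
#' Initialisation: `n0` from the first count, `b` from the last, `t_m` from
#' the first crossing of the half-range, `s` as a tenth of the assay span.
#' Non-convergence is reported in the `status` field (`"converged"`,
#' `"degenerate"` for flat series, or `"failed"`), never silently.
#'
#' @param series A data frame with columns `time_days` and `count`
#'   (and optionally `density`, carried through as metadata).
#' @return An object of class `sigmoid_fit`.
#' @examples
#' t <- 0:21
#' n <- 10 + 30 / (1 + exp((t - 8) / 2))
#' fit <- fit_count_sigmoid(data.frame(time_days = t, count = n))
#' glance(fit)
#' @export
fit_count_sigmoid <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("time_days", "count") %in% names(series)))
  tt <- series$time_days
  yy <- series$count
  if (length(tt) < 5) abort("need at least 5 time points to fit a sigmoid")
  if (is.unsorted(tt, strictly = TRUE)) abort("times must be strictly increasing")
  if (any(yy < 0)) abort("counts must be non-negative")
  density <- if ("density" %in% names(series)) series$density[1] else NA_real_
  span <- diff(range(tt))

  if (diff(range(yy)) == 0) {
    return(new_sigmoid_fit(n0 = yy[1], b = yy[1], t_m = mean(tt),
                           s = span / 10, series = series, density = density,
                           status = "degenerate"))
  }

  half_level <- (max(yy) + min(yy)) / 2
  k <- which(yy <= half_level)[1]
  tm0 <- if (is.na(k)) mean(tt) else tt[k]
  # multi-start over the slope scale: steep transitions sampled coarsely can
  # make the Jacobian singular at a single default start
  fit <- NULL
  last_error <- NULL
  for (s0 in span / c(10, 20, 40, 5)) {
    start <- list(b = max(tail(yy, 1), 1e-8),
                  delta = max(yy[1] - tail(yy, 1), diff(range(yy)) / 10, 1e-6),
                  tm = tm0, s = s0)
    cand <- tryCatch(
      minpack.lm::nlsLM(
        count ~ b + delta / (1 + exp((time_days - tm) / s)),
        data = series, start = start,
        lower = c(b = 0, delta = 0, tm = min(tt) - 2 * span, s = span * 1e-4),
        upper = c(b = Inf, delta = Inf, tm = max(tt) + 2 * span, s = span * 10),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) e
    )
    if (inherits(cand, "error")) {
      last_error <- cand
    } else if (is.null(fit) ||
               sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    return(new_sigmoid_fit(n0 = NA_real_, b = NA_real_, t_m = NA_real_,
                           s = NA_real_, series = series, density = density,
                           status = "failed",
                           message = conditionMessage(last_error)))
  }
  cf <- coef(fit)
  new_sigmoid_fit(n0 = unname(cf["b"] + cf["delta"]), b = unname(cf["b"]),
                  t_m = unname(cf["tm"]), s = unname(cf["s"]),
                  series = series, density = density, status = "converged")
}

new_sigmoid_fit <- function(n0, b, t_m, s, series, density, status,
                            message = NULL) {
  fit <- structure(
    list(n0 = n0, b = b, t_m = t_m, s = s, series = series,
         density = density, status = status, message = message),
    class = "sigmoid_fit"
  )
  if (status %in% c("converged", "degenerate")) {
    pred <- predict_sigmoid(fit, series$time_days)
    fit$resid_rms <- sqrt(mean((series$count - pred)^2))
    fit$t_half <- halving_time(fit)
    fit$t_lag <- lag_time(fit)
    fit$density_fraction <- density_fraction(fit)
  } else {
    fit$resid_rms <- NA_real_
    fit$t_half <- NA_real_
    fit$t_lag <- NA_real_
    fit$density_fraction <- NA_real_
  }
  fit
}

predict_sigmoid <- function(fit, t) {
  fit$b + (fit$n0 - fit$b) / (1 + exp((t - fit$t_m) / fit$s))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>", x$status, "| n0 =", format(x$n0, digits = 4),
      "b =", format(x$b, digits = 4), "t_m =", format(x$t_m, digits = 4),
      "d s =", format(x$s, digits = 4), "d\n")
  cat("  t_half =", format(x$t_half, digits = 4),
      "d | t_lag =", format(x$t_lag, digits = 4),
      "d | density fraction =", format(x$density_fraction, digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_count_sigmoid
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("n0", "b", "t_m", "s"),
         estimate = c(x$n0, x$b, x$t_m, x$s))
}

#' @rdname fit_count_sigmoid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(n0 = x$n0, b = x$b, t_m = x$t_m, s = x$s, t_half = x$t_half,
         t_lag = x$t_lag, density_fraction = x$density_fraction,
         resid_rms = x$resid_rms, status = x$status,
         nobs = nrow(x$series))
}

#' Halving time of a fitted count sigmoid
#'
#' Time at which the fitted curve reaches half of the initial fitted object
#' count, from the closed form
#' `t_half = t_m + s * log((n0 / 2) / (n0 / 2 - b))`. When the plateau `b`
#' is at or above `n0 / 2` the curve never halves and the halving time is
#' undefined (`NA`), the signature of a non-aggregating assay; this is a
#' first-class value, not an error.
#'
#' @param fit A `sigmoid_fit`.
#' @return Halving time (days) or `NA`.
#' @export
halving_time <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (is.na(fit$n0) || fit$n0 <= 0) return(NA_real_)
  if (fit$b >= fit$n0 / 2) return(NA_real_)
  fit$t_m + fit$s * log((fit$n0 / 2) / (fit$n0 / 2 - fit$b))
}

#' Lag time of a fitted count sigmoid
#'
#' The `"inflection"` convention (default) returns the time of the first
#' convexity change of the fitted curve; for the symmetric logistic this is
#' exactly the inflection time `t_m`. The `"plateau_departure"` convention
#' returns `t_m - 2 s`, the tangent construction for where the curve leaves
#' its initial plateau.
#'
#' @param fit A `sigmoid_fit`.
#' @param convention `"inflection"` or `"plateau_departure"`.
#' @return Lag time (days).
#' @export
lag_time <- function(fit, convention = c("inflection", "plateau_departure")) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  convention <- match.arg(convention)
  switch(convention,
         inflection = fit$t_m,
         plateau_departure = fit$t_m - 2 * fit$s)
}

#' Density fraction of a fitted count sigmoid
#'
#' Fractional reduction in the number of distinct objects over the assay,
#' `(n0 - b) / n0`, from the fitted parameters. 0 means no aggregation,
#' 1 means complete coalescence into a single connected mass per object.
#'
#' @param fit A `sigmoid_fit`.
#' @return A fraction in \[0, 1\].
#' @export
density_fraction <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (is.na(fit$n0)) return(NA_real_)
  if (fit$n0 == 0) abort("density fraction undefined for n0 = 0")
  (fit$n0 - fit$b) / fit$n0
}

#' Classify aggregation as directed or random from density scaling
#'
#' Random (Brownian) cluster motion makes coalescence a density-driven
#' collision process: halving times scale inversely with seeding density
#' (log-log slope near -1). Directed migration up attractant gradients
#' decouples halving times from density (slope near 0). This fits an
#' ordinary least-squares line to `log(t_half)` versus `log(density)` and
#' classifies the slope `beta`: `directed` if `beta` is above the upper
#' threshold, `random` if below the lower, otherwise `indeterminate`.
#'
#' @param assays A data frame with columns `density` (cells/mm^3) and
#'   `t_half` (days); rows with undefined halving times are dropped.
#' @param thresholds Length-2 numeric `c(directed, random)`: slope above the
#'   first is labelled directed, below the second random. Default
#'   `c(-0.3, -0.7)`, splitting the interval between the theoretical
#'   exponents 0 and -1 with a cautious indeterminate band.
#' @return An object of class `directionality_fit` with elements `beta`,
#'   `beta_se`, `label`, `n`, `thresholds` and the underlying `lm` fit.
#' @examples
#' d <- data.frame(density = c(15, 30, 60, 120), t_half = 120 / c(15, 30, 60, 120))
#' fit_directionality(d)$label
#' @export
fit_directionality <- function(assays, thresholds = c(-0.3, -0.7)) {
  assays <- as_tibble(assays)
  stopifnot(all(c("density", "t_half") %in% names(assays)),
            length(thresholds) == 2, thresholds[1] > thresholds[2])
  ok <- is.finite(assays$density) & is.finite(assays$t_half) &
    assays$density > 0 & assays$t_half > 0
  assays <- assays[ok, , drop = FALSE]
  if (nrow(assays) < 3) {
    abort("need at least 3 assays with defined halving times")
  }
  if (max(assays$density) / min(assays$density) < 2) {
    abort("densities must span at least a 2-fold range")
  }
  fit <- lm(log(t_half) ~ log(density), data = assays)
  beta <- unname(coef(fit)[2])
  beta_se <- summary(fit)$coefficients[2, 2]
  label <- if (beta > thresholds[1]) {
    "directed"
  } else if (beta < thresholds[2]) {
    "random"
  } else {
    "indeterminate"
  }
  structure(
    list(beta = beta, beta_se = beta_se, label = label, n = nrow(assays),
         thresholds = thresholds, fit = fit, assays = assays),
    class = "directionality_fit"
  )
}

#' @export
print.directionality_fit <- function(x, ...) {
  cat("<directionality_fit> beta =", format(x$beta, digits = 3),
      "+/-", format(x$beta_se, digits = 3), "->", x$label,
      "(", x$n, "assays )\n")
  invisible(x)
}

#' @rdname fit_directionality
#' @param x A `directionality_fit`.
#' @param ... Unused.
#' @export
tidy.directionality_fit <- function(x, ...) {
  tibble(term = "beta", estimate = x$beta, std.error = x$beta_se,
         label = x$label)
}

#' @rdname fit_directionality
#' @export
glance.directionality_fit <- function(x, ...) {
  tibble(beta = x$beta, beta_se = x$beta_se, label = x$label, n = x$n,
         r.squared = summary(x$fit)$r.squared)
}
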