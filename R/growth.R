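#' Pseudo-volume of a projected area
#'
#' For an initially monodisperse population the total projected area raised
#' to the power 3/2 scales like a volume and serves as a proxy for the total
#' cell number in a field of view.
#'
#' @param area Projected area (um^2); vectorised, must be non-negative.
#' @return `area^(3/2)`.
#' @export
pseudo_volume <- function(area) {
  if (any(area < 0)) abort("area must be non-negative")
  area^(3 / 2)
}

#' Fit exponential growth to a projected-area series
#'
#' Fits `A(t) = A0 * 2^(t / tau)` by linear least squares in log2 space
#' (`log2 A` versus `t`), which is exact for the stated model and
#' numerically stable. Because pseudo-volume `A^(3/2)` tracks cell number,
#' an area-doubling timescale `tau` corresponds to a cell doubling time
#' `T_d = (2/3) tau`. A flat series gives infinite `tau` and undefined
#' `T_d`; a shrinking series (negative slope) also reports `T_d` as
#' undefined.
#'
#' @param series A data frame with columns `time_days` and `area_um2`
#'   (all areas strictly positive).
#' @return An object of class `growth_fit` with `A0`, `tau` (days), `T_d`
#'   (days or `NA`) and `resid_rms` (log2 residual RMS).
#' @examples
#' s <- data.frame(time_days = 0:15, area_um2 = 100 * 2^(0:15 / 3))
#' fit_growth(s)$T_d  # 2 days
#' @export
fit_growth <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("time_days", "area_um2") %in% names(series)))
  if (nrow(series) < 3) abort("need at least 3 points to fit growth")
  if (any(series$area_um2 <= 0)) {
    abort("all areas must be positive for the log-space growth fit")
  }
  fit <- lm(log2(area_um2) ~ time_days, data = series)
  slope <- unname(coef(fit)[2])
  if (abs(slope) < 1e-12) slope <- 0  # numerically flat series
  tau <- if (slope == 0) Inf else 1 / slope
  T_d <- if (slope > 0) 2 * tau / 3 else NA_real_
  structure(
    list(A0 = 2^unname(coef(fit)[1]), tau = tau, T_d = T_d,
         resid_rms = sqrt(mean(stats::residuals(fit)^2)), fit = fit,
         series = series),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> A0 =", format(x$A0, digits = 4), "um^2 | tau =",
      format(x$tau, digits = 4), "d | T_d =", format(x$T_d, digits = 4),
      "d\n")
  invisible(x)
}

#' @rdname fit_growth
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("A0", "tau", "T_d"), estimate = c(x$A0, x$tau, x$T_d))
}

#' @rdname fit_growth
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(A0 = x$A0, tau = x$tau, T_d = x$T_d, resid_rms = x$resid_rms,
         nobs = nrow(x$series))
}

#' Net growth rate from adhering-cell counts
#'
#' Fits an exponential to cell counts over time (least squares on
#' `log(count)` versus time in hours) and returns the rate constant
#' (1/h). Positive rates indicate net growth, negative rates net loss
#' (toxicity).
#'
#' @param data A data frame with columns `time_h` and `count`
#'   (counts strictly positive).
#' @return Rate (1/h).
#' @examples
#' d <- data.frame(time_h = seq(0, 96, 24), count = 100 * 2^(seq(0, 96, 24) / 24))
#' net_growth_rate(d)  # log(2)/24
#' @export
net_growth_rate <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("time_h", "count") %in% names(data)))
  if (nrow(data) < 3) abort("need at least 3 points")
  if (any(data$count <= 0)) abort("counts must be positive")
  unname(coef(lm(log(count) ~ time_h, data = data))[2])
}

#' Pearson correlation between two kinetic quantities
#'
#' Standard Pearson correlation with a two-sided t-distribution p-value,
#' e.g. between per-line halving times and doubling times.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the two quantities.
#' @return A one-row tibble with `r`, `p_value` and `n`.
#' @export
correlate_times <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  stopifnot(length(xv) == length(yv))
  keep <- complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in one of the inputs")
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}
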