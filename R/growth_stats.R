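# Growth descriptors from green-area time series: RGR, exponential fits,
# group curves, interval increases, survival, and quartile summaries.

#' Relative growth rate of one area series
#'
#' Classical interval RGR: `(ln A2 - ln A1) / (t2 - t1)` per consecutive
#' interval, in pixel pixel^-1 day^-1. Intervals touching a zero (dead or
#' empty) area yield `NA` rather than an error.
#'
#' @param times Strictly increasing observation times, days.
#' @param areas Green areas, pixels (>= 0).
#' @return Data frame with `t1`, `t2`, `t_mid` and `rgr` (length
#'   `length(times) - 1`).
#' @examples
#' rgr(0:3, 100 * exp(0.5 * (0:3)))  # all intervals 0.5
#' @export
rgr <- function(times, areas) {
  stopifnot(length(times) == length(areas), length(times) >= 2,
            !is.unsorted(times, strictly = TRUE), all(areas >= 0))
  i <- seq_len(length(times) - 1)
  ok <- areas[i] > 0 & areas[i + 1] > 0
  data.frame(t1 = times[i], t2 = times[i + 1],
    t_mid = (times[i] + times[i + 1]) / 2,
    rgr = ifelse(ok, (log(areas[i + 1]) - log(areas[i])) /
                     (times[i + 1] - times[i]), NA_real_))
}

#' Per-interval RGR averaged over a group of plants
#'
#' The default averages each plant's interval RGR across plants
#' (plants that are dead in an interval drop out); `method = "group_mean"`
#' instead takes the RGR of the group mean curve.
#'
#' @param long Long data frame with columns `plant`, `time`, `area` and
#'   optionally `treatment`.
#' @param method `"per_plant"` (default) or `"group_mean"`.
#' @return Data frame with `treatment` (if present), `t_mid`, `rgr`
#'   (mean across plants), `se` and `n`.
#' @export
rgr_curve <- function(long, method = c("per_plant", "group_mean")) {
  method <- match.arg(method)
  if (!"treatment" %in% names(long)) long$treatment <- "all"
  out <- lapply(split(long, long$treatment), function(d) {
    if (method == "per_plant") {
      per <- lapply(split(d, d$plant), function(p) {
        p <- p[order(p$time), ]
        rgr(p$time, p$area)
      })
      all <- do.call(rbind, per)
      agg <- split(all$rgr, all$t_mid)
      data.frame(treatment = d$treatment[1],
        t_mid = as.numeric(names(agg)),
        rgr = vapply(agg, function(x) mean(x, na.rm = TRUE), numeric(1)),
        se = vapply(agg, function(x) {
          x <- x[!is.na(x)]
          if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
        }, numeric(1)),
        n = vapply(agg, function(x) sum(!is.na(x)), numeric(1)),
        row.names = NULL)
    } else {
      gm <- group_curve(d)
      r <- rgr(gm$time, gm$mean)
      data.frame(treatment = d$treatment[1], t_mid = r$t_mid, rgr = r$rgr,
                 se = NA_real_, n = max(gm$n), row.names = NULL)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit exponential growth by log-linear least squares
#'
#' Ordinary least squares of `ln(area)` on time over the positive-area
#' points: `A(t) = A0 exp(r t)`. The reported correlation is Pearson's r of
#' the linearised pairs and the significance is the regression F-test on
#' the linearised model.
#'
#' @param times,areas The series; at least 3 positive-area points.
#' @return An object of class `exp_growth_fit` with `a0` (pixels), `rate`
#'   (day^-1), `pearson_r`, `p_value`, `n`, and the underlying `lm` fit.
#'   Methods: `print`, `coef`, `predict(newdata = list(times = ...))`.
#' @examples
#' f <- fit_exponential(0:5, 120 * exp(0.35 * (0:5)))
#' coef(f)
#' @export
fit_exponential <- function(times, areas) {
  stopifnot(length(times) == length(areas))
  ok <- areas > 0
  if (sum(ok) < 3)
    stop("exponential fit needs at least 3 positive-area points")
  t <- times[ok]; la <- log(areas[ok])
  fit <- stats::lm(la ~ t)
  fs <- suppressWarnings(summary(fit))$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  r <- suppressWarnings(stats::cor(t, la))
  structure(list(a0 = exp(unname(stats::coef(fit)[1])),
    rate = unname(stats::coef(fit)[2]),
    pearson_r = r, p_value = unname(p), n = sum(ok), fit = fit),
    class = "exp_growth_fit")
}

#' @export
print.exp_growth_fit <- function(x, ...) {
  cat(sprintf("A(t) = %.1f * exp(%.4f t)   (n = %d, r = %.4f, p = %.3g)\n",
    x$a0, x$rate, x$n, x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
coef.exp_growth_fit <- function(object, ...) {
  c(a0 = object$a0, rate = object$rate)
}

#' @export
predict.exp_growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$fit$model$t else newdata$times
  object$a0 * exp(object$rate * t)
}

#' Group mean growth curve (mean +/- SE per time point)
#'
#' @param long Long data frame with `plant`, `time`, `area`, optionally
#'   `treatment`.
#' @return Data frame with `treatment` (if present), `time`, `mean`, `se`,
#'   `n`.
#' @export
group_curve <- function(long) {
  if (nrow(long) == 0) stop("empty group")
  by <- if ("treatment" %in% names(long))
    list(treatment = long$treatment, time = long$time)
  else list(time = long$time)
  agg <- split(long$area, by, drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(
    mean = vapply(agg, mean, numeric(1)),
    se = vapply(agg, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0, numeric(1)),
    n = vapply(agg, length, numeric(1)), row.names = NULL)
  if (ncol(keys) == 2) {
    out <- cbind(data.frame(treatment = keys[, 1],
      time = as.numeric(keys[, 2]), stringsAsFactors = FALSE), out)
    out <- out[order(out$treatment, out$time), ]
  } else {
    out <- cbind(data.frame(time = as.numeric(keys[, 1])), out)
    out <- out[order(out$time), ]
  }
  rownames(out) <- NULL
  out
}

#' Percentage area increase over a fixed window
#'
#' `100 * (A(t + window) - A(t)) / A(t)` for every observation with a
#' matching observation one window later; used to quantify the assay's
#' short-interval (e.g. 2-hour) sensitivity.
#'
#' @param times,areas The series (times in days).
#' @param window Window length, days (e.g. `2/24` for 2 hours).
#' @param tol Time-matching tolerance, days.
#' @return Numeric vector of percentages (`NA` where the baseline area is
#'   zero).
#' @export
interval_percent_increase <- function(times, areas, window, tol = 1e-6) {
  stopifnot(window > 0)
  if (window > diff(range(times))) stop("window exceeds the series span")
  out <- numeric(0)
  for (i in seq_along(times)) {
    j <- which(abs(times - (times[i] + window)) <= tol)
    if (length(j) == 1)
      out <- c(out, if (areas[i] > 0)
        100 * (areas[j] - areas[i]) / areas[i] else NA_real_)
  }
  out
}

#' Survival percentage at a given day
#'
#' A plant counts as dead once its area falls to the death threshold or
#' below at any observation up to `day`; death is absorbing, so a plant
#' dead earlier stays dead regardless of later values.
#'
#' @param long Long data frame with `plant`, `time`, `area`.
#' @param day Day at which survival is evaluated.
#' @param death_threshold Area at or below which a plant is dead (pixels).
#' @return Percentage of surviving plants.
#' @export
survival_rate <- function(long, day, death_threshold = 0) {
  if (nrow(long) == 0) stop("empty plant set")
  if (day < min(long$time) || day > max(long$time))
    stop("day outside the observed range")
  dead <- vapply(split(long, long$plant), function(p)
    any(p$area[p$time <= day] <= death_threshold), logical(1))
  100 * sum(!dead) / length(dead)
}

#' Survival curve per treatment
#' @inheritParams survival_rate
#' @return Data frame with `treatment`, `time`, `survival_pct`.
#' @export
survival_curve <- function(long, death_threshold = 0) {
  if (!"treatment" %in% names(long)) long$treatment <- "all"
  out <- do.call(rbind, lapply(split(long, long$treatment), function(d) {
    days <- sort(unique(d$time))
    data.frame(treatment = d$treatment[1], time = days,
      survival_pct = vapply(days, function(t)
        survival_rate(d, t, death_threshold), numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Population quartile summary of areas
#'
#' Q1/median/Q3 by linear interpolation between order statistics
#' (`stats::quantile` type 7), plus minimum, maximum and the standard error
#' of the mean — the per-day population descriptors reported alongside the
#' letter displays.
#'
#' @param x Numeric vector of areas (n >= 1).
#' @return One-row data frame with `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `se`.
#' @export
quartile_summary <- function(x) {
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = length(x), min = min(x), q1 = q[1], median = q[2],
    q3 = q[3], max = max(x),
    se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0)
}

#' Quartile summaries per treatment and day
#' @param long Long data frame with `treatment`, `time`, `area`.
#' @return Data frame of [quartile_summary()] rows keyed by `treatment`,
#'   `time`.
#' @export
quartile_table <- function(long) {
  if (!"treatment" %in% names(long)) long$treatment <- "all"
  parts <- split(long, list(long$treatment, long$time), drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(parts, function(d)
    cbind(data.frame(treatment = d$treatment[1], time = d$time[1]),
          quartile_summary(d$area))))
  out <- out[order(out$treatment, out$time), ]
  rownames(out) <- NULL
  out
}
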