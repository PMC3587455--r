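# Model evaluation statistics and temporal diagnostics following the UK
# DEFRA model evaluation protocol conventions, plus the constrained-NOx
# roadside NO2 chemistry test.

#' Evaluation statistics for one paired modelled/observed series
#'
#' Pairs with a missing modelled or observed value are dropped before any
#' statistic (pair-wise deletion). FAC2 counts pairs whose ratio M/O lies
#' in [0.5, 2]; a pair with O = 0 and M = 0 counts inside, with O = 0 and
#' M > 0 outside. MB is mean(M - O), NMB is sum(M - O) / sum(O), RMSE is
#' the root mean square error, r the Pearson correlation. r is NA when
#' fewer than two pairs remain or either series has zero variance.
#'
#' @param modelled,observed numeric vectors, ppb
#' @return data.frame row: `n`, `fac2`, `mb`, `nmb`, `rmse`, `r`
#' @export
eval_stats <- function(modelled, observed) {
  stopifnot(length(modelled) == length(observed))
  keep <- is.finite(modelled) & is.finite(observed)
  m <- modelled[keep]; o <- observed[keep]
  n <- length(m)
  if (n < 2) stop("need at least 2 complete pairs")
  inside <- ifelse(o == 0, m == 0, m / o >= 0.5 & m / o <= 2)
  r <- if (stats::sd(m) == 0 || stats::sd(o) == 0) NA_real_ else stats::cor(m, o)
  data.frame(n = n,
             fac2 = mean(inside),
             mb = mean(m - o),
             nmb = sum(m - o) / sum(o),
             rmse = sqrt(mean((m - o)^2)),
             r = r)
}

temporal_bins <- function(timestamps, mode) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  switch(mode,
    hour_of_day = list(bin = lt$hour + 1L, nbins = 24L),
    day_of_week = list(bin = (lt$wday + 6L) %% 7L + 1L, nbins = 7L),  # Mon=1
    month = list(bin = lt$mon + 1L, nbins = 12L),
    hour_of_week = list(bin = hour_of_week_index(timestamps), nbins = 168L),
    stop("unknown mode: ", mode))
}

#' Temporal bin means with confidence intervals
#'
#' Averages an hourly series by hour of day (24 bins), day of week (7,
#' Monday first), month (12) or hour of week (168, Monday 00:00 first).
#' The 95% confidence half-width is the normal approximation
#' 1.96 sd / sqrt(n) per bin; empty bins are NA.
#'
#' @param timestamps POSIXct (UTC)
#' @param values numeric series (NAs dropped per bin)
#' @param mode one of "hour_of_day", "day_of_week", "month", "hour_of_week"
#' @return data.frame: `bin`, `mean`, `ci_halfwidth`, `n`
#' @export
temporal_means <- function(timestamps, values, mode = "hour_of_day") {
  stopifnot(length(timestamps) == length(values))
  tb <- temporal_bins(timestamps, mode)
  out <- data.frame(bin = seq_len(tb$nbins), mean = NA_real_,
                    ci_halfwidth = NA_real_, n = 0L)
  for (b in seq_len(tb$nbins)) {
    v <- values[tb$bin == b & is.finite(values)]
    out$n[b] <- length(v)
    if (length(v)) {
      out$mean[b] <- mean(v)
      out$ci_halfwidth[b] <- if (length(v) > 1) {
        1.96 * stats::sd(v) / sqrt(length(v))
      } else 0
    }
  }
  out
}

#' Temporal profile of model residuals
#'
#' [temporal_means()] applied to modelled minus observed.
#'
#' @param timestamps POSIXct (UTC)
#' @param modelled,observed paired series, ppb
#' @inheritParams temporal_means
#' @return data.frame as [temporal_means()]
#' @export
residual_profile <- function(timestamps, modelled, observed,
                             mode = "hour_of_day") {
  stopifnot(length(modelled) == length(observed))
  temporal_means(timestamps, modelled - observed, mode)
}

#' Constrained-NOx roadside NO2 evaluation
#'
#' Isolates the chemistry scheme from the dispersion model: per hour the
#' modelled total NOx is constrained to the observed NOx at the site. In
#' the default `"total"` interpretation the background share of the
#' observed NOx is the downscaled background at the site and the remainder
#' is attributed to the road, split into NO and primary NO2 by `f_no2`;
#' under `"increment"` the entire observed NOx is treated as a road
#' increment on top of the background. The combined state is advanced over
#' the hour's time of flight and the modelled NO2 regressed (OLS with
#' intercept) on the observed NO2.
#'
#' @param observed_nox hourly observed NOx, ppb
#' @param f_no2 primary NO2 fraction of the road NOx (mole basis; equal to
#'   the inventory NO2-mass fraction of NOx-as-NO2)
#' @param background_o3 hourly background O3, ppb
#' @param rates a [rate_params()]
#' @param tof hourly time of flight, s (scalar or vector)
#' @param background_no,background_no2 hourly background NO and NO2, ppb
#'   (default 0)
#' @param observed_no2 hourly observed NO2, ppb; required for the
#'   regression output
#' @param mode "total" or "increment"
#' @return list: `modelled_no2` series, `r_squared` (NA when the
#'   regression is degenerate), `mean_modelled`, `mean_observed`
#' @export
constrained_no2_eval <- function(observed_nox, f_no2, background_o3, rates,
                                 tof, background_no = 0, background_no2 = 0,
                                 observed_no2 = NULL,
                                 mode = c("total", "increment")) {
  mode <- match.arg(mode)
  n <- length(observed_nox)
  if (length(background_o3) != n && length(background_o3) != 1) {
    stop("misaligned series: background_o3")
  }
  if (!is.null(observed_no2) && length(observed_no2) != n) {
    stop("misaligned series: observed_no2")
  }
  bg_no <- rep_len(background_no, n)
  bg_no2 <- rep_len(background_no2, n)
  bg_o3 <- rep_len(background_o3, n)
  if (mode == "total") {
    road_nox <- pmax(observed_nox - bg_no - bg_no2, 0)
  } else {
    road_nox <- pmax(observed_nox, 0)
  }
  st <- chem_state(no = bg_no + (1 - f_no2) * road_nox,
                   no2 = bg_no2 + f_no2 * road_nox,
                   o3 = bg_o3)
  out <- advance_chemistry(st, rates, rep_len(tof, n))
  r2 <- NA_real_
  if (!is.null(observed_no2)) {
    if (stats::sd(out$no2) > 0 && stats::sd(observed_no2) > 0) {
      # R^2 of the OLS-with-intercept regression of modelled on observed
      r2 <- stats::cor(out$no2, observed_no2)^2
    }
  }
  list(modelled_no2 = out$no2, r_squared = r2,
       mean_modelled = mean(out$no2),
       mean_observed = if (is.null(observed_no2)) NA_real_ else mean(observed_no2))
}
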