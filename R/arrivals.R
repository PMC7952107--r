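#' Hourly arrival-rate profile
#'
#' A non-homogeneous Poisson arrival process with a piecewise-constant
#' rate: one rate (patients/hour) per clock hour, repeated daily, plus the
#' proportion of arrivals triaged ESI 4 (the remainder are ESI 5).
#'
#' @param hourly_rates Numeric vector of 24 nonnegative rates,
#'   patients/hour, for clock hours 0-23.
#' @param esi4_fraction Proportion of arrivals labeled ESI 4, in \[0, 1\].
#' @return An object of class `arrival_profile`.
#' @export
arrival_profile <- function(hourly_rates, esi4_fraction) {
  hourly_rates <- as.numeric(hourly_rates)
  if (length(hourly_rates) != 24L || any(!is.finite(hourly_rates)))
    stop("hourly_rates must be 24 finite values")
  if (any(hourly_rates < 0)) stop("arrival rates must be nonnegative")
  stopifnot(length(esi4_fraction) == 1L, esi4_fraction >= 0,
            esi4_fraction <= 1)
  structure(list(hourly_rates = hourly_rates,
                 esi4_fraction = esi4_fraction),
            class = "arrival_profile")
}

#' @export
print.arrival_profile <- function(x, ...) {
  cat(sprintf(
    "<arrival_profile> %.0f expected arrivals/year (%.1f/day), rates %.2f-%.2f/h, ESI-4 fraction %.3f\n",
    365 * sum(x$hourly_rates), sum(x$hourly_rates),
    min(x$hourly_rates), max(x$hourly_rates), x$esi4_fraction))
  invisible(x)
}

#' Default diurnal arrival profile for the low-acuity track
#'
#' A smooth 24-point diurnal shape with its trough at 05:00 and peak at
#' 19:00 (a rising half-cosine over 05:00-19:00 and a falling one
#' overnight), affinely mapped so the slowest hour runs at `rate_min` and
#' the busiest at `rate_max`, then bent by a single power exponent --
#' solved numerically at construction -- so the expected annual volume is
#' exactly `annual_total`. Defaults reproduce the published low-acuity
#' workload: rates spanning 1.63-8.56 patients/hour and 44,962 annual
#' visits of which 35,838 are ESI 4.
#'
#' @param annual_total Expected arrivals per 365-day year.
#' @param annual_esi4 Expected ESI-4 arrivals per year (sets
#'   `esi4_fraction`).
#' @param rate_min,rate_max Slowest and busiest hourly rates,
#'   patients/hour.
#' @param trough_hour,peak_hour Clock hours of the diurnal trough and peak.
#' @return An [arrival_profile()].
#' @export
default_arrival_profile <- function(annual_total = 44962,
                                    annual_esi4 = 35838,
                                    rate_min = 1.63, rate_max = 8.56,
                                    trough_hour = 5, peak_hour = 19) {
  stopifnot(rate_max > rate_min, rate_min >= 0,
            annual_total > 0, annual_esi4 <= annual_total)
  h <- 0:23 + 0.5                       # rate evaluated at hour midpoints
  up <- ((h - trough_hour) %% 24) < ((peak_hour - trough_hour) %% 24)
  rise <- (peak_hour - trough_hour) %% 24
  fall <- 24 - rise
  shape <- ifelse(up,
                  (1 - cos(pi * ((h - trough_hour) %% 24) / rise)) / 2,
                  (1 + cos(pi * ((h - peak_hour) %% 24) / fall)) / 2)
  g <- (shape - min(shape)) / (max(shape) - min(shape))
  target_mean <- annual_total / 365 / 24
  mean_for <- function(p) mean(rate_min + (rate_max - rate_min) * g^p)
  if (target_mean <= mean_for(8) || target_mean >= mean_for(1 / 8))
    stop("annual_total is not reachable within [rate_min, rate_max]")
  p <- stats::uniroot(function(p) mean_for(p) - target_mean,
                      c(1 / 8, 8), tol = 1e-12)$root
  arrival_profile(rate_min + (rate_max - rate_min) * g^p,
                  annual_esi4 / annual_total)
}

#' Generate non-homogeneous Poisson arrivals
#'
#' Simulates the piecewise-constant-rate Poisson arrival process over a
#' horizon of whole days: for each day and clock hour the number of
#' arrivals is Poisson with that hour's rate and arrival instants are
#' uniform within the hour. Each arrival is labeled ESI 4 independently
#' with probability `esi4_fraction`, else ESI 5. Times are strictly
#' increasing (ties broken by generation order).
#'
#' @param profile An [arrival_profile()].
#' @param horizon_days Number of simulated days (>= 1).
#' @return A data frame with columns `time` (minutes since simulation
#'   start) and `esi` (integer 4 or 5), ordered by time.
#' @export
nhpp_arrivals <- function(profile, horizon_days) {
  stopifnot(inherits(profile, "arrival_profile"),
            length(horizon_days) == 1L, horizon_days >= 1)
  horizon_days <- as.integer(horizon_days)
  rates <- profile$hourly_rates
  # counts for every (day, hour) cell, then uniform placement within cell
  n_cell <- stats::rpois(horizon_days * 24L, rep(rates, horizon_days))
  total <- sum(n_cell)
  if (total == 0L) {
    return(data.frame(time = numeric(0), esi = integer(0)))
  }
  cell_start <- rep.int(seq_len(horizon_days * 24L) - 1L, n_cell) * 60
  times <- cell_start + stats::runif(total) * 60
  ord <- order(times)
  times <- times[ord]
  esi <- ifelse(stats::runif(total) < profile$esi4_fraction, 4L, 5L)
  data.frame(time = times, esi = esi)
}
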