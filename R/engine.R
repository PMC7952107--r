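#' Simulate one replication of low-acuity ED patient flow
#'
#' Runs the discrete-event model for `warmup + horizon` days of arrivals
#' and follows every patient to disposition (the run is drained past the
#' horizon, so late arrivals are not censored). Patients arriving during
#' the warm-up period are simulated -- they load the system -- but are
#' excluded from the returned visit log, which removes the empty-ED
#' initialization bias.
#'
#' Randomness is organised as named streams spawned from `seed` via
#' [stream_seeds()]: one stream for the arrival process (times and ESI
#' labels), one for the testing decision (a uniform per patient compared
#' against `p_test_esi4`/`p_test_esi5`, so raising the testing proportion
#' under the same seed only adds tested patients -- the common-random-
#' numbers coupling used for scenario comparisons), one for the resident
#' assignment, and one per service-time process. Service durations for
#' every process are drawn for every patient up front, so a patient's
#' durations do not depend on which branch they take.
#'
#' @param pathway A [pathway_config()].
#' @param resources A [resource_config()].
#' @param profile An [arrival_profile()].
#' @param horizon_days Length of the measured period in days (>= 1).
#' @param warmup_days Warm-up days preceding the measured period
#'   (>= 0, default 7).
#' @param seed Integer master seed for the replication.
#' @return A `visit_log` data frame, one row per non-warm-up patient:
#'   `patient_id`, `esi`, `arrival`, `screening_start`, `screening_end`,
#'   `vitals_end`, `room_entry`, `provider_start`, `tested`,
#'   `disposition`, `los`, `wait` (all times in minutes since simulation
#'   start, i.e. including the warm-up offset), plus the accounting
#'   columns `room_acquired`, `discharge_start`, `cleaning_end`,
#'   `nurse_min`, `provider_min` used by [utilization()].
#' @examples
#' log <- run_replication(default_pathway(), resource_config(12, 3, 2),
#'                        default_arrival_profile(),
#'                        horizon_days = 7, warmup_days = 2, seed = 1)
#' summarize_visits(log)
#' @export
run_replication <- function(pathway, resources, profile,
                            horizon_days = 365, warmup_days = 7,
                            seed = 1L) {
  stopifnot(inherits(pathway, "pathway_config"),
            inherits(resources, "resource_config"),
            inherits(profile, "arrival_profile"))
  if (horizon_days < 1) stop("horizon_days must be >= 1")
  if (warmup_days < 0) stop("warmup_days must be >= 0")

  labels <- c("arrivals", "tested", "resident", PROCESS_NAMES)
  ss <- stream_seeds(seed, length(labels), labels)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)

  total_days <- warmup_days + horizon_days
  set.seed(ss[["arrivals"]])
  arr <- nhpp_arrivals(profile, total_days)
  n <- nrow(arr)
  if (n == 0L) return(empty_visit_log())

  set.seed(ss[["tested"]])
  u_test <- stats::runif(n)
  p_test <- ifelse(arr$esi == 4L, pathway$p_test_esi4, pathway$p_test_esi5)
  tested <- u_test < p_test

  set.seed(ss[["resident"]])
  resident <- stats::runif(n) < resources$resident_fraction

  draw <- function(name) {
    set.seed(ss[[name]])
    build_sampler(pathway$specs[[name]])(n)
  }
  testing <- ifelse(arr$esi == 4L,
                    draw("testing_treatment_esi4"),
                    draw("testing_treatment_esi5"))
  dur <- cbind(draw("nurse_screening"), draw("vitals"),
               draw("transfer_to_room"), draw("attending_eval"),
               draw("resident_eval"), draw("attending_resident_review"),
               draw("attending_reassessment"), testing,
               draw("nurse_discharge"), draw("bed_cleaning"))

  out <- .sim_ed_cpp(arr$time, arr$esi, tested, resident, dur,
                     resources$n_rooms, resources$n_nurses,
                     resources$n_providers, resources$n_residents)

  keep <- arr$time >= warmup_days * 1440
  log <- data.frame(
    patient_id = which(keep),
    esi = arr$esi[keep],
    arrival = arr$time[keep],
    screening_start = out$screening_start[keep],
    screening_end = out$screening_end[keep],
    vitals_end = out$vitals_end[keep],
    room_entry = out$room_entry[keep],
    provider_start = out$provider_start[keep],
    tested = tested[keep],
    disposition = out$disposition[keep],
    room_acquired = out$room_acquired[keep],
    discharge_start = out$discharge_start[keep],
    cleaning_end = out$cleaning_end[keep],
    nurse_min = out$nurse_min[keep],
    provider_min = out$provider_min[keep]
  )
  log$los <- log$disposition - log$arrival
  log$wait <- log$provider_start - log$arrival
  class(log) <- c("visit_log", "data.frame")
  log
}

empty_visit_log <- function() {
  log <- data.frame(
    patient_id = integer(0), esi = integer(0), arrival = numeric(0),
    screening_start = numeric(0), screening_end = numeric(0),
    vitals_end = numeric(0), room_entry = numeric(0),
    provider_start = numeric(0), tested = logical(0),
    disposition = numeric(0), room_acquired = numeric(0),
    discharge_start = numeric(0), cleaning_end = numeric(0),
    nurse_min = numeric(0), provider_min = numeric(0),
    los = numeric(0), wait = numeric(0)
  )
  class(log) <- c("visit_log", "data.frame")
  log
}

#' Resource busy fractions over a simulated period
#'
#' Aggregates the per-patient service minutes in a visit log into mean
#' busy fractions per resource class: nurses (screening + vitals +
#' discharge), providers (evaluation, review, reassessment) and rooms
#' (from room acquisition until bed cleaning completes). Fractions are
#' service minutes delivered to logged patients divided by the resource
#' pool's capacity minutes over the horizon; warm-up patients' service is
#' not counted, so the figure describes the measured period.
#'
#' @param log A `visit_log` from [run_replication()].
#' @param resources The [resource_config()] used for the run.
#' @param horizon_days Length of the measured period in days.
#' @return Named numeric vector of busy fractions (`rooms`, `nurses`,
#'   `providers`), each in \[0, 1\] (service carried past the end of the
#'   horizon while the run drains is capped at full occupancy).
#' @export
utilization <- function(log, resources, horizon_days) {
  stopifnot(inherits(log, "visit_log"),
            inherits(resources, "resource_config"), horizon_days >= 1)
  if (nrow(log) == 0L) stop("empty visit log: nothing to summarize")
  cap <- horizon_days * 1440
  out <- c(
    rooms = sum(log$cleaning_end - log$room_acquired) /
      (resources$n_rooms * cap),
    nurses = sum(log$nurse_min) / (resources$n_nurses * cap),
    providers = sum(log$provider_min) / (resources$n_providers * cap))
  pmin(out, 1)
}
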