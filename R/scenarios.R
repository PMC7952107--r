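#' Testing-rate scenario configuration
#'
#' One what-if arm of a scenario experiment: a label, the per-ESI testing
#' proportions, and the replication design (number of independent
#' replications of a fixed horizon).
#'
#' @param label Scenario name.
#' @param p_test_esi4,p_test_esi5 Testing proportions in \[0, 1\].
#' @param n_reps Replications (>= 2 for interval inference; default 5).
#' @param horizon_days Days per replication (default 365).
#' @param warmup_days Warm-up days per replication (default 7).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(label, p_test_esi4, p_test_esi5,
                            n_reps = 5, horizon_days = 365,
                            warmup_days = 7) {
  stopifnot(is.character(label), length(label) == 1L,
            p_test_esi4 >= 0, p_test_esi4 <= 1,
            p_test_esi5 >= 0, p_test_esi5 <= 1,
            n_reps >= 2, horizon_days >= 1, warmup_days >= 0)
  structure(list(label = label, p_test_esi4 = p_test_esi4,
                 p_test_esi5 = p_test_esi5, n_reps = as.integer(n_reps),
                 horizon_days = horizon_days, warmup_days = warmup_days),
            class = "scenario_config")
}

#' Shipped calibrated resource configuration
#'
#' The resource counts obtained by calibrating the model against the
#' current-testing outcome surface (mean LOS 156.8/133.3 min and mean
#' wait 87.6/85.1 min for ESI 4/5) with [calibrate_resources()] over a
#' grid of 6-20 rooms, 2-8 nurses and 1-6 providers, using the default
#' pathway and arrival profile. See the package vignette for the
#' calibration procedure and its limits.
#'
#' @return A [resource_config()].
#' @export
default_resources <- function() {
  resource_config(n_rooms = 10, n_nurses = 2, n_providers = 2)
}

#' Run a multi-scenario replication experiment
#'
#' Simulates every scenario for its configured number of replications,
#' summarizes each replication per ESI, and compares each alternative
#' scenario against the first (baseline) scenario with pooled-variance t
#' intervals on the replication means (n = `n_reps` per arm), for both
#' outcomes (LOS and wait) and both ESI levels. Differences are reported
#' as baseline minus alternative, so a positive LOS difference means the
#' alternative shortens stays. Total patient-hours saved per ESI are the
#' per-year patient volume times the per-patient LOS difference.
#'
#' By default every arm and replication gets an independent random
#' stream. With `paired_streams = TRUE` replication r of every scenario
#' shares one stream (common random numbers): arrivals and service times
#' coincide and scenarios differ only through the testing threshold,
#' which makes monotonicity comparisons essentially noise-free.
#'
#' @param scenarios List of [scenario_config()]s; the first is the
#'   baseline arm.
#' @param resources A [resource_config()] (default the shipped calibrated
#'   configuration).
#' @param pathway A [pathway_config()] providing the service
#'   distributions; each scenario overrides its testing proportions.
#' @param profile An [arrival_profile()].
#' @param master_seed Integer master seed; per-(scenario, replication)
#'   seeds are spawned from it via [stream_seeds()].
#' @param paired_streams Use common random numbers across scenarios?
#' @return An object of class `experiment_result`: list with
#'   `summaries` (data frame: scenario, rep, esi, n, mean_los,
#'   mean_wait), `comparisons` (stacked [pooled_t_ci()] rows with
#'   `scenario` = the alternative's label), and `patient_hours` (data
#'   frame: scenario, esi, n_patients_year, hours_saved).
#' @export
run_experiment <- function(scenarios, resources = default_resources(),
                           pathway = default_pathway(),
                           profile = default_arrival_profile(),
                           master_seed = 1L, paired_streams = FALSE) {
  stopifnot(is.list(scenarios), length(scenarios) >= 2)
  for (sc in scenarios) stopifnot(inherits(sc, "scenario_config"))
  n_sc <- length(scenarios)
  labels <- vapply(scenarios, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique")
  max_reps <- max(vapply(scenarios, `[[`, 0L, "n_reps"))
  # Seeds keyed by scenario label (not list position), so results are
  # invariant to scenario ordering; paired_streams shares one seed set
  # across scenarios (common random numbers).
  seed_for <- function(label) {
    if (paired_streams) return(stream_seeds(master_seed, max_reps))
    h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99989L
    stream_seeds((as.integer(master_seed) %% 1000003L) * 2000L + h,
                 max_reps)
  }

  summaries <- do.call(rbind, lapply(seq_len(n_sc), function(i) {
    sc <- scenarios[[i]]
    rep_seeds <- seed_for(sc$label)
    pw <- pathway
    pw$p_test_esi4 <- sc$p_test_esi4
    pw$p_test_esi5 <- sc$p_test_esi5
    do.call(rbind, lapply(seq_len(sc$n_reps), function(r) {
      log <- run_replication(pw, resources, profile, sc$horizon_days,
                             sc$warmup_days, seed = rep_seeds[r])
      cbind(scenario = sc$label, summarize_visits(log, rep_id = r))
    }))
  }))

  base <- scenarios[[1L]]$label
  arm_stats <- function(label, esi, col) {
    x <- summaries[summaries$scenario == label & summaries$esi == esi,
                   col]
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  comparisons <- do.call(rbind, lapply(scenarios[-1L], function(sc) {
    do.call(rbind, lapply(c(4L, 5L), function(e) {
      do.call(rbind, lapply(c(los = "mean_los", wait = "mean_wait"),
                            function(col) {
        a <- arm_stats(base, e, col)
        b <- arm_stats(sc$label, e, col)
        cbind(scenario = sc$label,
              pooled_t_ci(a$mean, a$sd, a$n, b$mean, b$sd, b$n,
                          metric = sub("mean_", "", col), esi = e))
      }))
    }))
  }))
  rownames(comparisons) <- NULL

  horizon_base <- scenarios[[1L]]$horizon_days
  patient_hours <- do.call(rbind, lapply(scenarios[-1L], function(sc) {
    do.call(rbind, lapply(c(4L, 5L), function(e) {
      n_year <- mean(summaries[summaries$scenario == base &
                                 summaries$esi == e, "n"]) *
        365 / horizon_base
      d <- comparisons[comparisons$scenario == sc$label &
                         comparisons$esi == e &
                         comparisons$metric == "los", "difference"]
      data.frame(scenario = sc$label, esi = e,
                 n_patients_year = n_year,
                 hours_saved = total_patient_hours(n_year, d))
    }))
  }))

  structure(list(summaries = summaries, comparisons = comparisons,
                 patient_hours = patient_hours, baseline = base),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> baseline:", x$baseline, "\n")
  agg <- stats::aggregate(cbind(mean_los, mean_wait) ~ scenario + esi,
                          x$summaries, mean)
  print(agg, row.names = FALSE)
  cat("\nComparisons (baseline - alternative), 95% CI:\n")
  cmp <- x$comparisons[, c("scenario", "esi", "metric", "difference",
                           "ci_low", "ci_high")]
  cmp[, 4:6] <- lapply(cmp[, 4:6], round_display)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Calibrate resource counts against an outcome surface
#'
#' Grid search over integer resource counts minimizing the sum of squared
#' relative errors between simulated and target mean LOS/wait per ESI:
#' \eqn{\sum_k ((sim_k - target_k)/target_k)^2} over the four targets.
#' Every candidate is simulated with the same seed(s), so the search is
#' deterministic given `master_seed` and the comparison across candidates
#' uses common random numbers. A candidate within 25% of every target is
#' required for the calibration to be declared converged; otherwise the
#' best candidate is still returned with `converged = FALSE` and the
#' per-target errors for diagnosis.
#'
#' @param targets Named numeric vector with `los4`, `los5`, `wait4`,
#'   `wait5` (minutes).
#' @param search_space List with integer vectors `n_rooms`, `n_nurses`,
#'   `n_providers` defining the grid (defaults 6-20 rooms, 2-8 nurses,
#'   1-6 providers).
#' @param pathway,profile Model configuration to calibrate under.
#' @param horizon_days,warmup_days,n_reps Simulation effort per
#'   candidate.
#' @param master_seed Seed for the candidate replications.
#' @return List with `resources` (best [resource_config()]), `achieved`
#'   (named vector), `score`, `converged`, `max_rel_error`, and `fits`
#'   (data frame of every candidate's score).
#' @export
calibrate_resources <- function(targets,
                                search_space = list(n_rooms = 6:20,
                                                    n_nurses = 2:8,
                                                    n_providers = 1:6),
                                pathway = default_pathway(),
                                profile = default_arrival_profile(),
                                horizon_days = 90, warmup_days = 7,
                                n_reps = 1, master_seed = 1L) {
  req <- c("los4", "los5", "wait4", "wait5")
  stopifnot(all(req %in% names(targets)), all(targets[req] > 0))
  grid <- expand.grid(n_rooms = search_space$n_rooms,
                      n_nurses = search_space$n_nurses,
                      n_providers = search_space$n_providers)
  seeds <- stream_seeds(master_seed, n_reps)
  eval_candidate <- function(rooms, nurses, providers) {
    res <- resource_config(rooms, nurses, providers)
    s <- do.call(rbind, lapply(seeds, function(sd)
      summarize_visits(run_replication(pathway, res, profile,
                                       horizon_days, warmup_days, sd))))
    c(los4 = mean(s$mean_los[s$esi == 4]),
      los5 = mean(s$mean_los[s$esi == 5]),
      wait4 = mean(s$mean_wait[s$esi == 4]),
      wait5 = mean(s$mean_wait[s$esi == 5]))
  }
  achieved <- matrix(NA_real_, nrow(grid), 4,
                     dimnames = list(NULL, req))
  for (i in seq_len(nrow(grid))) {
    achieved[i, ] <- eval_candidate(grid$n_rooms[i], grid$n_nurses[i],
                                    grid$n_providers[i])
  }
  rel <- sweep(sweep(achieved, 2, targets[req]), 2, targets[req], "/")
  score <- rowSums(rel^2)
  best <- which.min(score)
  max_rel <- max(abs(rel[best, ]))
  fits <- cbind(grid, score = score)
  if (max_rel > 0.25) {
    warning(sprintf(
      "calibration failure: best candidate misses a target by %.0f%% (> 25%%)",
      100 * max_rel))
  }
  list(resources = resource_config(grid$n_rooms[best],
                                   grid$n_nurses[best],
                                   grid$n_providers[best]),
       achieved = achieved[best, ], score = score[best],
       converged = max_rel <= 0.25, max_rel_error = max_rel,
       fits = fits)
}

#' Individualized provider impact report
#'
#' Situates one provider's diagnostic-testing rate within the provider
#' panel (rate, rank, percentile, visit share) and predicts the change in
#' system mean LOS attributable to that provider moving their panel to
#' the benchmark testing rate. Attribution is linear: with `D` the full
#' current-versus-benchmark mean-LOS difference, `b` the benchmark rate,
#' `P` the visit-weighted population rate, provider `i` with visit share
#' `w_i` and rate `p_i` is credited
#' \eqn{D \cdot w_i (p_i - b) / (P - b)}, a documented reporting
#' convention under which the per-provider credits sum (visit-weighted)
#' to the full system difference.
#'
#' @param provider_id Provider to report on.
#' @param providers Provider table (see [compute_abc()]).
#' @param esi ESI level.
#' @param benchmark A `benchmark_result` for that ESI (default: computed
#'   from `providers`).
#' @param full_los_difference_min The system-wide mean-LOS difference
#'   (minutes) between current and benchmark testing, e.g. from
#'   [run_experiment()].
#' @return List with `provider_id`, `esi`, `rate`, `rank`,
#'   `percentile`, `visit_share`, `benchmark_rate`, `population_rate`,
#'   `predicted_los_change_min`, and `panel_rates` (all providers' rates,
#'   for the distribution display).
#' @export
provider_impact_report <- function(provider_id, providers, esi,
                                   benchmark = compute_abc(providers, esi),
                                   full_los_difference_min) {
  validate_provider_table(providers)
  sub <- providers[providers$esi == esi & providers$n_visits > 0, ,
                   drop = FALSE]
  idx <- match(provider_id, sub$provider_id)
  if (is.na(idx)) stop("unknown provider id: ", provider_id)
  rates <- sub$n_tested / sub$n_visits
  w <- sub$n_visits / sum(sub$n_visits)
  pop <- sum(w * rates)
  b <- benchmark$benchmark_rate
  credit <- if (abs(pop - b) < .Machine$double.eps^0.5) 0 else
    full_los_difference_min * w[idx] * (rates[idx] - b) / (pop - b)
  list(provider_id = provider_id, esi = esi,
       rate = rates[idx],
       rank = rank(rates, ties.method = "min")[idx],
       percentile = 100 * mean(rates <= rates[idx]),
       visit_share = w[idx],
       benchmark_rate = b, population_rate = pop,
       predicted_los_change_min = credit,
       panel_rates = stats::setNames(rates, sub$provider_id))
}
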