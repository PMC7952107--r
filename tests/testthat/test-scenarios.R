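short_scen <- function(label, p4, p5, reps = 2) {
  scenario_config(label, p4, p5, n_reps = reps, horizon_days = 30,
                  warmup_days = 3)
}

test_that("identical scenarios under paired streams differ by exactly zero", {
  ex <- run_experiment(list(short_scen("a", 0.2, 0.1),
                            short_scen("b", 0.2, 0.1)),
                       resource_config(10, 2, 2), master_seed = 5,
                       paired_streams = TRUE)
  expect_true(all(ex$comparisons$difference == 0))
  expect_true(all(ex$patient_hours$hours_saved == 0))
})

test_that("scenario outputs are invariant to scenario ordering", {
  scens <- list(short_scen("current", 0.225, 0.119),
                short_scen("abc", 0.135, 0.042))
  e1 <- run_experiment(scens, resource_config(10, 2, 2), master_seed = 9)
  e2 <- run_experiment(rev(scens), resource_config(10, 2, 2), master_seed = 9)
  for (lab in c("current", "abc")) {
    expect_equal(e1$summaries[e1$summaries$scenario == lab, -1],
                 e2$summaries[e2$summaries$scenario == lab, -1],
                 ignore_attr = TRUE)
  }
})

test_that("mean LOS is non-decreasing along the testing-rate ladder under CRN", {
  tab <- gen_provider_table(cohort_spec(seed = 17))
  p90_4 <- provider_percentile_rate(tab, 4, 90)
  p90_5 <- provider_percentile_rate(tab, 5, 90)
  max_4 <- provider_percentile_rate(tab, 4, 100)
  max_5 <- provider_percentile_rate(tab, 5, 100)
  b4 <- compute_abc(tab, 4)$benchmark_rate
  b5 <- compute_abc(tab, 5)$benchmark_rate
  ladder <- list(c(b4, b5), c(0.225, 0.119), c(p90_4, p90_5),
                 c(max_4, max_5), c(1, 1))
  expect_true(all(diff(vapply(ladder, `[`, 0, 1)) >= 0))  # rates ordered
  scens <- lapply(seq_along(ladder), function(i)
    short_scen(paste0("s", i), ladder[[i]][1], ladder[[i]][2]))
  ex <- run_experiment(scens, resource_config(10, 2, 2), master_seed = 31,
                       paired_streams = TRUE)
  los4 <- vapply(paste0("s", seq_along(ladder)), function(lab)
    mean(ex$summaries$mean_los[ex$summaries$scenario == lab &
                                 ex$summaries$esi == 4]), numeric(1))
  expect_true(all(diff(los4) >= 0))
})

test_that("comparisons are derived from the contained summaries", {
  scens <- list(short_scen("base", 0.3, 0.2), short_scen("alt", 0.1, 0.05))
  ex <- run_experiment(scens, resource_config(10, 2, 2), master_seed = 12)
  s <- ex$summaries
  a <- s$mean_los[s$scenario == "base" & s$esi == 4]
  b <- s$mean_los[s$scenario == "alt" & s$esi == 4]
  row <- ex$comparisons[ex$comparisons$esi == 4 &
                          ex$comparisons$metric == "los", ]
  expect_equal(row$difference, mean(a) - mean(b))
  expect_equal(row$n_a, length(a))
  ref <- pooled_t_ci(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  expect_equal(row$ci_low, ref$ci_low)
})

test_that("calibration on a size-one search space returns that configuration", {
  targets <- c(los4 = 100, los5 = 90, wait4 = 50, wait5 = 50)
  cal <- suppressWarnings(calibrate_resources(
    targets, search_space = list(n_rooms = 9, n_nurses = 3, n_providers = 2),
    horizon_days = 20, master_seed = 4))
  expect_equal(cal$resources$n_rooms, 9L)
  expect_equal(nrow(cal$fits), 1L)
  expect_true(is.finite(cal$score))
})

test_that("calibration recovers a known configuration from its own outputs", {
  prof <- default_arrival_profile()
  pw <- default_pathway()
  truth <- resource_config(10, 2, 2)
  seeds <- stream_seeds(901, 2)
  s <- do.call(rbind, lapply(seeds, function(sd)
    summarize_visits(run_replication(pw, truth, prof, 60, 5, sd))))
  targets <- c(los4 = mean(s$mean_los[s$esi == 4]),
               los5 = mean(s$mean_los[s$esi == 5]),
               wait4 = mean(s$mean_wait[s$esi == 4]),
               wait5 = mean(s$mean_wait[s$esi == 5]))
  cal <- calibrate_resources(
    targets, search_space = list(n_rooms = 9:11, n_nurses = 2:3,
                                 n_providers = 2),
    pathway = pw, profile = prof, horizon_days = 60, warmup_days = 5,
    n_reps = 2, master_seed = 77)
  expect_true(cal$converged)
  expect_true(all(abs(cal$achieved - targets) / targets < 0.10))
})

test_that("infeasible calibration targets are reported as failure", {
  targets <- c(los4 = 1, los5 = 1, wait4 = 0.5, wait5 = 0.5)
  expect_warning(
    cal <- calibrate_resources(
      targets, search_space = list(n_rooms = 10, n_nurses = 2,
                                   n_providers = 2),
      horizon_days = 10, master_seed = 3),
    "calibration failure")
  expect_false(cal$converged)
})

test_that("provider impact reports attribute the system difference linearly", {
  tab <- gen_provider_table(cohort_spec(seed = 13))
  b <- compute_abc(tab, 4)
  D <- 19.1
  reports <- lapply(tab$provider_id[tab$esi == 4], provider_impact_report,
                    providers = tab, esi = 4, benchmark = b,
                    full_los_difference_min = D)
  credits <- vapply(reports, `[[`, 0, "predicted_los_change_min")
  expect_equal(sum(credits), D)  # visit-weighted credits conserve the total
  # a provider exactly at the benchmark rate gets zero credit
  tab2 <- rbind(tab, data.frame(provider_id = "AT_BM", esi = 4L,
                                n_visits = 1000,
                                n_tested = round(1000 * b$benchmark_rate)))
  r <- provider_impact_report("AT_BM", tab2, 4, b, D)
  expect_lt(abs(r$predicted_los_change_min),
            abs(D) * 0.001 + 1e-6)
  expect_error(provider_impact_report("nobody", tab, 4, b, D), "unknown")
})
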