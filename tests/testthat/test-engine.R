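test_that("hand-traced single-patient pathway reproduces exact milestones", {
  pw <- constant_pathway(nurse_screening = const_spec(3),
                         vitals = const_spec(2),
                         transfer_to_room = const_spec(10),
                         attending_eval = const_spec(15),
                         nurse_discharge = const_spec(10),
                         bed_cleaning = const_spec(5))
  prof <- arrival_profile(c(0.5, rep(0, 23)), 1)  # sparse: no contention
  log <- run_replication(pw, ample(), prof, 20, 0, seed = 4)
  expect_gt(nrow(log), 3)
  expect_equal(unique(log$wait), 15)   # 3 + 2 + 10
  expect_equal(unique(log$los), 40)    # 3 + 2 + 10 + 15 + 10
  # bed cleaning happens after disposition and does not extend LOS
  expect_equal(log$cleaning_end - log$disposition, rep(5, nrow(log)))
})

test_that("all-zero services with ample resources give zero LOS and wait", {
  log <- run_replication(constant_pathway(), ample(),
                         arrival_profile(rep(1, 24), 0.8), 5, 0, seed = 2)
  expect_true(all(log$los == 0))
  expect_true(all(log$wait == 0))
})

test_that("identical seeds and configs give bitwise-identical visit logs", {
  pw <- default_pathway()
  res <- resource_config(8, 2, 2)
  prof <- default_arrival_profile()
  a <- run_replication(pw, res, prof, 10, 2, seed = 77)
  b <- run_replication(pw, res, prof, 10, 2, seed = 77)
  expect_identical(a, b)
})

test_that("visit logs satisfy the record invariants and conservation", {
  log <- run_replication(default_pathway(), default_resources(),
                         default_arrival_profile(), 30, 7, seed = 12)
  expect_false(anyNA(log))  # every arrival followed to disposition
  expect_false(anyDuplicated(log$patient_id) > 0)
  expect_true(all(log$arrival >= 7 * 1440))  # warm-up patients excluded
  with(log, {
    expect_true(all(arrival <= screening_start + 1e-9))
    expect_true(all(screening_start <= screening_end))
    expect_true(all(screening_end <= vitals_end))
    expect_true(all(vitals_end <= room_entry + 1e-9))
    expect_true(all(room_entry <= provider_start + 1e-9))
    expect_true(all(provider_start <= disposition + 1e-9))
    expect_true(all(abs(los - (disposition - arrival)) < 1e-9))
    expect_true(all(abs(wait - (provider_start - arrival)) < 1e-9))
    expect_true(all(wait >= 0 & wait <= los + 1e-9))
  })
})

test_that("with ample resources mean wait equals the analytic pre-provider path", {
  pw <- default_pathway(0, 0)
  log <- run_replication(pw, ample(), default_arrival_profile(), 60, 0,
                         seed = 3)
  expected <- analytic_mean(pw$specs$nurse_screening) +
    analytic_mean(pw$specs$vitals) +
    analytic_mean(pw$specs$transfer_to_room)
  se <- stats::sd(log$wait) / sqrt(nrow(log))
  expect_lt(abs(mean(log$wait) - expected), 4 * se)
})

test_that("mean LOS is non-decreasing in testing rate under common random numbers", {
  prev <- -Inf
  for (p in c(0, 0.135, 0.225, 0.5)) {
    log <- run_replication(default_pathway(p, p), resource_config(10, 2, 2),
                           default_arrival_profile(), 45, 5, seed = 42)
    m <- mean(log$los)
    expect_gte(m, prev)
    prev <- m
  }
})

test_that("M/M/1 time-in-system matches the closed form within 5%", {
  pw <- constant_pathway(attending_eval = dist_spec("exponential", 8))
  prof <- arrival_profile(rep(6, 24), 0.8)  # lambda 0.1/min, mu 0.125/min
  res <- resource_config(1e6, 1e6, 1)
  log <- run_replication(pw, res, prof, 750, 20, seed = 2)
  expect_gt(nrow(log), 1e5)
  expect_lt(abs(mean(log$los) - 40) / 40, 0.05)  # W = 1/(mu - lambda)
})

test_that("utilization reports busy fractions with exact arithmetic", {
  pw <- constant_pathway(transfer_to_room = const_spec(10),
                         attending_eval = const_spec(20),
                         nurse_discharge = const_spec(10),
                         bed_cleaning = const_spec(20))
  prof <- arrival_profile(c(0.25, rep(0, 23)), 1)
  res <- resource_config(1, 5, 5)
  log <- run_replication(pw, res, prof, 40, 0, seed = 9)
  u <- utilization(log, res, 40)
  # each patient occupies the room transfer+eval+discharge+cleaning = 60 min
  expect_equal(unname(u["rooms"]), nrow(log) * 60 / (40 * 1440))
  expect_equal(unname(u["providers"]), nrow(log) * 20 / (5 * 40 * 1440))
  expect_error(utilization(empty <- run_replication(
    constant_pathway(), ample(), arrival_profile(rep(0, 24), 1), 2, 0, 1),
    res, 2), "empty")
})

test_that("a saturated single room approaches full occupancy", {
  pw <- constant_pathway(attending_eval = const_spec(120))
  prof <- arrival_profile(rep(2, 24), 0.8)
  res <- resource_config(1, 1e6, 1e6)
  log <- run_replication(pw, res, prof, 10, 0, seed = 8)
  u <- utilization(log, res, 10)
  expect_gt(u["rooms"], 0.95)
  expect_lte(u["rooms"], 1)
})

test_that("resident path routes through resident evaluation and review", {
  pw <- constant_pathway(resident_eval = const_spec(12),
                         attending_resident_review = const_spec(6),
                         attending_eval = const_spec(15))
  prof <- arrival_profile(c(0.5, rep(0, 23)), 1)
  res <- resource_config(1e6, 1e6, 1e6, n_residents = 1e6,
                         resident_fraction = 1)
  log <- run_replication(pw, res, prof, 20, 0, seed = 6)
  expect_equal(unique(log$los), 18)  # resident 12 + review 6, no attending eval
  res0 <- resource_config(1e6, 1e6, 1e6)
  log0 <- run_replication(pw, res0, prof, 20, 0, seed = 6)
  expect_equal(unique(log0$los), 15)  # attending path
  expect_error(resource_config(5, 2, 2, 0, 0.5), "resident_fraction")
})
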