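test_that("adjusted performance fraction follows the add-one/add-two shrinkage", {
  expect_equal(adjusted_performance_fraction(0, 0), 0.5)
  expect_equal(adjusted_performance_fraction(8, 8), 0.9)
  expect_equal(adjusted_performance_fraction(95, 100), 96 / 102)
  expect_error(adjusted_performance_fraction(5, 3), "exceed")
  expect_error(adjusted_performance_fraction(-1, 3), "nonnegative")
})

five_provider_table <- function() {
  data.frame(provider_id = c("A", "B", "C", "D", "E"), esi = 4L,
             n_visits = c(100, 10, 50, 200, 40),
             n_tested = c(5, 0, 10, 60, 2))
}

test_that("pared-mean benchmark selects top performers to 10% coverage", {
  b <- compute_abc(five_provider_table(), esi = 4)
  # APF ranking: A > E > B > C > D; A alone covers 100 of 400 visits
  expect_equal(names(b$apf_by_provider)[1:3], c("A", "E", "B"))
  expect_equal(unname(b$apf_by_provider["A"]), 96 / 102)
  expect_equal(b$selected_providers, "A")
  expect_equal(b$benchmark_rate, 0.05)
  expect_equal(b$coverage, 0.25)
})

test_that("degenerate and tie cases behave as documented", {
  one <- data.frame(provider_id = "X", esi = 4L, n_visits = 30, n_tested = 3)
  expect_equal(compute_abc(one, 4)$benchmark_rate, 0.10)
  same <- data.frame(provider_id = c("a", "b", "c"), esi = 4L,
                     n_visits = c(50, 50, 50), n_tested = c(10, 10, 10))
  expect_equal(compute_abc(same, 4)$benchmark_rate, 0.2)
  expect_error(compute_abc(five_provider_table(), esi = 5), "no providers")
  expect_error(compute_abc(five_provider_table(), 4, min_coverage = 0), "min_coverage")
  expect_error(compute_abc(five_provider_table(), 4, min_coverage = 1.5), "min_coverage")
})

test_that("compute_abc agrees with a brute-force pared-mean oracle", {
  set.seed(404)
  for (i in 1:1000) {
    tab <- random_provider_table(n = sample(2:12, 1))
    expect_equal(compute_abc(tab, 4)$benchmark_rate, abc_oracle(tab, 4),
                 tolerance = 1e-12)
  }
})

test_that("benchmark never exceeds the population rate on realistic panels", {
  for (s in 1:25) {
    tab <- gen_provider_table(cohort_spec(seed = s))
    for (e in c(4L, 5L)) {
      b <- compute_abc(tab, e)
      expect_lte(b$benchmark_rate, b$population_rate + 1e-12)
      expect_gte(b$coverage, 0.10)
    }
  }
})

test_that("adding a large zero-testing provider never raises the benchmark", {
  set.seed(505)
  for (i in 1:50) {
    tab <- random_provider_table(n = sample(3:10, 1))
    before <- compute_abc(tab, 4)$benchmark_rate
    tab2 <- rbind(tab, data.frame(provider_id = "ZZZ", esi = 4L,
                                  n_visits = 500, n_tested = 0))
    expect_lte(compute_abc(tab2, 4)$benchmark_rate, before + 1e-12)
  }
})

test_that("provider percentile rate uses the nearest-rank rule", {
  tab <- data.frame(provider_id = sprintf("p%02d", 1:11), esi = 4L,
                    n_visits = 10, n_tested = 0:10)
  expect_equal(provider_percentile_rate(tab, 4, 90), 0.9)
  expect_equal(provider_percentile_rate(tab, 4, 100), 1.0)
  expect_equal(provider_percentile_rate(tab, 4, 0), 0.0)
  one <- tab[3, ]
  expect_equal(provider_percentile_rate(one, 4, 10), 0.2)
  expect_equal(provider_percentile_rate(one, 4, 95), 0.2)
  expect_error(provider_percentile_rate(tab, 4, 101), "percentile")
})

test_that("provider tables round-trip through CSV and reject bad counts", {
  tab <- five_provider_table()
  path <- tempfile(fileext = ".csv")
  write_provider_csv(tab, path)
  back <- read_provider_csv(path)
  expect_equal(back$n_visits, tab$n_visits)
  expect_equal(back$provider_id, tab$provider_id)
  bad <- tab
  bad$n_tested[1] <- 999
  expect_error(write_provider_csv(bad, path), "n_tested")
})

test_that("benchmark results serialize to JSON", {
  b <- compute_abc(five_provider_table(), 4)
  path <- tempfile(fileext = ".json")
  write_benchmark_json(b, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$benchmark_rate, 0.05)
  expect_equal(j$esi, 4)
})
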