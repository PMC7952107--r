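#' Adjusted performance fraction
#'
#' The shrunken provider performance used to rank providers for the
#' Achievable Benchmark of Care: `(x + 1) / (d + 2)`, where `x` is the
#' provider's count of desirable events and `d` their number of eligible
#' visits. The add-one/add-two adjustment pulls small-denominator
#' providers toward 1/2, so a provider with 0/0 scores 0.5 and cannot
#' dominate the ranking on tiny volume.
#'
#' @param x_desirable Count(s) of desirable events, `0 <= x <= d`.
#' @param d_visits Eligible visit count(s).
#' @return Adjusted performance fraction(s) in (0, 1).
#' @examples
#' adjusted_performance_fraction(8, 8)     # 0.9
#' adjusted_performance_fraction(95, 100)  # 96/102
#' @export
adjusted_performance_fraction <- function(x_desirable, d_visits) {
  stopifnot(length(x_desirable) == length(d_visits))
  if (any(x_desirable < 0 | d_visits < 0))
    stop("counts must be nonnegative")
  if (any(x_desirable > d_visits))
    stop("desirable events cannot exceed visits")
  (x_desirable + 1) / (d_visits + 2)
}

validate_provider_table <- function(providers) {
  req <- c("provider_id", "esi", "n_visits", "n_tested")
  if (!is.data.frame(providers) || !all(req %in% names(providers)))
    stop("provider table needs columns: ", paste(req, collapse = ", "))
  if (any(providers$n_tested < 0 | providers$n_visits < 0 |
            providers$n_tested > providers$n_visits))
    stop("provider table requires 0 <= n_tested <= n_visits")
  invisible(providers)
}

#' Achievable Benchmark of Care for diagnostic-testing rates
#'
#' Computes the pared-mean benchmark testing rate from a provider-level
#' table. Diagnostic testing in low-acuity visits is overuse, so the
#' desirable event is a visit *without* testing: providers are ranked by
#' the [adjusted_performance_fraction()] of untested visits (descending,
#' ties broken by `provider_id`), the best performers are selected from
#' the top until they cover at least `min_coverage` of all visits, and
#' the benchmark is the complement of their aggregate untested rate,
#' i.e. the testing rate actually achieved by the benchmark providers.
#'
#' @param providers Data frame with columns `provider_id`, `esi`,
#'   `n_visits`, `n_tested` (one row per provider per ESI level).
#' @param esi ESI level (4 or 5) to benchmark.
#' @param min_coverage Minimum fraction of total visits the selected
#'   providers must cover, in (0, 1\] (default 0.10, the pared-mean
#'   convention).
#' @param min_visits Providers with fewer visits are excluded before
#'   ranking (default 0: include everyone; the APF shrinkage already
#'   guards small denominators).
#' @return An object of class `benchmark_result`: list with `esi`,
#'   `benchmark_rate`, `selected_providers` (ids in rank order),
#'   `apf_by_provider` (named, rank order), `coverage` (fraction of
#'   visits represented by the selection), `population_rate` (the
#'   visit-weighted mean testing rate).
#' @examples
#' tab <- data.frame(provider_id = c("A", "B", "C", "D", "E"), esi = 4,
#'                   n_visits = c(100, 10, 50, 200, 40),
#'                   n_tested = c(5, 0, 10, 60, 2))
#' compute_abc(tab, esi = 4)$benchmark_rate   # 0.05
#' @export
compute_abc <- function(providers, esi, min_coverage = 0.10,
                        min_visits = 0) {
  validate_provider_table(providers)
  if (!(min_coverage > 0 && min_coverage <= 1))
    stop("min_coverage must be in (0, 1]")
  sub <- providers[providers$esi == esi & providers$n_visits > 0 &
                     providers$n_visits >= min_visits, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no providers with visits for ESI ", esi)
  desirable <- sub$n_visits - sub$n_tested
  apf <- adjusted_performance_fraction(desirable, sub$n_visits)
  ord <- order(-apf, as.character(sub$provider_id))
  sub <- sub[ord, , drop = FALSE]
  apf <- apf[ord]
  desirable <- desirable[ord]
  total <- sum(sub$n_visits)
  cum <- cumsum(sub$n_visits)
  k <- which(cum >= min_coverage * total)[1L]
  sel <- seq_len(k)
  structure(list(
    esi = esi,
    benchmark_rate = 1 - sum(desirable[sel]) / sum(sub$n_visits[sel]),
    selected_providers = as.character(sub$provider_id[sel]),
    apf_by_provider = stats::setNames(apf, sub$provider_id),
    coverage = cum[k] / total,
    population_rate = sum(sub$n_tested) / total
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> ESI %s: benchmark testing rate %.3f (population %.3f), %d provider(s) covering %.1f%% of visits\n",
    x$esi, x$benchmark_rate, x$population_rate,
    length(x$selected_providers), 100 * x$coverage))
  invisible(x)
}

#' Provider-level testing rate at a percentile
#'
#' The testing rate of the provider at the requested percentile of the
#' provider-level rate distribution (providers as units, unweighted by
#' visits), using the nearest-rank rule; percentile 100 is the
#' highest-testing provider. Used to define high-testing what-if
#' scenarios.
#'
#' @param providers Provider table as in [compute_abc()].
#' @param esi ESI level.
#' @param percentile Percentile in \[0, 100\].
#' @return The testing rate (proportion) at that percentile.
#' @export
provider_percentile_rate <- function(providers, esi, percentile) {
  validate_provider_table(providers)
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  sub <- providers[providers$esi == esi & providers$n_visits > 0, ,
                   drop = FALSE]
  if (nrow(sub) == 0L) stop("no providers with visits for ESI ", esi)
  rates <- sort(sub$n_tested / sub$n_visits)
  r <- max(1L, ceiling(percentile / 100 * length(rates)))
  rates[r]
}

#' Read or write a provider testing table as CSV
#'
#' @param providers Provider table (`provider_id`, `esi`, `n_visits`,
#'   `n_tested`).
#' @param path File path.
#' @return `write_provider_csv` returns `path` invisibly;
#'   `read_provider_csv` returns the validated table.
#' @export
write_provider_csv <- function(providers, path) {
  validate_provider_table(providers)
  utils::write.csv(providers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_provider_csv
#' @export
read_provider_csv <- function(path) {
  validate_provider_table(utils::read.csv(path,
                                          colClasses = c(provider_id = "character")))
}

#' Serialize a benchmark result as JSON
#'
#' @param result A `benchmark_result` from [compute_abc()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_benchmark_json <- function(result, path) {
  stopifnot(inherits(result, "benchmark_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
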