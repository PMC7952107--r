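# Shared fixture builders for the test suite (all data generated in code).

const_spec <- function(v) dist_spec("constant", v)

# Pathway with every process a constant, overridable by name.
constant_pathway <- function(..., p_test_esi4 = 0, p_test_esi5 = 0) {
  over <- list(...)
  specs <- stats::setNames(
    lapply(edflow:::PROCESS_NAMES, function(nm) {
      if (nm %in% names(over)) over[[nm]] else const_spec(0)
    }),
    edflow:::PROCESS_NAMES)
  pathway_config(specs, p_test_esi4, p_test_esi5)
}

ample <- function() resource_config(1e6, 1e6, 1e6)

# The eleven published process-duration specs, named, for parameterised
# distribution tests.
table_specs <- function() default_pathway()$specs

# Small random provider table for ABC property tests.
random_provider_table <- function(n, esi = 4L, max_visits = 60) {
  visits <- sample.int(max_visits, n, replace = TRUE)
  data.frame(provider_id = sprintf("R%03d", seq_len(n)), esi = esi,
             n_visits = visits,
             n_tested = vapply(visits, function(v) sample.int(v + 1L, 1L) - 1L,
                               integer(1)))
}

# Independent pared-mean oracle: plain sort + cumulative scan, written
# directly from the benchmark definition.
abc_oracle <- function(tab, esi, min_coverage = 0.10) {
  tab <- tab[tab$esi == esi & tab$n_visits > 0, ]
  good <- tab$n_visits - tab$n_tested
  apf <- (good + 1) / (tab$n_visits + 2)
  o <- order(-apf, as.character(tab$provider_id))
  v <- tab$n_visits[o]
  g <- good[o]
  need <- min_coverage * sum(v)
  tot_v <- 0
  tot_g <- 0
  for (i in seq_along(v)) {
    tot_v <- tot_v + v[i]
    tot_g <- tot_g + g[i]
    if (tot_v >= need) break
  }
  1 - tot_g / tot_v
}
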