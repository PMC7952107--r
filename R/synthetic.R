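#' Specification for a synthetic low-acuity cohort
#'
#' Parameters of the synthetic stand-in for the institutional
#' administrative extracts: a provider panel with right-skewed testing
#' rates (about a 10-fold spread between the 90th and 10th percentile
#' provider), annual low-acuity visit volumes, and monthly administrative
#' LOS/wait summaries. Defaults reproduce the published setting: 30
#' providers, mean testing rates 22.5% (ESI 4) and 11.9% (ESI 5), a
#' 10-fold rate spread, 35,838 ESI-4 and 9,124 ESI-5 annual visits, and
#' fiscal-year monthly summaries with means 169.8/136.4 min LOS and
#' 76.4/73.6 min wait (SDs 21.4/27.8 and 22.0/25.1) over 12 months.
#'
#' @param n_providers Number of providers.
#' @param mean_rate_esi4,mean_rate_esi5 Target visit-weighted mean
#'   testing rates, in (0, 1).
#' @param spread_factor Target ratio of the 90th- to 10th-percentile
#'   provider testing rate (>= 1).
#' @param annual_visits_esi4,annual_visits_esi5 Annual visit totals.
#' @param admin_mean_los,admin_sd_los,admin_mean_wait,admin_sd_wait
#'   Length-2 numeric vectors (ESI 4, ESI 5): monthly administrative
#'   means and SDs in minutes.
#' @param n_months Number of administrative months (>= 2).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_providers = 30,
                        mean_rate_esi4 = 0.225, mean_rate_esi5 = 0.119,
                        spread_factor = 10,
                        annual_visits_esi4 = 35838,
                        annual_visits_esi5 = 9124,
                        admin_mean_los = c(169.8, 136.4),
                        admin_sd_los = c(21.4, 27.8),
                        admin_mean_wait = c(76.4, 73.6),
                        admin_sd_wait = c(22.0, 25.1),
                        n_months = 12, seed = 1L) {
  stopifnot(n_providers >= 1,
            mean_rate_esi4 > 0, mean_rate_esi4 < 1,
            mean_rate_esi5 > 0, mean_rate_esi5 < 1,
            spread_factor >= 1,
            annual_visits_esi4 > 0, annual_visits_esi5 > 0,
            length(admin_mean_los) == 2, length(admin_sd_los) == 2,
            length(admin_mean_wait) == 2, length(admin_sd_wait) == 2,
            all(admin_sd_los >= 0), all(admin_sd_wait >= 0),
            n_months >= 2)
  structure(as.list(environment()), class = "cohort_spec")
}

# Largest-remainder rounding of shares * total to integers summing to total.
allocate_integer <- function(shares, total) {
  raw <- shares / sum(shares) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Symmetric Dirichlet(alpha) draw via normalized gammas.
rdirichlet_sym <- function(n, alpha = 2) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic provider testing table
#'
#' Draws per-provider testing rates from a lognormal on the rate scale
#' with its log-sd set so the population 90th/10th-percentile ratio
#' equals `spread_factor` (rates above 1 are redrawn), rescales the draws
#' so the realized visit-weighted mean matches the target mean rate,
#' allocates annual visits across providers by a symmetric Dirichlet, and
#' draws tested counts as Binomial(visits, rate). With
#' `spread_factor = 1` all providers share the mean rate and differ only
#' by binomial noise. Visit totals are conserved exactly.
#'
#' @param spec A [cohort_spec()].
#' @return Provider table data frame (`provider_id`, `esi`, `n_visits`,
#'   `n_tested`), two rows per provider.
#' @export
gen_provider_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  sigma <- log(spec$spread_factor) /
    (stats::qnorm(0.9) - stats::qnorm(0.1))
  ids <- sprintf("P%02d", seq_len(spec$n_providers))
  one_esi <- function(esi, mean_rate, total_visits) {
    if (mean_rate * spec$spread_factor / sqrt(spec$spread_factor) >= 1)
      stop("mean_rate ", mean_rate, " with spread_factor ",
           spec$spread_factor, " pushes top-decile rates past 1")
    mu <- log(mean_rate) - sigma^2 / 2
    rates <- stats::rlnorm(spec$n_providers, mu, sigma)
    for (i in seq_len(100)) {
      bad <- rates >= 1
      if (!any(bad)) break
      rates[bad] <- stats::rlnorm(sum(bad), mu, sigma)
    }
    if (any(rates >= 1))
      stop("could not draw provider rates inside (0, 1); ",
           "mean_rate/spread_factor combination is infeasible")
    shares <- rdirichlet_sym(spec$n_providers)
    visits <- allocate_integer(shares, total_visits)
    w <- visits / sum(visits)
    adj <- mean_rate / sum(w * rates)
    rates <- pmin(rates * adj, 0.999)
    data.frame(provider_id = ids, esi = esi, n_visits = visits,
               n_tested = stats::rbinom(spec$n_providers, visits, rates))
  }
  rbind(one_esi(4L, spec$mean_rate_esi4, spec$annual_visits_esi4),
        one_esi(5L, spec$mean_rate_esi5, spec$annual_visits_esi5))
}

#' Generate synthetic monthly administrative summaries
#'
#' Emulates the monthly administrative comparison surface: for each month
#' and ESI level, mean LOS and wait are drawn
#' Normal(admin mean, admin sd). With sd = 0 every month equals the mean.
#' The result is the arm-B input for validation-style pooled-t
#' comparisons with `n = n_months`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `month`, `esi`, `mean_los`,
#'   `mean_wait`.
#' @export
gen_admin_monthly <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed + 1L)
  m <- spec$n_months
  out <- lapply(1:2, function(i) {
    data.frame(month = seq_len(m), esi = c(4L, 5L)[i],
               mean_los = stats::rnorm(m, spec$admin_mean_los[i],
                                       spec$admin_sd_los[i]),
               mean_wait = stats::rnorm(m, spec$admin_mean_wait[i],
                                        spec$admin_sd_wait[i]))
  })
  do.call(rbind, out)
}

#' Write a complete synthetic demo dataset
#'
#' Writes the provider testing table and monthly administrative summary
#' CSVs for a cohort spec into a directory, the same dialects consumed by
#' [compute_abc()] and the comparison machinery.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(spec = cohort_spec(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  provider_path <- file.path(dir, "providers.csv")
  admin_path <- file.path(dir, "admin_monthly.csv")
  write_provider_csv(gen_provider_table(spec), provider_path)
  utils::write.csv(gen_admin_monthly(spec), admin_path,
                   row.names = FALSE)
  invisible(c(providers = provider_path, admin = admin_path))
}
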