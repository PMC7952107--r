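#' Write or read a full model configuration as YAML
#'
#' Serializes the pathway (each service distribution as
#' `{family, params, shift, scale_mult}` plus testing proportions and the
#' `pathway_variant` routing flag), the resource counts, and the arrival
#' profile (24 hourly rates in patients/hour and the ESI-4 fraction) into
#' one structured text file; all times are minutes. `read_model_config()`
#' reconstructs the three configuration objects and round-trips exactly.
#'
#' @param pathway A [pathway_config()].
#' @param resources A [resource_config()].
#' @param profile An [arrival_profile()].
#' @param path File path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a list with elements `pathway`,
#'   `resources`, `profile`.
#' @export
write_model_config <- function(pathway, resources, profile, path) {
  stopifnot(inherits(pathway, "pathway_config"),
            inherits(resources, "resource_config"),
            inherits(profile, "arrival_profile"))
  cfg <- list(
    pathway = c(
      list(p_test_esi4 = pathway$p_test_esi4,
           p_test_esi5 = pathway$p_test_esi5,
           pathway_variant = pathway$pathway_variant),
      list(processes = lapply(pathway$specs, function(s)
        list(family = s$family, params = as.numeric(s$params),
             shift = s$shift, scale_mult = s$scale_mult)))
    ),
    resources = unclass(resources),
    profile = list(hourly_rates = profile$hourly_rates,
                   esi4_fraction = profile$esi4_fraction)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$pathway$processes, function(s)
    dist_spec(s$family, as.numeric(s$params), s$shift, s$scale_mult))
  list(
    pathway = pathway_config(specs, cfg$pathway$p_test_esi4,
                             cfg$pathway$p_test_esi5,
                             cfg$pathway$pathway_variant),
    resources = resource_config(cfg$resources$n_rooms,
                                cfg$resources$n_nurses,
                                cfg$resources$n_providers,
                                cfg$resources$n_residents,
                                cfg$resources$resident_fraction),
    profile = arrival_profile(as.numeric(cfg$profile$hourly_rates),
                              cfg$profile$esi4_fraction)
  )
}

#' Write or read a visit log as CSV
#'
#' One row per patient in the documented column order, times in minutes
#' to 3 decimals. `read_visit_log()` restores the `visit_log` class and
#' round-trips a written log exactly (at the 3-decimal precision).
#'
#' @param log A `visit_log` from [run_replication()].
#' @param path File path.
#' @return `write_visit_log` returns `path` invisibly; `read_visit_log`
#'   returns the `visit_log`.
#' @export
write_visit_log <- function(log, path) {
  stopifnot(inherits(log, "visit_log"))
  out <- as.data.frame(log)
  num <- vapply(out, is.numeric, TRUE) & names(out) != "patient_id" &
    names(out) != "esi"
  out[num] <- lapply(out[num], function(x) round(x, 3))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visit_log
#' @export
read_visit_log <- function(path) {
  log <- utils::read.csv(path)
  log$tested <- as.logical(log$tested)
  class(log) <- c("visit_log", "data.frame")
  log
}
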