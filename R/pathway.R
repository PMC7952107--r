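PROCESS_NAMES <- c("nurse_screening", "vitals", "transfer_to_room",
                   "attending_eval", "resident_eval",
                   "attending_resident_review", "attending_reassessment",
                   "testing_treatment_esi4", "testing_treatment_esi5",
                   "nurse_discharge", "bed_cleaning")

#' Pathway configuration: service distributions and testing proportions
#'
#' Bundles one [dist_spec()] per patient-flow process with the fixed
#' per-ESI probability that a visit includes diagnostic testing. Untested
#' patients skip the testing/treatment delay and the attending
#' reassessment and go straight to nurse discharge after evaluation.
#'
#' @param specs Named list holding one [dist_spec()] for each of:
#'   `nurse_screening`, `vitals`, `transfer_to_room`, `attending_eval`,
#'   `resident_eval`, `attending_resident_review`,
#'   `attending_reassessment`, `testing_treatment_esi4`,
#'   `testing_treatment_esi5`, `nurse_discharge`, `bed_cleaning`.
#' @param p_test_esi4,p_test_esi5 Probability that an ESI-4 (ESI-5) visit
#'   includes diagnostic testing, in \[0, 1\].
#' @param pathway_variant Routing variant label; only
#'   `"screen_vitals_then_room"` (triage screening and vitals before
#'   rooming) is implemented.
#' @return An object of class `pathway_config`.
#' @seealso [default_pathway()]
#' @export
pathway_config <- function(specs, p_test_esi4, p_test_esi5,
                           pathway_variant = "screen_vitals_then_room") {
  stopifnot(is.list(specs))
  missing <- setdiff(PROCESS_NAMES, names(specs))
  if (length(missing))
    stop("missing process spec(s): ", paste(missing, collapse = ", "))
  for (nm in PROCESS_NAMES) {
    if (!inherits(specs[[nm]], "dist_spec"))
      stop("specs$", nm, " is not a dist_spec")
  }
  for (p in c(p_test_esi4, p_test_esi5)) {
    stopifnot(length(p) == 1L, is.finite(p), p >= 0, p <= 1)
  }
  pathway_variant <- match.arg(pathway_variant)
  structure(list(specs = specs[PROCESS_NAMES],
                 p_test_esi4 = p_test_esi4, p_test_esi5 = p_test_esi5,
                 pathway_variant = pathway_variant),
            class = "pathway_config")
}

#' Default pathway: published pediatric-ED process-duration distributions
#'
#' The service-time distributions fitted for a large, urban, academic
#' pediatric ED low-acuity track (minutes): Gamma triage screening,
#' shifted-Gamma vitals, Triangular(5, 10, 12) transfer-to-room,
#' range-expanded Beta provider evaluations, shifted Weibull/exponential
#' review and reassessment, long right-skewed testing-and-treatment delays
#' (shifted Gamma for ESI 4, shifted Weibull for ESI 5),
#' Triangular(5, 10, 15) nurse discharge and shifted-lognormal bed
#' cleaning. Default testing proportions are the current local rates,
#' 22.5% of ESI-4 and 11.9% of ESI-5 visits.
#'
#' @param p_test_esi4,p_test_esi5 Testing proportions per ESI.
#' @return A [pathway_config()].
#' @export
default_pathway <- function(p_test_esi4 = 0.225, p_test_esi5 = 0.119) {
  specs <- list(
    nurse_screening = dist_spec("gamma", c(0.567, 4.9)),
    vitals = dist_spec("gamma", c(1.58, 1.51), shift = 1),
    transfer_to_room = dist_spec("triangular", c(5, 10, 12)),
    attending_eval = dist_spec("beta", c(0.726, 1.08),
                               shift = 2, scale_mult = 28),
    resident_eval = dist_spec("beta", c(1.11, 1.04),
                              shift = 2, scale_mult = 28),
    attending_resident_review = dist_spec("weibull", c(6.4, 1.27),
                                          shift = -0.001),
    attending_reassessment = dist_spec("exponential", 3.88,
                                       shift = -0.001),
    testing_treatment_esi4 = dist_spec("gamma", c(136, 0.874), shift = 5),
    testing_treatment_esi5 = dist_spec("weibull", c(45.1, 0.701),
                                       shift = 5),
    nurse_discharge = dist_spec("triangular", c(5, 10, 15)),
    bed_cleaning = dist_spec("lognormal", c(17.4, 16.2), shift = 2)
  )
  pathway_config(specs, p_test_esi4, p_test_esi5)
}

#' Resource configuration
#'
#' Counts of the contended resources in the low-acuity track: treatment
#' rooms (held from room transfer until bed cleaning completes), nurses
#' (triage screening + vitals, and the discharge process) and providers
#' (evaluation, resident review, and post-testing reassessment).
#' Residents, when staffed, perform the initial evaluation on a
#' `resident_fraction` share of visits, followed by an attending review.
#'
#' @param n_rooms,n_nurses,n_providers Positive integer counts.
#' @param n_residents Nonnegative integer count (default 0: the track is
#'   staffed by attendings/NPs/PAs only).
#' @param resident_fraction Proportion of visits first seen by a resident;
#'   must be 0 when `n_residents` is 0.
#' @return An object of class `resource_config`.
#' @export
resource_config <- function(n_rooms, n_nurses, n_providers,
                            n_residents = 0, resident_fraction = 0) {
  for (v in c(n_rooms, n_nurses, n_providers)) {
    stopifnot(length(v) == 1L, is.finite(v), v >= 1, v == as.integer(v))
  }
  stopifnot(n_residents >= 0, n_residents == as.integer(n_residents),
            resident_fraction >= 0, resident_fraction <= 1)
  if (n_residents == 0 && resident_fraction > 0)
    stop("resident_fraction must be 0 when n_residents is 0")
  structure(list(n_rooms = as.integer(n_rooms),
                 n_nurses = as.integer(n_nurses),
                 n_providers = as.integer(n_providers),
                 n_residents = as.integer(n_residents),
                 resident_fraction = resident_fraction),
            class = "resource_config")
}

#' @export
print.resource_config <- function(x, ...) {
  cat(sprintf(
    "<resource_config> rooms %d, nurses %d, providers %d, residents %d (fraction %.2f)\n",
    x$n_rooms, x$n_nurses, x$n_providers, x$n_residents,
    x$resident_fraction))
  invisible(x)
}
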