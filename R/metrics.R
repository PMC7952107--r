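#' Per-ESI outcome summary of a visit log
#'
#' Computes the two outcome measures per ESI level: mean length of stay
#' (arrival to disposition) and mean wait (arrival to the start of
#' provider evaluation), with the patient count. ESI levels with no
#' patients are reported with `n = 0` and `NA` means.
#'
#' @param log A `visit_log` from [run_replication()] (or any data frame
#'   with numeric `esi`, `los`, `wait` columns).
#' @param rep_id Optional replication identifier carried into the result.
#' @return A data frame with one row per ESI level (4 and 5): `rep_id`,
#'   `esi`, `n`, `mean_los`, `mean_wait`.
#' @export
summarize_visits <- function(log, rep_id = NA_integer_) {
  req <- c("esi", "los", "wait")
  if (!all(req %in% names(log)))
    stop("visit log must have columns: ", paste(req, collapse = ", "))
  bad <- !is.finite(log$los) | !is.finite(log$wait) | log$los < 0 |
    log$wait < 0 | log$wait > log$los | !(log$esi %in% c(4L, 5L))
  if (any(bad))
    stop("malformed visit-log rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "")
  out <- lapply(c(4L, 5L), function(e) {
    sub <- log[log$esi == e, , drop = FALSE]
    data.frame(rep_id = rep_id, esi = e, n = nrow(sub),
               mean_los = if (nrow(sub)) mean(sub$los) else NA_real_,
               mean_wait = if (nrow(sub)) mean(sub$wait) else NA_real_)
  })
  do.call(rbind, out)
}

#' Two-sample pooled-variance t interval from summary statistics
#'
#' Difference of means `mean_a - mean_b` with a `level` confidence
#' interval using the pooled-variance two-sample t construction:
#' \deqn{s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}, \quad
#'   d \pm t_{n_a+n_b-2,\,(1+level)/2}\; s_p \sqrt{1/n_a + 1/n_b}.}
#' This is the interval construction that reproduces published
#' replication-versus-replication (5 vs 5) and replication-versus-
#' monthly-administrative (5 vs 12) ED comparisons; internal arithmetic
#' is unrounded, display rounding is the caller's concern (see
#' [round_display()]).
#'
#' @param mean_a,sd_a,n_a Mean, SD and size of arm A.
#' @param mean_b,sd_b,n_b Mean, SD and size of arm B.
#' @param level Confidence level (default 0.95).
#' @param metric,esi Optional labels carried into the result.
#' @return An object of class `comparison_result`: a one-row data frame
#'   with `metric`, `esi`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `difference`, `ci_low`, `ci_high`, `level`.
#' @examples
#' pooled_t_ci(156.8, 6.2, 5, 137.7, 2.4, 5)   # 19.1 (12.2, 26.0)
#' @export
pooled_t_ci <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                        level = 0.95, metric = NA_character_,
                        esi = NA_integer_) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0,
            level > 0, level < 1)
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  se <- sp * sqrt(1 / n_a + 1 / n_b)
  d <- mean_a - mean_b
  half <- stats::qt((1 + level) / 2, df) * se
  out <- data.frame(metric = metric, esi = esi,
                    mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                    mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                    difference = d, ci_low = d - half, ci_high = d + half,
                    level = level)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Display rounding, half away from zero
#'
#' Rounds to `digits` decimals with halves away from zero (the rounding
#' used in printed clinical tables), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_display <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Total patient-hours for a per-patient difference
#'
#' Converts a per-patient difference in minutes into the total hours a
#' patient population would collectively gain (or lose) over a period:
#' `n * difference / 60`, rounded to the nearest whole hour.
#'
#' @param n_patients Number of patients (>= 0).
#' @param per_patient_difference_min Per-patient difference in minutes.
#' @return Whole hours (numeric).
#' @examples
#' total_patient_hours(9124, 10.9)   # 1658
#' @export
total_patient_hours <- function(n_patients, per_patient_difference_min) {
  stopifnot(n_patients >= 0)
  round_display(n_patients * per_patient_difference_min / 60, digits = 0)
}

#' Is a length-of-stay reduction clinically impactful?
#'
#' A reduction of at least `threshold_min` minutes (default 15, roughly
#' 10% of a typical low-acuity length of stay) is flagged as clinically
#' impactful; the boundary is inclusive.
#'
#' @param difference_min Mean LOS reduction in minutes.
#' @param threshold_min Impact threshold in minutes (default 15).
#' @return Logical.
#' @export
clinical_impact_flag <- function(difference_min, threshold_min = 15) {
  difference_min >= threshold_min
}

#' Write or read a comparison table as CSV
#'
#' Comparison tables mirror the published layout: one row per ESI and
#' metric with both arms' summary statistics, the difference and its CI.
#'
#' @param comparisons A data frame of stacked `comparison_result` rows.
#' @param path File path.
#' @return `write_comparison_csv` returns `path` invisibly;
#'   `read_comparison_csv` returns the data frame.
#' @export
write_comparison_csv <- function(comparisons, path) {
  utils::write.csv(as.data.frame(comparisons), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  utils::read.csv(path)
}
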