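# Synthetic cohort result tables: paired baseline/follow-up draws with a
# stated within-subject correlation and group effects, feeding the cohort
# statistics and their calibration tests.

#' Specification of a synthetic cohort
#'
#' Each measurement is defined per group by a baseline mean/SD, a follow-up
#' effect (shift in baseline-SD units applied at FU), and is drawn as a
#' correlated bivariate Gaussian pair per subject. Defaults mirror the study
#' design this pipeline targets: 7 operated (OP) and 13 non-operated (NOP)
#' subjects, baseline and follow-up visits.
#'
#' @param n_OP,n_NOP group sizes
#' @param measurements named list; each element a list with `location`
#'   (result-table location label), `units`, and per-group `mean`, `sd`
#'   (named vectors with entries OP and NOP) plus `fu_effect_sd` (named
#'   vector, follow-up shift in SD units; 0 = null)
#' @param correlation within-subject B-FU correlation in `[0, 1)`
#' @param seed RNG seed
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_OP = 7, n_NOP = 13,
                        measurements = default_cohort_measurements(),
                        correlation = 0.6, seed = 1L) {
  stopifnot(correlation >= 0, correlation < 1)
  for (m in measurements) stopifnot(all(m$sd > 0))
  structure(list(n_OP = n_OP, n_NOP = n_NOP, measurements = measurements,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic measurement set (null effects)
#' @return named list of measurement definitions
#' @export
default_cohort_measurements <- function() {
  list(
    wss_outer_ascending = list(
      location = "outer_ascending", units = "N/m^2",
      mean = c(OP = 0.7, NOP = 0.6), sd = c(OP = 0.2, NOP = 0.2),
      fu_effect_sd = c(OP = 0, NOP = 0)),
    forward_flow_ascending = list(
      location = "P4", units = "mL",
      mean = c(OP = 55, NOP = 69), sd = c(OP = 10, NOP = 14),
      fu_effect_sd = c(OP = 0, NOP = 0)))
}

#' Generate a synthetic cohort result table
#'
#' Per subject and measurement, (B, FU) values are drawn from a bivariate
#' Gaussian with the group's mean/SD, the stated within-subject correlation,
#' and the follow-up effect added as a multiple of the baseline SD. The
#' output is a standard result table (one row per subject x timepoint x
#' measurement), fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()]
#' @return result-table data.frame (see [result_rows()])
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(spec$n_OP + spec$n_NOP)),
    group = c(rep("OP", spec$n_OP), rep("NOP", spec$n_NOP)))
  rho <- spec$correlation
  rows <- list()
  for (mn in names(spec$measurements)) {
    m <- spec$measurements[[mn]]
    for (i in seq_len(nrow(subjects))) {
      g <- subjects$group[i]
      z1 <- stats::rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
      bval <- m$mean[[g]] + m$sd[[g]] * z1
      fval <- m$mean[[g]] + m$sd[[g]] * z2 + m$fu_effect_sd[[g]] * m$sd[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects$subject_id[i],
        timepoint = c("B", "FU"), group = g, measurement_name = mn,
        location_label = m$location, value = c(bval, fval),
        units = m$units, qc_flag = "INCLUDED")
    }
  }
  validate_result_table(do.call(rbind, rows))
}
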