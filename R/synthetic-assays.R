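# Simulators for the validation-stage assays: serial-dilution
# concentration-response, flow-cytometry event samples, and qPCR Ct
# quadruples. All are parameterised by the quantity the matching estimator
# is supposed to recover, so zero-noise round-trips are exact.

#' Four-parameter logistic response
#'
#' `bottom + (top - bottom) / (1 + (ec50 / x)^hill)`: the standard sigmoidal
#' concentration-response model, increasing in `x` for `hill > 0`.
#'
#' @param x Concentration(s), same units as `ec50`; must be positive.
#' @param bottom,top Lower/upper asymptote (response units, here percent
#'   activity).
#' @param ec50 Concentration of half-maximal response.
#' @param hill Hill slope.
#' @return Response value(s).
#' @export
logistic4 <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Simulate a serial-dilution concentration-response series
#'
#' Activity follows a four-parameter logistic curve plus Gaussian noise.
#' Dilutions above a cytotoxicity threshold get their cell counts depressed
#' and their activity emitted as missing, emulating instruments that report
#' no intensity for heavily cytotoxic wells.
#'
#' @param true_fit Named list or vector with `bottom`, `top`, `ec50`, `hill`.
#' @param concentrations Positive, strictly decreasing concentrations
#'   (mg/mL), e.g. from [serial_dilution()].
#' @param noise_sd Gaussian noise SD on the activity scale (percent points).
#' @param cytotoxic_above Concentration above which dilutions are cytotoxic,
#'   or `NULL` for none.
#' @param seed Integer seed.
#' @param cells_mean,cells_sd Healthy per-well cell count distribution.
#' @param kill_fraction Fraction of cells lost in cytotoxic dilutions.
#' @return Data frame: `concentration`, `activity` (`NA` where cytotoxic),
#'   `cell_count`, `cytotoxic_true`.
#' @export
simulate_dose_series <- function(true_fit, concentrations, noise_sd = 0,
                                 cytotoxic_above = NULL, seed = 1,
                                 cells_mean = 3500, cells_sd = 500,
                                 kill_fraction = 0.8) {
  fit <- as.list(true_fit)
  stopifnot(all(c("bottom", "top", "ec50", "hill") %in% names(fit)))
  if (!is.numeric(concentrations) || length(concentrations) == 0 ||
    any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop_hcs("hcs_domain_error", "concentrations must be positive and finite")
  }
  if (length(concentrations) > 1 && any(diff(concentrations) >= 0)) {
    stop_hcs("hcs_domain_error", "concentrations must be strictly decreasing")
  }
  check_scalar(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    n <- length(concentrations)
    activity <- logistic4(concentrations, fit$bottom, fit$top, fit$ec50, fit$hill)
    if (noise_sd > 0) activity <- activity + stats::rnorm(n, 0, noise_sd)
    counts <- pmax(0L, as.integer(round(stats::rnorm(n, cells_mean, cells_sd))))
    tox <- if (is.null(cytotoxic_above)) rep(FALSE, n) else concentrations > cytotoxic_above
    counts[tox] <- as.integer(round((1 - kill_fraction) * counts[tox]))
    activity[tox] <- NA_real_
    data.frame(
      concentration = concentrations, activity = activity,
      cell_count = counts, cytotoxic_true = tox
    )
  })
}

#' Simulate a flow-cytometry event intensity sample
#'
#' @param n_events Number of events (>= 1).
#' @param mean,sd Intensity distribution parameters (`sd >= 0`).
#' @param seed Integer seed.
#' @return Numeric vector of event intensities, truncated at 0.
#' @export
simulate_flow <- function(n_events, mean, sd, seed = 1) {
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 1) {
    stop_hcs("hcs_domain_error", "n_events must be >= 1")
  }
  check_scalar(sd, "sd", min = 0)
  with_seed(seed, rnorm_pos(as.integer(n_events), mean, sd))
}

#' Simulate a qPCR Ct quadruple for a known relative quantification
#'
#' Produces the four cycle-threshold values (target/housekeeping gene under
#' treated/reference conditions) whose delta-delta-Ct equals
#' `-log2(true_rq)` exactly at zero noise, so [rq_ddct()] recovers
#' `true_rq`.
#'
#' @param true_rq Planted fold change relative to the reference condition
#'   (> 0).
#' @param ct_housekeeping Housekeeping-gene Ct in both conditions.
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise SD (cycles) added to each Ct.
#' @param target_ref_offset Ct offset of the target gene over the
#'   housekeeping gene in the reference condition (sets absolute Ct levels
#'   only; cancels in the delta-delta-Ct).
#' @return Named list: `ct_target_treated`, `ct_hk_treated`,
#'   `ct_target_ref`, `ct_hk_ref`.
#' @export
simulate_qpcr <- function(true_rq, ct_housekeeping = 20, seed = 1,
                          noise_sd = 0, target_ref_offset = 2) {
  if (!is.numeric(true_rq) || length(true_rq) != 1 || !is.finite(true_rq) || true_rq <= 0) {
    stop_hcs("hcs_domain_error", "true_rq must be > 0")
  }
  check_scalar(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    ct <- c(
      ct_target_treated = ct_housekeeping + target_ref_offset - log2(true_rq),
      ct_hk_treated = ct_housekeeping,
      ct_target_ref = ct_housekeeping + target_ref_offset,
      ct_hk_ref = ct_housekeeping
    )
    if (noise_sd > 0) ct <- ct + stats::rnorm(4, 0, noise_sd)
    as.list(ct)
  })
}
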