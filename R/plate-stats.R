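# Control-anchored plate normalisation and assay quality control.
#
# Screens of this kind are scored against on-plate controls: the negative
# (vehicle) control defines 0% activity, the positive (stimulated) control
# defines 100%, and the Z'-factor 1 - 3(sd_p + sd_n)/|mu_p - mu_n|
# summarises whether the window between the controls is wide enough,
# relative to their noise, for single-well hit calling.

#' Compute control statistics for a plate
#'
#' Sample means and SDs (n - 1 denominator) of the positive and negative
#' control wells' `avg_gfp`, plus mean/SD of the negative controls' cell
#' counts (the anchor of the viability band). Wells with missing `avg_gfp`
#' are excluded from the intensity statistics (their count still enters the
#' cell-count statistics).
#'
#' @param measurements Data frame with at least `role`, `avg_gfp`,
#'   `cell_count` (e.g. from [simulate_screen()] or [aggregate_well()]
#'   joined to a plate map).
#' @return Object of class `control_stats` with fields `mu_p`, `delta_p`,
#'   `mu_n`, `delta_n`, `n_pos`, `n_neg`, `cell_mu_n`, `cell_delta_n`.
#' @export
control_stats <- function(measurements) {
  need <- c("role", "avg_gfp", "cell_count")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    stop_hcs("hcs_input_error", "measurements must contain columns %s", paste(need, collapse = ", "))
  }
  pos <- measurements[measurements$role == "POS" & !is.na(measurements$avg_gfp), ]
  neg <- measurements[measurements$role == "NEG" & !is.na(measurements$avg_gfp), ]
  if (nrow(pos) < 2 || nrow(neg) < 2) {
    stop_hcs(
      "hcs_insufficient_controls_error",
      "need >= 2 usable wells per control role (got %d POS, %d NEG)", nrow(pos), nrow(neg)
    )
  }
  neg_counts <- measurements$cell_count[measurements$role == "NEG"]
  structure(
    list(
      mu_p = mean(pos$avg_gfp), delta_p = stats::sd(pos$avg_gfp),
      mu_n = mean(neg$avg_gfp), delta_n = stats::sd(neg$avg_gfp),
      n_pos = nrow(pos), n_neg = nrow(neg),
      cell_mu_n = mean(neg_counts), cell_delta_n = stats::sd(neg_counts)
    ),
    class = "control_stats"
  )
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf(
    "control_stats: POS %.4g +/- %.4g (n=%d), NEG %.4g +/- %.4g (n=%d)\n  NEG cells %.4g +/- %.4g; Z' = %.3f\n",
    x$mu_p, x$delta_p, x$n_pos, x$mu_n, x$delta_n, x$n_neg,
    x$cell_mu_n, x$cell_delta_n, z_prime(x)
  ))
  invisible(x)
}

#' Percent activity of a well on the control-anchored scale
#'
#' `100 * (x - mu_n) / (mu_p - mu_n)`: 0 at the negative-control mean, 100
#' at the positive-control mean, unclamped (values below 0 or above 100 are
#' legitimate).
#'
#' @param x Well-average reporter intensity (vectorised).
#' @param controls A [control_stats()] object.
#' @return Percent activity, same length as `x`.
#' @export
percent_activity <- function(x, controls) {
  stopifnot(inherits(controls, "control_stats"))
  if (controls$mu_p == controls$mu_n) {
    stop_hcs("hcs_degenerate_controls_error", "mu_p equals mu_n; percent activity undefined")
  }
  100 * (x - controls$mu_n) / (controls$mu_p - controls$mu_n)
}

#' Z'-factor assay quality metric
#'
#' `1 - 3 * (delta_p + delta_n) / |mu_p - mu_n|`. Always <= 1; values
#' around 0.5 and above indicate a screening window comfortably wider than
#' the control noise, negative values an unusable assay.
#'
#' @param controls A [control_stats()] object.
#' @return Z'-factor (unitless scalar).
#' @export
z_prime <- function(controls) {
  stopifnot(inherits(controls, "control_stats"))
  if (controls$mu_p == controls$mu_n) {
    stop_hcs("hcs_degenerate_controls_error", "mu_p equals mu_n; Z'-factor undefined")
  }
  1 - 3 * (controls$delta_p + controls$delta_n) / abs(controls$mu_p - controls$mu_n)
}

#' Plate quality-control report
#'
#' @param controls A [control_stats()] object.
#' @param z_min Minimal acceptable Z'-factor (default 0.4); the plate
#'   passes iff `z_prime >= z_min`.
#' @return List of class `plate_qc`: `pass`, `z_prime`, `z_min`, `controls`.
#' @export
plate_qc <- function(controls, z_min = 0.4) {
  z <- z_prime(controls)
  structure(
    list(pass = z >= z_min, z_prime = z, z_min = z_min, controls = controls),
    class = "plate_qc"
  )
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf(
    "plate_qc: %s (Z' = %.3f, threshold %.2f)\n",
    if (x$pass) "PASS" else "FAIL", x$z_prime, x$z_min
  ))
  invisible(x)
}

#' Score every extract well of a plate against its controls
#'
#' @param measurements Per-well data frame (columns `role`, `extract_id`,
#'   `well`, `avg_gfp`, `cell_count`, optionally `gfp_missing`).
#' @param controls A [control_stats()] object for the same plate.
#' @return Data frame of activity results, one row per extract well:
#'   `extract_id`, `well`, `percent_activity` (`NA` where GFP missing),
#'   `cell_count`, `gfp_missing`.
#' @export
score_activities <- function(measurements, controls) {
  ext <- measurements[measurements$role == "EXTRACT", , drop = FALSE]
  missing <- if ("gfp_missing" %in% names(ext)) {
    ext$gfp_missing | is.na(ext$avg_gfp)
  } else {
    is.na(ext$avg_gfp)
  }
  pa <- rep(NA_real_, nrow(ext))
  if (any(!missing)) pa[!missing] <- percent_activity(ext$avg_gfp[!missing], controls)
  out <- data.frame(
    extract_id = ext$extract_id, well = ext$well,
    percent_activity = pa, cell_count = ext$cell_count,
    gfp_missing = missing, stringsAsFactors = FALSE
  )
  if ("plate_id" %in% names(ext)) out <- cbind(plate_id = ext$plate_id, out)
  rownames(out) <- NULL
  out
}
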