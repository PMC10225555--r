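# Dual-criterion hit calling: a well is a hit when its percent activity
# strictly exceeds the activity threshold AND its cell count sits inside
# the viability band anchored on the negative-control cell density. The
# second criterion removes cytotoxic extracts whose apparent activity is an
# artefact of cell loss.

#' Viability band around the negative-control cell density
#'
#' The band is `cell_mu_n +/- k * cell_delta_n`. `sided = "both"` (the
#' primary-screen reading of "within one standard deviation") applies both
#' limits; `sided = "lower"` (the validation reading, "below the mean minus
#' one standard deviation is cytotoxic") applies only the floor.
#'
#' @param controls A [control_stats()] object (or any list with `cell_mu_n`,
#'   `cell_delta_n`).
#' @param k Band half-width in negative-control SD units (default 1, >= 0).
#' @param sided `"both"` or `"lower"`.
#' @return Object of class `viability_band`: `floor`, `ceiling` (`NA` when
#'   one-sided), `k`, `sided`.
#' @export
viability_band <- function(controls, k = 1, sided = c("both", "lower")) {
  sided <- match.arg(sided)
  if (!is.numeric(k) || length(k) != 1 || k < 0) {
    stop_hcs("hcs_domain_error", "k must be >= 0")
  }
  if (is.null(controls$cell_mu_n) || is.null(controls$cell_delta_n) ||
    is.na(controls$cell_delta_n)) {
    stop_hcs("hcs_input_error", "controls must provide cell_mu_n and cell_delta_n")
  }
  structure(
    list(
      floor = controls$cell_mu_n - k * controls$cell_delta_n,
      ceiling = if (sided == "both") controls$cell_mu_n + k * controls$cell_delta_n else NA_real_,
      k = k, sided = sided
    ),
    class = "viability_band"
  )
}

#' @export
print.viability_band <- function(x, ...) {
  cat(sprintf(
    "viability_band: floor %.4g%s (k = %g, %s-sided)\n",
    x$floor, if (is.na(x$ceiling)) "" else sprintf(", ceiling %.4g", x$ceiling),
    x$k, if (x$sided == "both") "two" else "one"
  ))
  invisible(x)
}

#' Call hits from activity results under the dual criterion
#'
#' A well is a hit iff its percent activity strictly exceeds
#' `activity_threshold`, its cell count is within the viability band
#' (boundary values kept), and its reporter intensity was not missing.
#' Order of the input is preserved; per-well failure reasons are reported.
#'
#' @param activities Activity-result data frame from [score_activities()]
#'   (columns `extract_id`, `percent_activity`, `cell_count`, `gfp_missing`).
#' @param band A [viability_band()].
#' @param activity_threshold Percent-activity threshold (default 40; strict
#'   `>`).
#' @return The input data frame plus `is_hit` (logical) and `fail_reasons`
#'   (comma-joined subset of `LOW_ACTIVITY`, `CYTOTOXIC`, `HIGH_COUNT`,
#'   `MISSING_GFP`; empty string for hits).
#' @export
call_hits <- function(activities, band, activity_threshold = 40) {
  stopifnot(inherits(band, "viability_band"))
  if (!is.data.frame(activities) || nrow(activities) == 0) {
    out <- activities
    out$is_hit <- logical(0)
    out$fail_reasons <- character(0)
    return(out)
  }
  missing <- activities$gfp_missing | is.na(activities$percent_activity)
  low_act <- !missing & activities$percent_activity <= activity_threshold
  cytotox <- activities$cell_count < band$floor
  high_ct <- !is.na(band$ceiling) & activities$cell_count > band$ceiling
  reasons <- mapply(function(m, l, c, h) {
    paste(c(
      if (m) "MISSING_GFP", if (l) "LOW_ACTIVITY",
      if (c) "CYTOTOXIC", if (h) "HIGH_COUNT"
    ), collapse = ",")
  }, missing, low_act, cytotox, high_ct)
  out <- activities
  out$is_hit <- !(missing | low_act | cytotox | high_ct)
  out$fail_reasons <- unname(reasons)
  out
}

#' Summarise a screen's hit calls, optionally against planted ground truth
#'
#' @param hit_calls Data frame from [call_hits()].
#' @param ground_truth Optional ground-truth data frame (columns
#'   `extract_id`, `is_hit`) as produced by [simulate_screen()].
#' @return List of class `screen_report`: `hits` (hit rows only, listing
#'   plate, well, cell number and percent activity), `n_tested`, `n_hits`,
#'   and, when truth is supplied, `confusion` (`tp`, `fp`, `fn`, `tn`) plus
#'   the identities of false positives/negatives.
#' @export
screen_report <- function(hit_calls, ground_truth = NULL) {
  hits <- hit_calls[isTRUE_vec(hit_calls$is_hit), , drop = FALSE]
  keep <- intersect(
    c("plate_id", "well", "extract_id", "cell_count", "percent_activity"),
    names(hits)
  )
  rep <- list(
    hits = hits[, keep, drop = FALSE],
    n_tested = nrow(hit_calls),
    n_hits = nrow(hits)
  )
  if (!is.null(ground_truth)) {
    truth <- ground_truth$is_hit[match(hit_calls$extract_id, ground_truth$extract_id)]
    called <- isTRUE_vec(hit_calls$is_hit)
    rep$confusion <- c(
      tp = sum(called & truth), fp = sum(called & !truth),
      fn = sum(!called & truth), tn = sum(!called & !truth)
    )
    rep$false_positives <- hit_calls$extract_id[called & !truth]
    rep$false_negatives <- hit_calls$extract_id[!called & truth]
  }
  structure(rep, class = "screen_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen_report: %d hits of %d wells tested\n", x$n_hits, x$n_tested))
  if (x$n_hits > 0) print(x$hits, row.names = FALSE)
  if (!is.null(x$confusion)) {
    cat(sprintf(
      "vs ground truth: TP=%d FP=%d FN=%d TN=%d\n",
      x$confusion["tp"], x$confusion["fp"], x$confusion["fn"], x$confusion["tn"]
    ))
  }
  invisible(x)
}
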