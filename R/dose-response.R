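# Serial-dilution validation: build dilution series, fit four-parameter
# logistic (4PL) concentration-response curves by least squares on
# log-concentration, and classify extracts as validated actives under the
# same dual activity/viability criterion as the primary screen.

#' Build a serial dilution series
#'
#' `concentrations[i] = start / factor^(i-1)`, strictly decreasing.
#'
#' @param start Starting concentration (mg/mL, > 0).
#' @param factor Dilution factor (> 1).
#' @param n_points Number of dilutions (>= 1).
#' @return Object of class `dilution_series`: `concentrations`,
#'   `dilution_factor`, `start`.
#' @export
#' @examples
#' serial_dilution(0.5, 3, 7)
serial_dilution <- function(start, factor, n_points) {
  check_scalar(start, "start", min = 0, strict_min = TRUE)
  check_scalar(factor, "factor", min = 1, strict_min = TRUE)
  check_scalar(n_points, "n_points", min = 1)
  structure(
    list(
      concentrations = start / factor^(seq_len(n_points) - 1),
      dilution_factor = factor, start = start
    ),
    class = "dilution_series"
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "dilution_series: %s mg/mL (factor %g)\n",
    paste(format_concentration(x$concentrations), collapse = ", "),
    x$dilution_factor
  ))
  invisible(x)
}

#' Format concentrations the way assay reports print them
#'
#' Two significant figures, three when the leading significant digit is 1
#' (the usual extra-digit convention), trailing zeros stripped. A 3-fold
#' series from 0.5 mg/mL formats as 0.5, 0.167, 0.056, 0.0185, 0.0062,
#' 0.0021, 0.00069.
#'
#' @param x Numeric concentrations.
#' @return Character vector.
#' @export
format_concentration <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) {
      return(as.character(v))
    }
    lead <- floor(abs(v) / 10^floor(log10(abs(v))))
    digits <- if (lead == 1) 3 else 2
    formatC(signif(v, digits), format = "fg", flag = "#", digits = digits) |>
      sub(pattern = "\\.?0*$", replacement = "") |>
      sub(pattern = "\\.$", replacement = "")
  }, character(1))
}

four_pl <- function(logx, bottom, top, lec50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (lec50 - logx)))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ec50/x)^hill)`
#' on log-concentration. Missing responses (e.g. cytotoxic dilutions whose
#' intensity was not reported) are excluded. Initialisation: `bottom` at the
#' minimum response, `top` at the maximum, `ec50` at the geometric
#' mid-concentration, `hill = 1`; bounds `ec50` within \[min conc / 10,
#' max conc * 10\] and `hill` within \[0.1, 10\].
#'
#' @param series A [serial_dilution()] object or numeric concentration
#'   vector (> 0).
#' @param responses Percent activity per dilution; `NA` allowed.
#' @return Object of class `dose_response_fit`: `bottom`, `top`, `ec50`,
#'   `hill`, `converged`, `degenerate`, `rss`, `n_used`.
#' @export
fit_sigmoid <- function(series, responses) {
  conc <- if (inherits(series, "dilution_series")) series$concentrations else series
  if (!is.numeric(conc) || any(conc <= 0, na.rm = TRUE)) {
    stop_hcs("hcs_domain_error", "concentrations must be positive")
  }
  if (length(conc) != length(responses)) {
    stop_hcs("hcs_input_error", "series and responses lengths differ")
  }
  ok <- !is.na(responses) & !is.na(conc)
  x <- conc[ok]
  y <- responses[ok]
  if (sum(ok) < 4 || length(unique(x)) < 4) {
    stop_hcs(
      "hcs_insufficient_data_error",
      "need >= 4 non-missing responses at >= 4 distinct concentrations (got %d)", sum(ok)
    )
  }
  logx <- log(x)
  if (diff(range(y)) == 0) { # flat data: 4PL unidentifiable, report the plateau
    return(structure(
      list(
        bottom = y[1], top = y[1], ec50 = exp(mean(range(logx))), hill = 1,
        converged = TRUE, degenerate = TRUE, rss = 0, n_used = length(y)
      ),
      class = "dose_response_fit"
    ))
  }
  lower <- c(bottom = min(y) - diff(range(y)), top = min(y) - diff(range(y)),
             lec50 = log(min(x) / 10), hill = 0.1)
  upper <- c(bottom = max(y) + diff(range(y)), top = max(y) + diff(range(y)),
             lec50 = log(max(x) * 10), hill = 10)
  start <- list(bottom = min(y), top = max(y), lec50 = mean(range(logx)), hill = 1)

  fit <- tryCatch(
    stats::nls(y ~ four_pl(logx, bottom, top, lec50, hill),
      start = start, lower = lower, upper = upper, algorithm = "port",
      control = stats::nls.control(maxiter = 500, tol = 1e-10, warnOnly = FALSE)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    converged <- TRUE
  } else {
    obj <- function(p) sum((y - four_pl(logx, p[1], p[2], p[3], p[4]))^2)
    op <- stats::optim(unlist(start), obj,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 1000, factr = 10)
    )
    p <- op$par
    rss <- op$value
    converged <- op$convergence == 0
  }
  structure(
    list(
      bottom = unname(p["bottom"]), top = unname(p["top"]),
      ec50 = exp(unname(p["lec50"])), hill = unname(p["hill"]),
      converged = converged, degenerate = FALSE, rss = rss, n_used = length(y)
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: bottom %.3g, top %.3g, EC50 %.4g, hill %.3g (%s, RSS %.3g, n=%d)\n",
    x$bottom, x$top, x$ec50, x$hill,
    if (x$degenerate) "degenerate" else if (x$converged) "converged" else "NOT converged",
    x$rss, x$n_used
  ))
  invisible(x)
}

#' Classify a dilution series as validated active or inactive
#'
#' Active iff at least one dilution is non-cytotoxic (cell count within the
#' band, `NA` activity excluded) with activity strictly above the
#' threshold. The best dilution is the qualifying one with maximal
#' activity; ties are broken toward the lower concentration.
#'
#' @param points Data frame with `concentration`, `activity`, `cell_count`
#'   (e.g. from [simulate_dose_series()]).
#' @param band A [viability_band()] (typically one-sided for validation).
#' @param activity_threshold Percent threshold (default 40, strict `>`).
#' @return List of class `validation_call`: `is_active`,
#'   `best_concentration`, `best_activity` (both `NA` when inactive).
#' @export
classify_validated <- function(points, band, activity_threshold = 40) {
  stopifnot(inherits(band, "viability_band"))
  if (nrow(points) == 0) {
    return(structure(
      list(is_active = FALSE, best_concentration = NA_real_, best_activity = NA_real_),
      class = "validation_call"
    ))
  }
  viable <- points$cell_count >= band$floor &
    (is.na(band$ceiling) | points$cell_count <= band$ceiling)
  qual <- viable & !is.na(points$activity) & points$activity > activity_threshold
  if (!any(qual)) {
    return(structure(
      list(is_active = FALSE, best_concentration = NA_real_, best_activity = NA_real_),
      class = "validation_call"
    ))
  }
  q <- points[qual, , drop = FALSE]
  q <- q[order(-q$activity, q$concentration), , drop = FALSE]
  structure(
    list(
      is_active = TRUE,
      best_concentration = q$concentration[1], best_activity = q$activity[1]
    ),
    class = "validation_call"
  )
}

#' @export
print.validation_call <- function(x, ...) {
  if (x$is_active) {
    cat(sprintf(
      "validation_call: ACTIVE, best %.3g%% at %s mg/mL\n",
      x$best_activity, format_concentration(x$best_concentration)
    ))
  } else {
    cat("validation_call: inactive\n")
  }
  invisible(x)
}

#' Activity-versus-cell-number diagnostic table
#'
#' Tidy per-dilution table for the plots used to pick the dilution with the
#' highest activity at acceptable viability. Cytotoxic rows keep their cell
#' count with missing activity.
#'
#' @param points Data frame with `concentration`, `activity`, `cell_count`.
#' @param band Optional [viability_band()] used to set `cytotoxic_flag`
#'   (otherwise flagged where activity is missing).
#' @return Data frame (`cell_count`, `activity`, `concentration`,
#'   `cytotoxic_flag`) ordered by decreasing concentration.
#' @export
activity_vs_cellnumber <- function(points, band = NULL) {
  if (is.null(points) || nrow(points) == 0) {
    return(data.frame(
      cell_count = integer(0), activity = numeric(0),
      concentration = numeric(0), cytotoxic_flag = logical(0)
    ))
  }
  flag <- if (!is.null(band)) {
    points$cell_count < band$floor
  } else {
    is.na(points$activity)
  }
  out <- data.frame(
    cell_count = points$cell_count, activity = points$activity,
    concentration = points$concentration, cytotoxic_flag = flag
  )
  out[order(-out$concentration), , drop = FALSE]
}
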