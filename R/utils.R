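#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' All well names of a 96-well plate in row-major order ("A1" ... "H12")
#' @noRd
plate_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Split a well name like "B4" into row letter and column number
#' @noRd
parse_well <- function(well) {
  stopifnot(is.character(well))
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  bad <- !(row %in% PLATE_ROWS) | is.na(col) | col < 1 | col > 12
  if (any(bad)) {
    stop("invalid well name(s): ", paste(well[bad], collapse = ", "), call. = FALSE)
  }
  list(row = row, col = col)
}

#' Evaluate `expr` with a private RNG state seeded by `seed`
#'
#' Every stochastic operation in the package routes its randomness through
#' this helper so that a call never perturbs (and is never perturbed by) the
#' caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a child seed from a run seed and a stage label, staying below 2^31
#' @noRd
derive_seed <- function(seed, label) {
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) + offset * 1009) %% .Machine$integer.max)
}

#' Stop with a classed condition so callers can test on error class
#' @noRd
stop_hcs <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hcs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Scalar numeric check
#' @noRd
check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_hcs("hcs_domain_error", "`%s` must be a finite numeric scalar", name)
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stop_hcs(
      "hcs_domain_error", "`%s` = %g is outside the allowed range %s%g, %g]",
      name, x, if (strict_min) "(" else "[", min, max
    )
  }
  invisible(x)
}

#' Truncated-at-zero normal draws (well-average intensity model)
#' @noRd
rnorm_pos <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}
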