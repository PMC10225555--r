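# Plain-text interchange: plate maps, measurement tables and run
# configurations. CSV columns follow the conventions used throughout the
# package (see the plate-map and measurement writers).

#' Write / read a plate map CSV
#'
#' Columns: `plate_id`, `well`, `role` (`EXTRACT`/`POS`/`NEG`/`EMPTY`),
#' `extract_id`, `concentration_mg_per_ml`.
#'
#' @param plate_map Data frame as from [build_plate_maps()].
#' @param path File path.
#' @return `path` (writer) / the data frame (reader).
#' @export
write_plate_map <- function(plate_map, path) {
  utils::write.csv(plate_map, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("plate_id", "well", "role", "extract_id", "concentration_mg_per_ml")
  if (!all(need %in% names(df))) {
    stop_hcs("hcs_input_error", "plate map must have columns %s", paste(need, collapse = ", "))
  }
  parse_well(df$well) # validates
  df
}

#' Write / read a per-well measurement CSV
#'
#' Columns: `plate_id`, `well`, `role`, `extract_id`, `cell_count`,
#' `avg_gfp` (empty where missing), `gfp_missing`.
#'
#' @param measurements Data frame of per-well measurements.
#' @param path File path.
#' @return `path` (writer) / the data frame (reader).
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("plate_id", "well", "cell_count", "avg_gfp") %in% names(df))) {
    stop_hcs("hcs_input_error", "measurement table missing required columns")
  }
  if (is.null(df$gfp_missing)) df$gfp_missing <- is.na(df$avg_gfp)
  df$gfp_missing <- as.logical(df$gfp_missing)
  df
}

#' Bundle pipeline settings into a run configuration
#'
#' A run configuration is serialisable to JSON and back without loss, and
#' every stochastic stage of [run_screen_pipeline()] derives its seed
#' deterministically from `seed`.
#'
#' @param scenario A [screen_scenario()].
#' @param mode `"table"` (score the simulated well table directly) or
#'   `"image"` (render fields per well, quantify them, and score the
#'   measurements recovered from the images).
#' @param activity_threshold Percent-activity hit threshold (default 40).
#' @param k Viability band half-width in SD units (default 1).
#' @param sided Band sidedness for the primary screen (default `"both"`).
#' @param z_min Minimal acceptable plate Z'-factor (default 0.4).
#' @param imaging Named list of image-mode settings: `image_shape`,
#'   `nucleus_radius_px`, `ring_width_px`, `noise_sd`, `n_fields`,
#'   `field_fraction` (fraction of a well's cells captured per rendered
#'   field), `smoothing_sigma`, `min_area`.
#' @param seed Master run seed (integer).
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = screen_scenario(),
                       mode = c("table", "image"),
                       activity_threshold = 40, k = 1,
                       sided = c("both", "lower"), z_min = 0.4,
                       imaging = list(), seed = 42) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  img_defaults <- list(
    image_shape = c(96L, 96L), nucleus_radius_px = 3, ring_width_px = 2,
    noise_sd = 50, n_fields = 1L, field_fraction = 0.006,
    smoothing_sigma = 1, min_area = 5
  )
  imaging <- utils::modifyList(img_defaults, imaging)
  structure(
    list(
      scenario = scenario, mode = mode,
      activity_threshold = activity_threshold, k = k, sided = sided,
      z_min = z_min, imaging = imaging, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Serialise / restore a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` (writer) / a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    scenario = unclass(config$scenario),
    mode = config$mode, activity_threshold = config$activity_threshold,
    k = config$k, sided = config$sided, z_min = config$z_min,
    imaging = config$imaging, seed = config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(screen_scenario, p$scenario)
  run_config(
    scenario = sc, mode = p$mode, activity_threshold = p$activity_threshold,
    k = p$k, sided = p$sided, z_min = p$z_min,
    imaging = as.list(p$imaging), seed = p$seed
  )
}
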