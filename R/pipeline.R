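# End-to-end orchestration: simulate -> (render/quantify) -> normalise ->
# QC -> call hits -> validate. Deterministic given the run seed; each stage
# draws from a seed derived from the master seed and a stage label.

# Quantify one well by rendering and segmenting synthetic fields. A field
# captures `field_fraction` of the well's cells; the well-level count is
# scaled back up by the same factor.
quantify_well_from_images <- function(cell_count, avg_gfp, scenario, imaging, seed) {
  n_field_cells <- max(0L, as.integer(round(cell_count * imaging$field_fraction)))
  gfp_mean <- if (is.na(avg_gfp)) scenario$neg_mean else avg_gfp
  fields <- lapply(seq_len(imaging$n_fields), function(f) {
    spec <- field_image_spec(
      image_shape = imaging$image_shape, n_cells = n_field_cells,
      nucleus_radius_px = imaging$nucleus_radius_px,
      ring_width_px = imaging$ring_width_px,
      cytoplasm_gfp_mean = gfp_mean, noise_sd = imaging$noise_sd,
      seed = derive_seed(seed, sprintf("field%d", f))
    )
    fi <- render_field(spec)
    quantify_field(
      fi$dna, fi$gfp,
      smoothing_sigma = imaging$smoothing_sigma, min_area = imaging$min_area,
      ring_width_px = imaging$ring_width_px
    )
  })
  wm <- aggregate_well(fields)
  scale <- imaging$n_fields * imaging$field_fraction
  list(
    cell_count = as.integer(round(wm$cell_count / scale)),
    avg_gfp = wm$avg_gfp
  )
}

#' Run the full primary-screen pipeline on a synthetic scenario
#'
#' Simulates the screen described by `config$scenario`, obtains per-well
#' measurements either directly (`mode = "table"`) or by rendering and
#' quantifying synthetic field images per well (`mode = "image"`), computes
#' per-plate control statistics and Z'-factor QC, scores percent activity,
#' applies the dual activity/viability hit criterion per plate, and scores
#' the calls against the planted ground truth. Rerunning with an identical
#' configuration reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @return List of class `screen_run`: `config`, `simulation`,
#'   `measurements` (the table actually scored), `qc` (per-plate
#'   [plate_qc()] list), `activities`, `hit_calls`, `report`
#'   ([screen_report()] with confusion counts).
#' @export
run_screen_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  sc$seed <- derive_seed(config$seed, "simulate")
  sim <- simulate_screen(sc)

  meas <- sim$measurements
  if (config$mode == "image") {
    floor_count <- sc$missing_gfp_floor * sc$cells_per_well_mean
    live <- which(meas$role %in% c("NEG", "POS", "EXTRACT"))
    for (i in live) {
      q <- quantify_well_from_images(
        meas$cell_count[i], meas$avg_gfp[i], sc, config$imaging,
        derive_seed(config$seed, paste0("well_", meas$plate_id[i], "_", meas$well[i]))
      )
      meas$cell_count[i] <- q$cell_count
      meas$avg_gfp[i] <- q$avg_gfp
    }
    meas$gfp_missing <- meas$role %in% c("NEG", "POS", "EXTRACT") &
      meas$cell_count < floor_count
    meas$avg_gfp[meas$gfp_missing | meas$role == "EMPTY"] <- NA_real_
  }

  plates <- unique(meas$plate_id)
  qc <- list()
  activities <- NULL
  hit_calls <- NULL
  for (p in plates) {
    pm <- meas[meas$plate_id == p, , drop = FALSE]
    ctrl <- control_stats(pm)
    qc[[p]] <- plate_qc(ctrl, config$z_min)
    act <- score_activities(pm, ctrl)
    band <- viability_band(ctrl, config$k, config$sided)
    hc <- call_hits(act, band, config$activity_threshold)
    activities <- rbind(activities, act)
    hit_calls <- rbind(hit_calls, hc)
  }

  structure(
    list(
      config = config, simulation = sim, measurements = meas,
      qc = qc, activities = activities, hit_calls = hit_calls,
      report = screen_report(hit_calls, sim$ground_truth)
    ),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  zs <- vapply(x$qc, function(q) q$z_prime, numeric(1))
  cat(sprintf(
    "screen_run (%s mode, seed %d): %d plates, Z' %.3f-%.3f\n",
    x$config$mode, x$config$seed, length(x$qc), min(zs), max(zs)
  ))
  print(x$report)
  invisible(x)
}

#' Default planted truth for the validation stage
#'
#' Assigns each hit extract a true concentration-response: the first
#' `n_validated` extracts (by id order) get supra-threshold plateaus
#' (top ~ 45-70% activity) reached at non-cytotoxic dilutions, the rest get
#' marginal plateaus below the threshold; every series is cytotoxic above
#' 0.2 mg/mL so the top dilution of a standard 3-fold series from 0.5 mg/mL
#' is flagged.
#'
#' @param hit_ids Character vector of extract ids.
#' @param n_validated How many should truly validate (default
#'   `min(4, length(hit_ids))`).
#' @param seed Integer seed for the effect-size draws.
#' @return Data frame: `extract_id`, `bottom`, `top`, `ec50`, `hill`,
#'   `cytotoxic_above`.
#' @export
default_validation_truth <- function(hit_ids, n_validated = min(4L, length(hit_ids)),
                                     seed = 1) {
  n <- length(hit_ids)
  if (n == 0) {
    return(data.frame(
      extract_id = character(0), bottom = numeric(0), top = numeric(0),
      ec50 = numeric(0), hill = numeric(0), cytotoxic_above = numeric(0)
    ))
  }
  ids <- sort(hit_ids)
  with_seed(seed, {
    top <- c(
      stats::runif(n_validated, 50, 70),
      stats::runif(n - n_validated, 10, 25)
    )
    data.frame(
      extract_id = ids, bottom = 0, top = top,
      ec50 = stats::runif(n, 0.01, 0.03), hill = stats::runif(n, 1, 2),
      cytotoxic_above = 0.2
    )
  })
}

#' Run the serial-dilution validation pipeline for hit extracts
#'
#' For each hit extract: simulate a dilution series from its planted
#' concentration-response truth, fit the four-parameter logistic model, and
#' classify the extract as validated active or inactive under the dual
#' criterion (one-sided viability band by default, as cytotoxicity is the
#' only viability failure mode in dilution series).
#'
#' @param config A [run_config()] (supplies the scenario's cell-count
#'   distribution, the activity threshold and the master seed).
#' @param hit_ids Character vector of extract ids to validate.
#' @param truth Optional planted truth data frame as from
#'   [default_validation_truth()].
#' @param dilution A [serial_dilution()] (default 7-point 3-fold from
#'   0.5 mg/mL).
#' @param noise_sd Activity noise SD per dilution (default 2).
#' @param sided Band sidedness (default `"lower"`).
#' @return List of class `validation_run`: `per_extract` (list with
#'   `points`, `fit`, `call` per extract), `summary` data frame
#'   (`extract_id`, `is_active`, `best_concentration`, `best_activity`,
#'   `ec50`), `n_validated`.
#' @export
run_validation_pipeline <- function(config, hit_ids, truth = NULL,
                                    dilution = serial_dilution(0.5, 3, 7),
                                    noise_sd = 2, sided = "lower") {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  if (is.null(truth)) {
    truth <- default_validation_truth(hit_ids, seed = derive_seed(config$seed, "valtruth"))
  }
  missing_ids <- setdiff(hit_ids, truth$extract_id)
  if (length(missing_ids)) {
    stop_hcs("hcs_input_error", "no planted truth for: %s", paste(missing_ids, collapse = ", "))
  }
  band <- viability_band(
    list(cell_mu_n = sc$cells_per_well_mean, cell_delta_n = sc$cells_per_well_sd),
    config$k, sided
  )
  per_extract <- list()
  summary_rows <- NULL
  for (id in sort(hit_ids)) {
    tr <- truth[truth$extract_id == id, ]
    pts <- simulate_dose_series(
      list(bottom = tr$bottom, top = tr$top, ec50 = tr$ec50, hill = tr$hill),
      dilution$concentrations,
      noise_sd = noise_sd,
      cytotoxic_above = tr$cytotoxic_above,
      seed = derive_seed(config$seed, paste0("dose_", id)),
      cells_mean = sc$cells_per_well_mean, cells_sd = sc$cells_per_well_sd
    )
    fit <- tryCatch(
      fit_sigmoid(dilution$concentrations, pts$activity),
      hcs_insufficient_data_error = function(e) NULL
    )
    call <- classify_validated(pts, band, config$activity_threshold)
    per_extract[[id]] <- list(points = pts, fit = fit, call = call)
    summary_rows <- rbind(summary_rows, data.frame(
      extract_id = id, is_active = call$is_active,
      best_concentration = call$best_concentration,
      best_activity = call$best_activity,
      ec50 = if (is.null(fit)) NA_real_ else fit$ec50
    ))
  }
  structure(
    list(
      per_extract = per_extract, summary = summary_rows,
      n_validated = if (is.null(summary_rows)) 0L else sum(summary_rows$is_active)
    ),
    class = "validation_run"
  )
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf(
    "validation_run: %d of %d extracts validated active\n",
    x$n_validated, length(x$per_extract)
  ))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialise a screen run report to canonical JSON text
#'
#' Used for structured output and for byte-level determinism checks:
#' identical configurations yield identical JSON.
#'
#' @param run A `screen_run` from [run_screen_pipeline()].
#' @return A JSON string.
#' @export
report_json <- function(run) {
  stopifnot(inherits(run, "screen_run"))
  payload <- list(
    seed = run$config$seed,
    mode = run$config$mode,
    qc = lapply(run$qc, function(q) {
      list(pass = q$pass, z_prime = q$z_prime, controls = unclass(q$controls))
    }),
    hits = run$report$hits,
    confusion = as.list(run$report$confusion),
    n_tested = run$report$n_tested
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 12, pretty = TRUE))
}
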