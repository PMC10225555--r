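# Synthetic primary-screen generator.
#
# The generator emulates the screening campaign the analysis pipeline is
# built for: 96-well plates of crude-extract wells flanked by negative
# (1% DMSO vehicle) and positive (IFN-gamma) control columns, read out as a
# per-well cell count and an average reporter (GFP) intensity per cell per
# pixel. Ground truth (which extracts are active, which are cytotoxic) is
# planted explicitly so every downstream estimator can be scored exactly.

#' Define a synthetic screening scenario
#'
#' A scenario fixes the "world" a simulated screen is drawn from: library
#' size, number and strength of planted active extracts, number of cytotoxic
#' decoys, and the intensity distributions of the negative (vehicle) and
#' positive (cytokine-stimulated) control wells. Defaults describe a
#' 480-extract library screened at 0.175 mg/mL with control distributions
#' whose true Z'-factor is 0.5 (separation 800 intensity units, each control
#' SD 800/12).
#'
#' @param n_extracts Number of library extracts (default 480).
#' @param n_true_hits Number of planted activity-inducing extracts.
#' @param hit_effect True percent activity of planted hits, on the scale
#'   anchored by the control means: scalar, or length-2 range sampled
#'   uniformly. Must exceed 40.
#' @param n_cytotoxic Number of planted cytotoxic decoy extracts (disjoint
#'   from the hits).
#' @param cytotoxic_kill_fraction Fraction of cells removed in cytotoxic
#'   wells, in \[0, 1\].
#' @param neg_mean,neg_sd Well-average GFP intensity distribution of the
#'   1% DMSO negative controls (arbitrary units).
#' @param pos_mean,pos_sd Same for the IFN-gamma positive controls; must
#'   satisfy `pos_mean > neg_mean`.
#' @param cells_per_well_mean,cells_per_well_sd Healthy per-well cell count
#'   distribution.
#' @param null_activity_sd SD (percent-activity points) of the true activity
#'   of inactive extracts around 0.
#' @param screen_concentration Concentration (mg/mL) recorded for every
#'   extract well (default 0.175).
#' @param missing_gfp_floor Fraction of `cells_per_well_mean` below which
#'   the instrument reports no GFP value (default 0.25), mirroring screens
#'   where heavily cytotoxic wells come back without an intensity reading.
#' @param seed Integer seed; all randomness of [simulate_screen()] derives
#'   from it.
#' @return An object of class `screen_scenario`.
#' @seealso [simulate_screen()]
#' @export
screen_scenario <- function(n_extracts = 480,
                            n_true_hits = 7,
                            hit_effect = c(47, 68),
                            n_cytotoxic = 20,
                            cytotoxic_kill_fraction = 0.5,
                            neg_mean = 200, neg_sd = 200 / 3,
                            pos_mean = 1000, pos_sd = 200 / 3,
                            cells_per_well_mean = 3500,
                            cells_per_well_sd = 500,
                            null_activity_sd = 5,
                            screen_concentration = 0.175,
                            missing_gfp_floor = 0.25,
                            seed = 1) {
  check_scalar(n_extracts, "n_extracts", min = 0)
  check_scalar(n_true_hits, "n_true_hits", min = 0)
  check_scalar(n_cytotoxic, "n_cytotoxic", min = 0)
  if (n_true_hits + n_cytotoxic > n_extracts) {
    stop_hcs("hcs_domain_error", "n_true_hits + n_cytotoxic exceeds n_extracts")
  }
  check_scalar(cytotoxic_kill_fraction, "cytotoxic_kill_fraction", min = 0, max = 1)
  check_scalar(neg_sd, "neg_sd", min = 0)
  check_scalar(pos_sd, "pos_sd", min = 0)
  check_scalar(cells_per_well_sd, "cells_per_well_sd", min = 0)
  check_scalar(null_activity_sd, "null_activity_sd", min = 0)
  if (!(pos_mean > neg_mean)) {
    stop_hcs("hcs_domain_error", "pos_mean must exceed neg_mean")
  }
  if (!is.numeric(hit_effect) || !length(hit_effect) %in% c(1, 2)) {
    stop_hcs("hcs_domain_error", "hit_effect must be a scalar or a length-2 range")
  }
  if (n_true_hits > 0 && any(hit_effect <= 40)) {
    stop_hcs("hcs_domain_error", "hit_effect must exceed the 40%% activity scale point")
  }
  structure(
    list(
      n_extracts = as.integer(n_extracts),
      n_true_hits = as.integer(n_true_hits),
      hit_effect = hit_effect,
      n_cytotoxic = as.integer(n_cytotoxic),
      cytotoxic_kill_fraction = cytotoxic_kill_fraction,
      neg_mean = neg_mean, neg_sd = neg_sd,
      pos_mean = pos_mean, pos_sd = pos_sd,
      cells_per_well_mean = cells_per_well_mean,
      cells_per_well_sd = cells_per_well_sd,
      null_activity_sd = null_activity_sd,
      screen_concentration = screen_concentration,
      missing_gfp_floor = missing_gfp_floor,
      seed = as.integer(seed)
    ),
    class = "screen_scenario"
  )
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat(sprintf(
    paste0(
      "screen_scenario: %d extracts (%d planted hits, %d cytotoxic decoys)\n",
      "  controls: NEG ~ N(%.4g, %.4g), POS ~ N(%.4g, %.4g)  [true Z' = %.3f]\n",
      "  cells/well ~ N(%.4g, %.4g), seed = %d\n"
    ),
    x$n_extracts, x$n_true_hits, x$n_cytotoxic,
    x$neg_mean, x$neg_sd, x$pos_mean, x$pos_sd,
    1 - 3 * (x$pos_sd + x$neg_sd) / abs(x$pos_mean - x$neg_mean),
    x$cells_per_well_mean, x$cells_per_well_sd, x$seed
  ))
  invisible(x)
}

#' Lay out a library across 96-well plates
#'
#' Controls occupy whole columns (default: column 1 negative, column 12
#' positive); extracts fill the remaining wells row-major. As many plates as
#' needed are produced.
#'
#' @param n_extracts Number of extract wells required.
#' @param neg_col,pos_col Control column indices (1-12), distinct.
#' @param concentration Concentration (mg/mL) recorded for extract wells.
#' @return Data frame with columns `plate_id`, `well`, `role`
#'   (`EXTRACT`/`POS`/`NEG`/`EMPTY`), `extract_id`, `concentration_mg_per_ml`.
#' @export
build_plate_maps <- function(n_extracts, neg_col = 1, pos_col = 12,
                             concentration = 0.175) {
  check_scalar(n_extracts, "n_extracts", min = 0)
  if (neg_col == pos_col || !all(c(neg_col, pos_col) %in% PLATE_COLS)) {
    stop_hcs("hcs_layout_error", "control columns must be distinct columns in 1..12")
  }
  capacity <- 96L - 2L * 8L
  n_plates <- max(1L, ceiling(n_extracts / capacity))
  maps <- lapply(seq_len(n_plates), function(p) {
    wells <- plate_wells()
    cols <- parse_well(wells)$col
    role <- ifelse(cols == neg_col, "NEG", ifelse(cols == pos_col, "POS", "EXTRACT"))
    df <- data.frame(
      plate_id = sprintf("PLATE%02d", p), well = wells, role = role,
      extract_id = NA_character_, concentration_mg_per_ml = NA_real_,
      stringsAsFactors = FALSE
    )
    slots <- which(df$role == "EXTRACT")
    idx0 <- (p - 1L) * capacity
    n_here <- min(capacity, max(0L, n_extracts - idx0))
    if (n_here < length(slots)) {
      df$role[slots[seq_along(slots) > n_here]] <- "EMPTY"
    }
    if (n_here > 0) {
      df$extract_id[slots[seq_len(n_here)]] <- sprintf("EXT%04d", idx0 + seq_len(n_here))
      df$concentration_mg_per_ml[slots[seq_len(n_here)]] <- concentration
    }
    df
  })
  do.call(rbind, maps)
}

#' Simulate a primary screen with planted ground truth
#'
#' Draws one measurement row per well of the plate maps implied by the
#' scenario. Control wells sample their stated intensity distributions;
#' extract wells sample a well-average GFP intensity whose expectation
#' corresponds exactly to the extract's planted percent activity on the
#' control-anchored scale. Cytotoxic decoys have their cell counts reduced
#' by the kill fraction, and any well whose count falls below the
#' missing-GFP floor is emitted with a missing intensity, as instruments do
#' for heavily cytotoxic wells.
#'
#' Planted hit wells are given the healthy mean cell count deterministically
#' so that the planted "non-cytotoxic active" label is unambiguous under any
#' viability band centred on the negative controls; see the package
#' vignette.
#'
#' @param scenario A [screen_scenario()].
#' @param neg_col,pos_col Control column placement, passed to
#'   [build_plate_maps()].
#' @return A list of class `screen_simulation`: `plate_map`, `measurements`
#'   (one row per well: `plate_id`, `well`, `role`, `extract_id`,
#'   `cell_count`, `avg_gfp`, `gfp_missing`), and `ground_truth`
#'   (`extract_id`, `true_activity`, `is_cytotoxic`, `true_ec50`,
#'   `true_hill`).
#' @export
simulate_screen <- function(scenario, neg_col = 1, pos_col = 12) {
  stopifnot(inherits(scenario, "screen_scenario"))
  sc <- scenario
  pm <- build_plate_maps(sc$n_extracts, neg_col, pos_col, sc$screen_concentration)

  with_seed(sc$seed, {
    ids <- sprintf("EXT%04d", seq_len(sc$n_extracts))
    special <- sample(ids, sc$n_true_hits + sc$n_cytotoxic)
    hit_ids <- special[seq_len(sc$n_true_hits)]
    tox_ids <- setdiff(special, hit_ids)

    true_activity <- stats::rnorm(sc$n_extracts, 0, sc$null_activity_sd)
    names(true_activity) <- ids
    if (sc$n_true_hits > 0) {
      true_activity[hit_ids] <- if (length(sc$hit_effect) == 1) {
        sc$hit_effect
      } else {
        stats::runif(sc$n_true_hits, min(sc$hit_effect), max(sc$hit_effect))
      }
    }

    gt <- data.frame(
      extract_id = ids,
      true_activity = unname(true_activity),
      is_hit = ids %in% hit_ids,
      is_cytotoxic = ids %in% tox_ids,
      true_ec50 = rep(NA_real_, length(ids)), true_hill = rep(NA_real_, length(ids)),
      stringsAsFactors = FALSE
    )

    n_well <- nrow(pm)
    cell_count <- integer(n_well)
    avg_gfp <- rep(NA_real_, n_well)
    healthy <- function(n) {
      pmax(0L, as.integer(round(stats::rnorm(n, sc$cells_per_well_mean, sc$cells_per_well_sd))))
    }
    for (role in c("NEG", "POS", "EXTRACT")) {
      idx <- which(pm$role == role)
      if (!length(idx)) next
      if (role == "NEG") {
        cell_count[idx] <- healthy(length(idx))
        avg_gfp[idx] <- rnorm_pos(length(idx), sc$neg_mean, sc$neg_sd)
      } else if (role == "POS") {
        cell_count[idx] <- healthy(length(idx))
        avg_gfp[idx] <- rnorm_pos(length(idx), sc$pos_mean, sc$pos_sd)
      } else {
        eid <- pm$extract_id[idx]
        ta <- true_activity[eid]
        is_hit <- eid %in% hit_ids
        is_tox <- eid %in% tox_ids
        counts <- healthy(length(idx))
        counts[is_hit] <- as.integer(round(sc$cells_per_well_mean))
        counts[is_tox] <- as.integer(round((1 - sc$cytotoxic_kill_fraction) * counts[is_tox]))
        cell_count[idx] <- counts
        target_mean <- sc$neg_mean + ta / 100 * (sc$pos_mean - sc$neg_mean)
        avg_gfp[idx] <- rnorm_pos(length(idx), target_mean, sc$neg_sd)
      }
    }

    floor_count <- sc$missing_gfp_floor * sc$cells_per_well_mean
    gfp_missing <- pm$role %in% c("NEG", "POS", "EXTRACT") & cell_count < floor_count
    avg_gfp[gfp_missing | pm$role == "EMPTY"] <- NA_real_

    meas <- data.frame(
      plate_id = pm$plate_id, well = pm$well, role = pm$role,
      extract_id = pm$extract_id, cell_count = cell_count,
      avg_gfp = avg_gfp, gfp_missing = gfp_missing,
      stringsAsFactors = FALSE
    )
    structure(
      list(plate_map = pm, measurements = meas, ground_truth = gt, scenario = sc),
      class = "screen_simulation"
    )
  })
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat(sprintf(
    "screen_simulation: %d wells on %d plate(s); %d extracts (%d planted hits)\n",
    nrow(x$measurements), length(unique(x$measurements$plate_id)),
    nrow(x$ground_truth), sum(x$ground_truth$is_hit)
  ))
  invisible(x)
}
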