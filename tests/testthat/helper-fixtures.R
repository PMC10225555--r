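# Shared fixture builders. Everything is generated in code; no stored data.

# A measurement frame with explicit control intensities and cell counts.
make_controls <- function(neg_gfp, pos_gfp,
                          neg_cells = rep(4000L, length(neg_gfp)),
                          pos_cells = rep(4000L, length(pos_gfp))) {
  data.frame(
    plate_id = "P1",
    well = sprintf("X%d", seq_len(length(neg_gfp) + length(pos_gfp))),
    role = rep(c("NEG", "POS"), c(length(neg_gfp), length(pos_gfp))),
    extract_id = NA_character_,
    cell_count = c(neg_cells, pos_cells),
    avg_gfp = c(neg_gfp, pos_gfp),
    gfp_missing = FALSE,
    stringsAsFactors = FALSE
  )
}

# An activity-result frame as score_activities() would emit.
make_activities <- function(percent_activity, cell_count,
                            gfp_missing = rep(FALSE, length(percent_activity))) {
  data.frame(
    extract_id = sprintf("E%03d", seq_along(percent_activity)),
    well = sprintf("B%d", seq_along(percent_activity) %% 12 + 1),
    percent_activity = percent_activity,
    cell_count = cell_count,
    gfp_missing = gfp_missing,
    stringsAsFactors = FALSE
  )
}

# A fixed-width viability band independent of any control frame.
make_band <- function(floor, ceiling = NA_real_) {
  structure(
    list(
      floor = floor, ceiling = ceiling, k = 1,
      sided = if (is.na(ceiling)) "lower" else "both"
    ),
    class = "viability_band"
  )
}

# Single-disk nucleus label matrix (radius r at the image centre).
make_disk_labels <- function(size, r, center = c(size, size) / 2) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  m <- matrix(0L, size, size)
  m[d2 <= r^2] <- 1L
  m
}
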