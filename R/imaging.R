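# Per-cell reporter quantification from two-channel field images.
#
# The chain mirrors what high-content imagers do for reporter screens:
# smooth the DNA channel, threshold it (Otsu), label connected nuclei,
# grow a ring-shaped cytoplasmic mask around each nucleus, and average the
# reporter channel inside each ring. Implemented directly on matrices;
# images at screen scale are small enough that vectorised R is adequate.

# --- low-level image ops ----------------------------------------------------

# Separable Gaussian smoothing with edge replication.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) {
    return(img)
  }
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  convolve_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (t in -radius:radius) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n) # replicate edges
      out <- out + k[t + radius + 1] * (if (along_rows) m[idx, , drop = FALSE] else m[, idx, drop = FALSE])
    }
    out
  }
  convolve_axis(convolve_axis(img, TRUE), FALSE)
}

# Otsu's histogram threshold (256 bins over the observed range).
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) {
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- -Inf
  mids[which.max(sigma_b2)]
}

# Label 8-connected foreground components; returns an integer label matrix.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) {
    return(labels)
  }
  current <- 0L
  queue <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    queue[1] <- start
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1L:1L) {
        for (dc in -1L:1L) {
          rr <- r + dr
          c2 <- cc + dc
          if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
          q <- (c2 - 1L) * nr + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- current
            tail <- tail + 1L
            if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[tail] <- q
          }
        }
      }
    }
  }
  labels
}

# --- exported operations ----------------------------------------------------

#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian smoothing followed by Otsu thresholding and connected-component
#' labelling. Components smaller than `min_area` are dropped; components
#' touching the image border are dropped under `border_policy = "exclude"`.
#' A separation guard refuses to call foreground on effectively unimodal
#' images (uniform background, pure noise), where Otsu's split is
#' meaningless: foreground and background class means must differ by at
#' least `min_separation` pooled within-class standard deviations.
#'
#' @param dna_channel 2-D numeric matrix of DNA-stain intensities.
#' @param smoothing_sigma Gaussian smoothing SD in pixels (default 1).
#' @param min_area Minimum nucleus area in pixels (default 10).
#' @param border_policy `"exclude"` (default) or `"keep"` for nuclei
#'   touching the image border.
#' @param min_separation Minimal foreground/background class separation in
#'   pooled-SD units (default 4).
#' @return Integer matrix of nucleus labels (0 = background), labels
#'   consecutive from 1.
#' @export
segment_nuclei <- function(dna_channel, smoothing_sigma = 1, min_area = 10,
                           border_policy = c("exclude", "keep"),
                           min_separation = 4) {
  border_policy <- match.arg(border_policy)
  if (!is.matrix(dna_channel) || !is.numeric(dna_channel) || length(dna_channel) == 0) {
    stop_hcs("hcs_input_error", "dna_channel must be a non-empty 2-D numeric matrix")
  }
  if (any(dna_channel < 0)) {
    stop_hcs("hcs_input_error", "dna_channel must be non-negative")
  }
  smoothed <- gaussian_smooth(dna_channel, smoothing_sigma)
  thr <- otsu_threshold(as.vector(smoothed))
  empty <- matrix(0L, nrow(dna_channel), ncol(dna_channel))
  if (is.na(thr)) {
    return(empty)
  } # constant image
  fg <- smoothed > thr
  if (!any(fg) || all(fg)) {
    return(empty)
  }
  mu_fg <- mean(smoothed[fg])
  mu_bg <- mean(smoothed[!fg])
  pooled <- sqrt((stats::var(smoothed[fg]) + stats::var(smoothed[!fg])) / 2)
  if (!is.finite(pooled)) pooled <- 0
  if (pooled > 0 && (mu_fg - mu_bg) < min_separation * pooled) {
    return(empty)
  }
  labels <- label_components(fg)
  keep <- which(tabulate(labels[labels > 0L]) >= min_area)
  if (border_policy == "exclude" && length(keep)) {
    border_labs <- unique(c(
      labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)]
    ))
    keep <- setdiff(keep, border_labs)
  }
  relabel <- integer(max(labels, 1L))
  relabel[sort(keep)] <- seq_along(keep)
  out <- empty
  nz <- labels > 0L
  out[nz] <- relabel[labels[nz]]
  out
}

# Centroids (0-based) of each label in a label matrix; rows indexed by label.
label_centroids <- function(labels) {
  labs <- sort(unique(labels[labels > 0L]))
  if (!length(labs)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  idx <- which(labels > 0L)
  r <- ((idx - 1L) %% nrow(labels))
  cc <- ((idx - 1L) %/% nrow(labels))
  l <- labels[idx]
  cbind(
    row = as.vector(tapply(r, l, mean)),
    col = as.vector(tapply(cc, l, mean))
  )
}

#' Build disjoint cytoplasmic ring masks around segmented nuclei
#'
#' Each cell's cytoplasm is the Euclidean dilation of its nucleus by
#' `ring_width_px` minus all nuclear pixels. Pixels reachable from more
#' than one nucleus are assigned to the nucleus with the nearest centroid,
#' so masks are pairwise disjoint.
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param ring_width_px Ring width in pixels (>= 0); 0 yields empty masks.
#' @return Integer label matrix of cytoplasmic masks (same label ids).
#' @export
cytoplasmic_masks <- function(nucleus_labels, ring_width_px = 5) {
  if (!is.matrix(nucleus_labels)) {
    stop_hcs("hcs_input_error", "nucleus_labels must be a matrix")
  }
  if (!is.numeric(ring_width_px) || length(ring_width_px) != 1 || ring_width_px < 0) {
    stop_hcs("hcs_domain_error", "ring_width_px must be >= 0")
  }
  nr <- nrow(nucleus_labels)
  nc <- ncol(nucleus_labels)
  out <- matrix(0L, nr, nc)
  w <- floor(ring_width_px)
  if (w == 0 || !any(nucleus_labels > 0L)) {
    return(out)
  }
  cent <- label_centroids(nucleus_labels)
  offsets <- expand.grid(dr = -w:w, dc = -w:w)
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= w^2, ]
  rows0 <- matrix(0:(nr - 1), nr, nc)
  cols0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  best_d2 <- matrix(Inf, nr, nc)
  nuclear <- nucleus_labels > 0L
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]
    dc <- offsets$dc[i]
    # shifted[r, c] = labels[r - dr, c - dc]
    src_r <- seq(max(1, 1 - dr), min(nr, nr - dr))
    src_c <- seq(max(1, 1 - dc), min(nc, nc - dc))
    if (!length(src_r) || !length(src_c)) next
    shifted <- matrix(0L, nr, nc)
    shifted[src_r + dr, src_c + dc] <- nucleus_labels[src_r, src_c]
    cand <- shifted > 0L & !nuclear
    if (!any(cand)) next
    lab <- shifted[cand]
    d2 <- (rows0[cand] - cent[lab, 1])^2 + (cols0[cand] - cent[lab, 2])^2
    better <- d2 < best_d2[cand]
    ci <- which(cand)[better]
    out[ci] <- lab[better]
    best_d2[ci] <- d2[better]
  }
  out
}

#' Measure per-cell reporter intensity within cytoplasmic masks
#'
#' @param gfp_channel 2-D numeric matrix, same shape as the masks.
#' @param cytoplasm_labels Integer label matrix from [cytoplasmic_masks()].
#' @param nucleus_labels Optional nucleus label matrix; when supplied,
#'   centroids and nuclear areas are reported per cell.
#' @return Data frame of cell records: `label`, `centroid_row`,
#'   `centroid_col` (0-based), `nuclear_area`, `cytoplasm_area`, `mean_gfp`
#'   (arithmetic mean of reporter pixels in the cytoplasm mask; `NA` for an
#'   empty mask).
#' @export
quantify_cells <- function(gfp_channel, cytoplasm_labels, nucleus_labels = NULL) {
  if (!is.matrix(gfp_channel) || !identical(dim(gfp_channel), dim(cytoplasm_labels))) {
    stop_hcs("hcs_input_error", "gfp_channel and cytoplasm_labels shapes differ")
  }
  labs <- sort(unique(c(
    cytoplasm_labels[cytoplasm_labels > 0L],
    if (!is.null(nucleus_labels)) nucleus_labels[nucleus_labels > 0L]
  )))
  if (!length(labs)) {
    return(data.frame(
      label = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
      nuclear_area = integer(0), cytoplasm_area = integer(0), mean_gfp = numeric(0)
    ))
  }
  cyto_idx <- which(cytoplasm_labels > 0L)
  cl <- factor(cytoplasm_labels[cyto_idx], levels = labs)
  area <- as.integer(table(cl))
  sums <- tapply(gfp_channel[cyto_idx], cl, sum)
  mean_gfp <- as.numeric(ifelse(area > 0, sums / area, NA_real_))
  if (!is.null(nucleus_labels)) {
    cent <- label_centroids(nucleus_labels)
    nuc_area <- tabulate(nucleus_labels[nucleus_labels > 0L], nbins = max(labs))
    centroid_row <- cent[match(labs, sort(unique(nucleus_labels[nucleus_labels > 0L]))), 1]
    centroid_col <- cent[match(labs, sort(unique(nucleus_labels[nucleus_labels > 0L]))), 2]
    nuclear_area <- nuc_area[labs]
  } else {
    centroid_row <- centroid_col <- rep(NA_real_, length(labs))
    nuclear_area <- rep(NA_integer_, length(labs))
  }
  data.frame(
    label = labs, centroid_row = centroid_row, centroid_col = centroid_col,
    nuclear_area = nuclear_area, cytoplasm_area = area, mean_gfp = mean_gfp
  )
}

#' Run the whole imaging chain on one two-channel field
#'
#' @param dna_channel,gfp_channel Matched intensity matrices.
#' @param smoothing_sigma,min_area,border_policy Passed to
#'   [segment_nuclei()].
#' @param ring_width_px Passed to [cytoplasmic_masks()].
#' @return Cell-record data frame as from [quantify_cells()].
#' @export
quantify_field <- function(dna_channel, gfp_channel, smoothing_sigma = 1,
                           min_area = 10, border_policy = "exclude",
                           ring_width_px = 5) {
  nuc <- segment_nuclei(dna_channel, smoothing_sigma, min_area, border_policy)
  cyto <- cytoplasmic_masks(nuc, ring_width_px)
  quantify_cells(gfp_channel, cyto, nuc)
}

#' Aggregate per-field cell records into a per-well measurement
#'
#' @param fields List of cell-record data frames (>= 1), one per imaged
#'   field.
#' @param plate_id,well Optional identifiers carried into the result.
#' @return One-row data frame: `plate_id`, `well`, `cell_count` (cells
#'   summed over fields), `avg_gfp` (unweighted mean over cells of
#'   `mean_gfp`; `NA` when no cells), `n_fields`.
#' @export
aggregate_well <- function(fields, plate_id = NA_character_, well = NA_character_) {
  if (!is.list(fields) || length(fields) == 0 || !all(vapply(fields, is.data.frame, TRUE))) {
    stop_hcs("hcs_input_error", "fields must be a non-empty list of cell-record data frames")
  }
  all_cells <- do.call(rbind, fields)
  n <- nrow(all_cells)
  gfp <- all_cells$mean_gfp[!is.na(all_cells$mean_gfp)]
  data.frame(
    plate_id = plate_id, well = well,
    cell_count = n,
    avg_gfp = if (n == 0 || !length(gfp)) NA_real_ else mean(gfp),
    n_fields = length(fields),
    stringsAsFactors = FALSE
  )
}
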