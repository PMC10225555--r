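# Geometric field-image phantoms: disk nuclei on a DNA channel, annular
# cytoplasm on a GFP channel, with per-cell planted ground truth. These are
# segmentation benchmarks, not optical simulations - no PSF, no shading.

#' Specify a synthetic two-channel field image
#'
#' @param image_shape Integer `(rows, cols)` of the field, pixels.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius_px Nucleus disk radius, pixels.
#' @param ring_width_px Width of the cytoplasmic annulus, pixels. Cell
#'   centres are placed at least `2 * (nucleus_radius_px + ring_width_px) + 1`
#'   pixels apart so planted counts and masks are unambiguous.
#' @param cytoplasm_gfp_mean Mean GFP intensity painted on each annulus.
#' @param noise_sd Gaussian noise SD added to both channels.
#' @param dna_nucleus_mean,dna_background DNA-channel intensities of nucleus
#'   disks and background.
#' @param gfp_background GFP-channel background intensity.
#' @param seed Integer seed.
#' @return Object of class `field_image_spec`.
#' @export
field_image_spec <- function(image_shape = c(160, 160),
                             n_cells = 35,
                             nucleus_radius_px = 4,
                             ring_width_px = 3,
                             cytoplasm_gfp_mean = 1000,
                             noise_sd = 50,
                             dna_nucleus_mean = 20000,
                             dna_background = 500,
                             gfp_background = 50,
                             seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  check_scalar(n_cells, "n_cells", min = 0)
  check_scalar(nucleus_radius_px, "nucleus_radius_px", min = 1)
  check_scalar(ring_width_px, "ring_width_px", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  for (v in c(cytoplasm_gfp_mean, dna_nucleus_mean, dna_background, gfp_background)) {
    check_scalar(v, "intensity", min = 0, max = 65535)
  }
  structure(
    list(
      image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
      nucleus_radius_px = nucleus_radius_px, ring_width_px = ring_width_px,
      cytoplasm_gfp_mean = cytoplasm_gfp_mean, noise_sd = noise_sd,
      dna_nucleus_mean = dna_nucleus_mean, dna_background = dna_background,
      gfp_background = gfp_background, seed = as.integer(seed)
    ),
    class = "field_image_spec"
  )
}

# Place n integer-coordinate centres with pairwise distance >= min_sep and
# margin from the border, by bounded rejection sampling.
place_centers <- function(n, shape, min_sep, margin, max_tries = 2000L * max(n, 1L)) {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  lo <- margin + 1
  hi_r <- shape[1] - margin
  hi_c <- shape[2] - margin
  if (hi_r < lo || hi_c < lo) {
    stop_hcs("hcs_placement_error", "field too small for the requested geometry")
  }
  centers <- matrix(NA_real_, nrow = n, ncol = 2, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_hcs(
        "hcs_placement_error",
        "could not place %d cells with separation %g in a %dx%d field",
        n, min_sep, shape[1], shape[2]
      )
    }
    cand <- c(sample(lo:hi_r, 1), sample(lo:hi_c, 1))
    if (placed == 0L ||
      min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2)) >= min_sep) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

#' Render a two-channel field image with planted cells
#'
#' Channel 1 (DNA) carries disk nuclei above background; channel 2 (GFP)
#' carries an annulus of the stated mean intensity around each nucleus.
#' Gaussian noise is added to both channels and values are clamped to the
#' unsigned 16-bit range. The painted GFP annulus extends one pixel beyond
#' the nominal ring so that masks derived from a segmented nucleus dilated
#' by `ring_width_px` stay inside the signal region.
#'
#' @param spec A [field_image_spec()].
#' @return List of class `field_image`: `dna` and `gfp` intensity matrices,
#'   `cells` (planted truth: `label`, `centroid_row`, `centroid_col` 0-based,
#'   `true_mean_gfp`), and planted `nucleus_labels` / `cytoplasm_labels`
#'   matrices (cytoplasm = annulus between the nucleus radius and
#'   `nucleus_radius_px + ring_width_px`).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_image_spec"))
  shape <- spec$image_shape
  r <- spec$nucleus_radius_px
  w <- spec$ring_width_px
  with_seed(spec$seed, {
    min_sep <- 2 * (r + w) + 1
    margin <- ceiling(r + w + 2)
    centers <- place_centers(spec$n_cells, shape, min_sep, margin)

    dna <- matrix(spec$dna_background, shape[1], shape[2])
    gfp <- matrix(spec$gfp_background, shape[1], shape[2])
    nucleus_labels <- matrix(0L, shape[1], shape[2])
    cytoplasm_labels <- matrix(0L, shape[1], shape[2])

    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
      nuc <- d2 <= r^2
      ann <- d2 > r^2 & d2 <= (r + w)^2
      paint <- d2 > r^2 & d2 <= (r + w + 1)^2 # one-pixel guard band
      dna[nuc] <- spec$dna_nucleus_mean
      gfp[paint] <- spec$cytoplasm_gfp_mean
      nucleus_labels[nuc] <- i
      cytoplasm_labels[ann] <- i
    }
    if (spec$noise_sd > 0) {
      dna <- dna + matrix(stats::rnorm(length(dna), 0, spec$noise_sd), shape[1], shape[2])
      gfp <- gfp + matrix(stats::rnorm(length(gfp), 0, spec$noise_sd), shape[1], shape[2])
    }
    dna <- pmin(pmax(dna, 0), 65535)
    gfp <- pmin(pmax(gfp, 0), 65535)

    cells <- data.frame(
      label = seq_len(nrow(centers)),
      centroid_row = centers[, 1] - 1, # 0-based, matching the imaging module
      centroid_col = centers[, 2] - 1,
      true_mean_gfp = rep(spec$cytoplasm_gfp_mean, nrow(centers))
    )
    structure(
      list(
        dna = dna, gfp = gfp, cells = cells,
        nucleus_labels = nucleus_labels, cytoplasm_labels = cytoplasm_labels,
        spec = spec
      ),
      class = "field_image"
    )
  })
}

#' Write a rendered field to a pair of TIFF files
#'
#' Files follow the `{plate}_{well}_f{field}_{channel}.tif` convention with
#' channels `ch1` (DNA) and `ch2` (GFP).
#'
#' @param field A `field_image` from [render_field()].
#' @param dir Output directory (created if needed).
#' @param plate,well,field_index Identifiers used in the filenames.
#' @return Character vector of the two paths written.
#' @export
write_field_tiffs <- function(field, dir, plate, well, field_index = 1) {
  stopifnot(inherits(field, "field_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, sprintf("%s_%s_f%d", plate, well, field_index))
  p1 <- paste0(base, "_ch1.tif")
  p2 <- paste0(base, "_ch2.tif")
  write_tiff16(field$dna, p1)
  write_tiff16(field$gfp, p2)
  c(p1, p2)
}
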