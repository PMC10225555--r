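# Imaging chain: segmentation, cytoplasmic masks, per-cell quantification,
# per-well aggregation.

test_that("segment_nuclei finds planted disks and rejects degenerate images", {
  # blank (uniform) image
  expect_equal(max(segment_nuclei(matrix(500, 80, 80))), 0)
  # pure noise: Otsu's split is meaningless, the separation guard refuses it
  noisy <- matrix(abs(rnorm(6400, 500, 50)), 80, 80)
  expect_equal(max(segment_nuclei(noisy)), 0)
  # 50 well-separated disks -> exactly 50 consecutive labels
  fi <- render_field(field_image_spec(image_shape = c(200, 200), n_cells = 50, seed = 12))
  labs <- segment_nuclei(fi$dna)
  expect_equal(sort(unique(labs[labs > 0])), 1:50)
  # input validation
  expect_error(segment_nuclei(array(1, c(2, 2, 2))), class = "hcs_input_error")
  expect_error(segment_nuclei(matrix(-1, 4, 4)), class = "hcs_input_error")
})

test_that("min_area filters small objects and border nuclei are excluded", {
  img <- matrix(100, 60, 60)
  img[30:31, 30:31] <- 20000 # 4-pixel speck
  expect_equal(max(segment_nuclei(img, smoothing_sigma = 0, min_area = 10)), 0)
  expect_equal(max(segment_nuclei(img, smoothing_sigma = 0, min_area = 4)), 1)
  img2 <- matrix(100, 60, 60)
  img2[1:6, 10:15] <- 20000 # touches the top border
  img2[30:35, 30:35] <- 20000
  expect_equal(max(segment_nuclei(img2, border_policy = "exclude")), 1)
  expect_equal(max(segment_nuclei(img2, border_policy = "keep")), 2)
})

test_that("count recovery is exact on spacing-compliant phantoms across seeds", {
  for (seed in 1:20) {
    n <- 20 + (seed %% 4) * 10
    fi <- render_field(field_image_spec(
      image_shape = c(200, 200), n_cells = n, seed = seed
    ))
    expect_equal(max(segment_nuclei(fi$dna)), n, info = sprintf("seed %d", seed))
  }
})

test_that("cytoplasmic_masks matches the brute-force dilation oracle", {
  # Oracle: a pixel belongs to the ring iff it is non-nuclear and within
  # Euclidean distance w of some nucleus pixel.
  r <- 4
  w <- 3
  labs <- make_disk_labels(41, r, center = c(21, 21))
  ring <- cytoplasmic_masks(labs, w)
  nuc_idx <- which(labs == 1L)
  nr <- nrow(labs)
  nuc_rc <- cbind((nuc_idx - 1) %% nr, (nuc_idx - 1) %/% nr)
  oracle <- matrix(0L, nr, nr)
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (labs[i, j] == 1L) next
      d <- sqrt((i - 1 - nuc_rc[, 1])^2 + (j - 1 - nuc_rc[, 2])^2)
      if (min(d) <= w) oracle[i, j] <- 1L
    }
  }
  expect_identical(ring, oracle)
  # ring is inside the ideal annulus (r, r + w]
  d2 <- outer((1:nr - 21)^2, (1:nr - 21)^2, "+")
  expect_true(all(d2[ring == 1L] > r^2 & d2[ring == 1L] <= (r + w)^2))
})

test_that("cytoplasmic masks of close nuclei are disjoint and complete", {
  labs <- matrix(0L, 40, 40)
  labs[18:22, 10:14] <- 1L
  labs[18:22, 18:22] <- 2L # 3 px gap between the squares
  ring <- cytoplasmic_masks(labs, 4)
  # disjoint by construction (single label per pixel); both cells present
  expect_setequal(unique(ring[ring > 0]), c(1L, 2L))
  # no ring pixel on nuclear ground
  expect_true(all(labs[ring > 0] == 0L))
  # contested middle column pixels split by nearest centroid
  mid <- ring[18:22, 16]
  expect_true(all(mid %in% c(1L, 2L)))
  # ring_width 0 -> empty; negative -> error
  expect_equal(max(cytoplasmic_masks(labs, 0)), 0)
  expect_error(cytoplasmic_masks(labs, -1), class = "hcs_domain_error")
})

test_that("quantify_cells averages reporter pixels per mask", {
  labs <- make_disk_labels(41, 4)
  ring <- cytoplasmic_masks(labs, 3)
  # uniform reporter value g -> every mean is g
  g <- matrix(77.5, 41, 41)
  rec <- quantify_cells(g, ring, labs)
  expect_equal(rec$mean_gfp, 77.5)
  expect_equal(rec$cytoplasm_area, sum(ring == 1L))
  expect_equal(rec$nuclear_area, sum(labs == 1L))
  # shape mismatch
  expect_error(quantify_cells(matrix(1, 5, 5), ring), class = "hcs_input_error")
})

test_that("noiseless and noisy phantoms quantify to the planted mean", {
  spec <- field_image_spec(
    image_shape = c(200, 200), n_cells = 30, noise_sd = 0,
    cytoplasm_gfp_mean = 900, seed = 9
  )
  fi <- render_field(spec)
  rec <- quantify_field(fi$dna, fi$gfp, ring_width_px = spec$ring_width_px)
  expect_equal(nrow(rec), 30)
  expect_equal(rec$mean_gfp, rep(900, 30), tolerance = 1e-12)
  # 5% noise: segmented-mask means within 1% of planted (annulus ~330 px at
  # the r=8/w=5 geometry, so the pixel-mean SE is ~0.3%)
  spec2 <- field_image_spec(
    image_shape = c(320, 320), n_cells = 30, noise_sd = 45,
    nucleus_radius_px = 8, ring_width_px = 5,
    cytoplasm_gfp_mean = 900, seed = 10
  )
  fi2 <- render_field(spec2)
  rec2 <- quantify_field(fi2$dna, fi2$gfp, ring_width_px = spec2$ring_width_px)
  expect_equal(nrow(rec2), 30)
  expect_true(all(abs(rec2$mean_gfp - 900) / 900 < 0.01))
})

test_that("intensity linearity: scaling the reporter scales every mean", {
  fi <- render_field(field_image_spec(n_cells = 15, seed = 3))
  nuc <- segment_nuclei(fi$dna)
  ring <- cytoplasmic_masks(nuc, 3)
  base <- quantify_cells(fi$gfp, ring, nuc)
  for (a in c(0.5, 2, 7.25)) {
    scaled <- quantify_cells(fi$gfp * a, ring, nuc)
    expect_equal(scaled$mean_gfp, a * base$mean_gfp, tolerance = 1e-12)
  }
})

test_that("mask disjointness: per-cell areas sum to the union area", {
  fi <- render_field(field_image_spec(image_shape = c(200, 200), n_cells = 40, seed = 8))
  nuc <- segment_nuclei(fi$dna)
  ring <- cytoplasmic_masks(nuc, 3)
  rec <- quantify_cells(fi$gfp, ring, nuc)
  expect_equal(sum(rec$cytoplasm_area), sum(ring > 0L))
})

test_that("aggregate_well pools fields per the unweighted-cell mean", {
  cellrec <- function(gfp) data.frame(
    label = seq_along(gfp),
    centroid_row = numeric(length(gfp)), centroid_col = numeric(length(gfp)),
    nuclear_area = rep(10L, length(gfp)), cytoplasm_area = rep(20L, length(gfp)),
    mean_gfp = gfp
  )
  # 12 fields x 10 cells of mean 5
  wm <- aggregate_well(rep(list(cellrec(rep(5, 10))), 12), "P1", "A2")
  expect_equal(wm$cell_count, 120)
  expect_equal(wm$avg_gfp, 5)
  expect_equal(wm$n_fields, 12)
  # hand arithmetic: (2*10 + 3*20) / 5 = 16
  wm <- aggregate_well(list(cellrec(rep(10, 2)), cellrec(rep(20, 3))))
  expect_equal(wm$cell_count, 5)
  expect_equal(wm$avg_gfp, 16)
  # zero cells -> missing intensity
  wm <- aggregate_well(list(cellrec(numeric(0))))
  expect_equal(wm$cell_count, 0)
  expect_true(is.na(wm$avg_gfp))
  expect_error(aggregate_well(list()), class = "hcs_input_error")
})
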