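test_that("degenerate slices are handled as specified", {
  zero <- matrix(0, 32, 32)
  ls <- segment_nuclei_slice(zero, segmentation_params())
  expect_identical(nrow(ls$components), 0L)
  # all-constant with Otsu: empty result, not an error
  const <- matrix(7, 32, 32)
  expect_identical(nrow(segment_nuclei_slice(const)$components), 0L)
  bad <- zero; bad[3, 3] <- NA
  expect_error(segment_nuclei_slice(bad), "non-finite")
})

test_that("disc areas and size gating match the analytic geometry", {
  img <- matrix(0, 96, 96)
  radii <- c(10, 13, 7)
  centers <- list(c(25, 25), c(30, 70), c(70, 40))
  for (i in 1:3) img <- draw_disc(img, centers[[i]][1], centers[[i]][2],
                                  radii[i], 100)
  p <- segmentation_params(smooth_sigma_px = 0, threshold = 50,
                           min_area_px2 = 1, fill_holes = FALSE)
  ls <- segment_nuclei_slice(img, p)
  expect_identical(nrow(ls$components), 3L)
  for (i in seq_len(3)) {
    # match component by centroid (0-based px)
    d <- (ls$components$centroid_y - (centers[[i]][1] - 1))^2 +
      (ls$components$centroid_x - (centers[[i]][2] - 1))^2
    comp <- ls$components[which.min(d), ]
    expect_lt(abs(comp$area - pi * radii[i]^2) / (pi * radii[i]^2), 0.05)
  }
  # raising min_area_px2 drops exactly the smallest object
  p2 <- segmentation_params(smooth_sigma_px = 0, threshold = 50,
                            min_area_px2 = pi * 8^2, fill_holes = FALSE)
  ls2 <- segment_nuclei_slice(img, p2)
  expect_identical(nrow(ls2$components), 2L)
  expect_true(all(ls2$components$area > pi * 8^2))
})

test_that("component records are exactly recomputable from the label image", {
  fld <- clean_field(seed = 9, cells_per_field = 4)
  dapi <- get_channel(fld$grid, "dapi")
  p <- segmentation_params(smooth_sigma_px = 0, threshold = 50,
                           min_area_px2 = 1, fill_holes = FALSE)
  ls <- segment_nuclei_slice(dapi[, , 7], p, z = 6L)
  rec <- nucleovol:::component_records(ls$labels, dapi[, , 7])
  expect_equal(ls$components, rec)
  expect_true(all(ls$components$centroid_y >= 0 &
                  ls$components$centroid_y <= nrow(ls$labels) - 1))
})

test_that("gates are monotone: tightening never adds components", {
  fld <- clean_field(seed = 13, cells_per_field = 6)
  dapi <- get_channel(fld$grid, "dapi")
  sl <- dapi[, , 7]
  base <- segment_nuclei_slice(sl, segmentation_params(
    smooth_sigma_px = 0, threshold = 50, min_area_px2 = 1,
    fill_holes = FALSE))
  n_prev <- nrow(base$components)
  for (amin in c(50, 200, 500, 900)) {
    n <- nrow(segment_nuclei_slice(sl, segmentation_params(
      smooth_sigma_px = 0, threshold = 50, min_area_px2 = amin,
      fill_holes = FALSE))$components)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- nrow(base$components)
  for (imin in c(40, 80, 101)) {
    n <- nrow(segment_nuclei_slice(sl, segmentation_params(
      smooth_sigma_px = 0, threshold = 50, min_area_px2 = 1,
      min_mean_intensity = imin, fill_holes = FALSE))$components)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("watershed splitting separates touching discs", {
  img <- matrix(0, 64, 96)
  img <- draw_disc(img, 32, 34, 12, 100)
  img <- draw_disc(img, 32, 56, 12, 100)
  img[img > 100] <- 100 # overlapping region
  merged <- segment_nuclei_slice(img, segmentation_params(
    smooth_sigma_px = 0, threshold = 50, min_area_px2 = 1,
    fill_holes = FALSE, split_touching = FALSE))
  expect_identical(nrow(merged$components), 1L)
  split <- segment_nuclei_slice(img, segmentation_params(
    smooth_sigma_px = 0, threshold = 50, min_area_px2 = 1,
    fill_holes = FALSE, split_touching = TRUE))
  expect_identical(nrow(split$components), 2L)
})

test_that("focus detection obeys the null, brightness and restriction semantics", {
  # nucleus disc with nucleoplasmic level 10
  dapi <- draw_disc(matrix(0, 64, 64), 32, 32, 20, 100)
  nl <- segment_nuclei_slice(dapi, segmentation_params(
    smooth_sigma_px = 0, threshold = 50, min_area_px2 = 1,
    fill_holes = FALSE))
  # uniform marker: no foci
  uni <- matrix(10, 64, 64)
  expect_identical(nrow(detect_foci_slice(uni, nl, foci_params())), 0L)
  # two bright foci (5x nucleoplasm) inside the nucleus
  marker <- draw_disc(matrix(0, 64, 64), 32, 32, 20, 10)
  marker <- draw_disc(marker, 26, 28, 3, 40)
  marker <- draw_disc(marker, 40, 38, 3, 40)
  f <- detect_foci_slice(marker, nl, foci_params(brightness_factor = 2,
                                                 min_area_px2 = 3,
                                                 scale_px = 3))
  expect_identical(nrow(f), 2L)
  expect_true(all(f$nucleus_label == 1L))
  # a dim focus (1.5x nucleoplasm) fails the brightness gate
  dim_m <- draw_disc(matrix(0, 64, 64), 32, 32, 20, 10)
  dim_m <- draw_disc(dim_m, 32, 32, 3, 5)
  expect_identical(nrow(detect_foci_slice(dim_m, nl,
                                          foci_params(brightness_factor = 2,
                                                      min_area_px2 = 3,
                                                      scale_px = 3))), 0L)
  # focus outside every nucleus: dropped when restricted, kept otherwise
  out_m <- draw_disc(matrix(0, 64, 64), 8, 8, 3, 40)
  expect_identical(nrow(detect_foci_slice(out_m, nl,
                                          foci_params(min_area_px2 = 3,
                                                      scale_px = 3))), 0L)
  f2 <- detect_foci_slice(out_m, nl, foci_params(min_area_px2 = 3,
                                                 scale_px = 3,
                                                 restrict_to_nucleus = FALSE))
  expect_identical(nrow(f2), 1L)
  expect_identical(f2$nucleus_label, 0L)
  # shape mismatch is an explicit error
  expect_error(detect_foci_slice(matrix(0, 10, 10), nl, foci_params()),
               "shape")
})

test_that("detector recall is exact on clean phantom slices", {
  # every planted focus intersecting a slice is found, nothing spurious
  cfg <- oracle_config()
  hits <- 0L; planted <- 0L
  for (seed in 1:10) {
    fld <- clean_field(seed = 300 + seed, cells_per_field = 4)
    dapi <- get_channel(fld$grid, "dapi")
    marker <- get_channel(fld$grid, "marker")
    for (z in seq_len(dim(dapi)[3]) - 1L) {
      nl <- segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z)
      f <- detect_foci_slice(marker[, , z + 1], nl, cfg$foci)
      zc <- (z + 0.5) * fld$grid$z_step
      dz <- abs(fld$foci$cz_um - zc)
      rr <- sqrt(pmax(fld$foci$radius_um^2 - dz^2, 0)) / 0.3 # in-plane px
      # intersections with at least a pixel of support must be found; none
      # beyond the geometric intersections may be reported
      expect_gte(nrow(f), sum(rr >= 1.5))
      expect_lte(nrow(f), sum(rr > 0))
      planted <- planted + sum(rr >= 1.5); hits <- hits + nrow(f)
    }
  }
  expect_gte(hits, planted)
  expect_gt(planted, 50L)
})
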