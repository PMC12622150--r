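test_that("a single nucleus spanning slices 2-6 links into one object", {
  slices <- lapply(0:8, function(z) {
    if (z >= 2 && z <= 6) disc_label_slice(z, list(c(30, 30)), 10)
    else disc_label_slice(z, list(), 10)
  })
  objs <- link_slices(slices, c(0.3, 1), link_params(min_slices = 2))
  expect_length(objs, 1L)
  expect_identical(nrow(objs[[1]]$members), 5L)
  expect_identical(objs[[1]]$members$z, 2:6)
})

test_that("the distance cap prevents merging of separated columns", {
  slices <- lapply(0:4, function(z)
    disc_label_slice(z, list(c(20, 20), c(20, 44)), 8))
  # 24 px * 0.3 um = 7.2 um apart, cap 2 um
  objs <- link_slices(slices, c(0.3, 1), link_params())
  expect_length(objs, 2L)
  expect_true(all(vapply(objs, function(o) nrow(o$members), integer(1)) == 5L))
})

test_that("z ordering is validated", {
  s <- lapply(c(0, 2, 1), function(z) disc_label_slice(z, list(c(10, 10)), 4, 32, 32))
  expect_error(link_slices(s, c(0.3, 1)), "ordered")
  s2 <- lapply(c(0, 1, 1), function(z) disc_label_slice(z, list(c(10, 10)), 4, 32, 32))
  expect_error(link_slices(s2, c(0.3, 1)), "duplicate")
})

test_that("slice linking matches brute-force 26-connected labelling on phantoms", {
  cfg <- oracle_config()
  for (seed in 1:8) {
    fld <- clean_field(seed = 100 + seed)
    dapi <- get_channel(fld$grid, "dapi")
    slices <- lapply(seq_len(dim(dapi)[3]) - 1L, function(z)
      segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z))
    linked <- link_slices(slices, c(0.3, 1), cfg$linking)
    oracle <- label_3d_components(dapi > 50)
    sets_linked <- canonical_partition(lapply(linked, function(o) o$voxels))
    sets_oracle <- canonical_partition(
      split(which(oracle > 0), oracle[oracle > 0]))
    expect_identical(length(sets_linked), length(sets_oracle))
    expect_identical(sets_linked, sets_oracle)
  }
})

test_that("the volume identity holds exactly and integration is exact", {
  fld <- clean_field(seed = 42, cells_per_field = 4, intensity_cv = 0)
  cfg <- oracle_config()
  dapi <- get_channel(fld$grid, "dapi")
  slices <- lapply(seq_len(dim(dapi)[3]) - 1L, function(z)
    segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z))
  objs <- link_slices(slices, c(0.3, 1), cfg$linking)
  for (o in objs)
    expect_identical(o$volume_um3, o$voxel_count * 0.3^2 * 1)
  # constant channel integrates to the constant
  const <- fld$grid
  const$channels$flat <- array(3.5, dim(dapi))
  m <- integrate_object(objs[[1]], const, "flat")
  expect_identical(m$mean, 3.5)
  expect_identical(m$integrated, 3.5 * objs[[1]]$voxel_count)
  expect_error(integrate_object(objs[[1]], const, "nope"), "unknown channel")
  # noise-free nucleus: mean DAPI equals amplitude up to discretisation
  md <- integrate_object(objs[[1]], fld$grid, "dapi")
  expect_lt(abs(md$mean - 100), 1e-9)
})

test_that("the 3D partition is invariant to slice label permutation", {
  fld <- clean_field(seed = 77, cells_per_field = 5)
  cfg <- oracle_config()
  dapi <- get_channel(fld$grid, "dapi")
  slices <- lapply(seq_len(dim(dapi)[3]) - 1L, function(z)
    segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z))
  permuted <- lapply(slices, function(sl) {
    k <- nrow(sl$components)
    if (k < 2) return(sl)
    set.seed(sl$z + 1)
    perm <- sample(k)
    labs <- sl$labels
    pos <- labs > 0
    labs[pos] <- perm[labs[pos]]
    structure(list(z = sl$z, labels = labs,
                   components = nucleovol:::component_records(
                     labs, dapi[, , sl$z + 1])),
              class = "label_slice")
  })
  a <- canonical_partition(lapply(
    link_slices(slices, c(0.3, 1), cfg$linking), function(o) o$voxels))
  b <- canonical_partition(lapply(
    link_slices(permuted, c(0.3, 1), cfg$linking), function(o) o$voxels))
  expect_identical(a, b)
})

test_that("increasing the gap tolerance never increases the object count", {
  # a column with a missing middle slice
  slices <- lapply(0:6, function(z) {
    if (z == 3) disc_label_slice(z, list(), 8)
    else disc_label_slice(z, list(c(30, 30)), 8)
  })
  n_prev <- Inf
  for (gap in 0:3) {
    n <- length(link_slices(slices, c(0.3, 1),
                            link_params(max_z_gap = gap, min_slices = 1)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_identical(length(link_slices(slices, c(0.3, 1),
                                      link_params(max_z_gap = 1,
                                                  min_slices = 1))), 1L)
  expect_identical(length(link_slices(slices, c(0.3, 1),
                                      link_params(max_z_gap = 0,
                                                  min_slices = 1))), 2L)
})

test_that("cytoplasmic shells have the analytic volume and exclude nuclei", {
  # calibration chosen so the kernel radii are exact in voxels
  d <- clean_design(cells_per_field = 1, seed = 31,
                    image_shape = c(24, 96, 96), pixel_size_xy = 0.25,
                    z_step = 0.5, nuclear_radius_um = c(3, 0),
                    foci_per_nucleus = c(0, 0), min_center_spacing_um = 4)
  set.seed(31)
  fld <- simulate_field(d, "EV", "W01", 1)
  cfg <- oracle_config()
  dapi <- get_channel(fld$grid, "dapi")
  slices <- lapply(seq_len(dim(dapi)[3]) - 1L, function(z)
    segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z))
  nuc <- link_slices(slices, c(0.25, 0.5), cfg$linking)
  expect_length(nuc, 1L)
  shell <- cytoplasm_region(nuc[[1]], nuc, cyto_params(shell_width_um = 1.5))
  expect_length(intersect(shell, nuc[[1]]$voxels), 0L)
  sa <- fld$cells[1, c("sa_y_um", "sa_x_um", "sa_z_um")]
  v_analytic <- 4 / 3 * pi * ((sa[[1]] + 1.5) * (sa[[2]] + 1.5) *
                              (sa[[3]] + 1.5) - sa[[1]] * sa[[2]] * sa[[3]])
  v_measured <- length(shell) * 0.25^2 * 0.5
  expect_lt(abs(v_measured - v_analytic) / v_analytic, 0.10)
})

test_that("shells are clipped at image borders without error", {
  ls <- lapply(0:3, function(z) disc_label_slice(z, list(c(3, 3)), 4, 32, 32))
  nuc <- link_slices(ls, c(0.3, 1), link_params(min_slices = 1,
                                                border_policy = "keep"))
  shell <- cytoplasm_region(nuc[[1]], nuc, cyto_params(1.5))
  expect_true(all(shell >= 1 & shell <= 32 * 32 * 4))
  expect_gt(length(shell), 0)
})

test_that("foci linking and registration follow containment semantics", {
  fld <- clean_field(seed = 55, cells_per_field = 5)
  cfg <- oracle_config()
  dapi <- get_channel(fld$grid, "dapi")
  marker <- get_channel(fld$grid, "marker")
  slices <- lapply(seq_len(dim(dapi)[3]) - 1L, function(z)
    segment_nuclei_slice(dapi[, , z + 1], cfg$segmentation, z = z))
  nuclei <- link_slices(slices, c(0.3, 1), cfg$linking)
  foci2d <- lapply(seq_along(slices), function(i)
    detect_foci_slice(marker[, , i], slices[[i]], cfg$foci))
  f3 <- link_foci(foci2d, dim(marker), c(0.3, 1), cfg$foci_linking)
  expect_identical(length(f3), nrow(fld$foci))
  f3 <- assign_foci(f3, nuclei)
  hosts <- vapply(f3, function(f) f$host_nucleus_id, integer(1))
  expect_true(all(hosts > 0))
  # each focus is registered to the nucleus that generated it
  for (i in seq_len(nrow(fld$foci))) {
    tr <- fld$foci[i, ]
    j <- nearest_object(f3, tr$cz_um, tr$cy_um, tr$cx_um)
    cell <- fld$cells[fld$cells$cell == tr$cell, ]
    k <- nearest_object(nuclei, cell$cz_um, cell$cy_um, cell$cx_um)
    expect_identical(hosts[j], nuclei[[k]]$id)
  }
})

test_that("a single-slice focus survives with min_slices 1 and background foci stay unassigned", {
  f2d <- list(data.frame(z = 3L, label = 1L, centroid_y = 5, centroid_x = 5,
                         area = 4L, mean_intensity = 50, peak_intensity = 50,
                         nucleus_label = 0L,
                         pixels = I(list(c(1, 2, 33, 34)))))
  f3 <- link_foci(f2d, c(32, 32, 8), c(0.3, 1))
  expect_length(f3, 1L)
  expect_identical(nrow(f3[[1]]$members), 1L)
  f3 <- assign_foci(f3, list()) # no nuclei at all
  expect_identical(f3[[1]]$host_nucleus_id, 0L)
})
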