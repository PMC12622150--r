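test_that("design validation rejects impossible or inconsistent worlds", {
  expect_error(phantom_design(conditions = character()), "condition")
  expect_error(phantom_design("EV", cells_per_field = 0), ">= 1")
  expect_error(phantom_design("EV", image_shape = c(10, 30, 30),
                              cells_per_field = 40),
               "image too small")
  expect_error(phantom_design(c("EV", "M"),
                              effect_table = data.frame(condition = "EV",
                                                        quantity = "focus_area",
                                                        factor = 2)),
               "control")
  expect_error(phantom_design(c("EV", "M"),
                              effect_table = data.frame(condition = "M",
                                                        quantity = "volume",
                                                        factor = 2)),
               "unknown effect")
  expect_error(phantom_design("EV",
                              effect_table = data.frame(condition = "EV",
                                                        quantity = "focus_area",
                                                        factor = -1)),
               "> 0")
})

test_that("noise-free rendering produces disjoint ellipsoids with the right voxel counts", {
  fld <- clean_field(seed = 21, cells_per_field = 3,
                     foci_per_nucleus = c(0, 0))
  dapi <- get_channel(fld$grid, "dapi")
  lab <- label_3d_components(dapi > 50)
  expect_identical(max(lab), 3L)
  vx <- fld$grid$pixel_size_xy^2 * fld$grid$z_step
  seen <- integer(0)
  for (i in seq_len(3)) {
    tr <- fld$cells[i, ]
    lbl <- lab[1 + floor(tr$cy_um / 0.3) + 128 * floor(tr$cx_um / 0.3) +
               128 * 128 * floor(tr$cz_um / 1)]
    expect_gt(lbl, 0)
    seen <- c(seen, lbl)
    vol_voxels <- sum(lab == lbl) * vx
    # voxelisation of a smooth ellipsoid: surface-term discretisation bound
    expect_lt(abs(vol_voxels - tr$volume_um3) / tr$volume_um3, 0.08)
  }
  expect_identical(anyDuplicated(seen), 0L)
})

test_that("generation is bit-identical for a fixed seed", {
  d <- clean_design(seed = 7, fields = 2,
                    noise = list(read_sd = 2, poisson = TRUE))
  p1 <- make_plate_phantom(d)
  p2 <- make_plate_phantom(d)
  expect_identical(p1$stacks, p2$stacks)
  expect_identical(p1$truth, p2$truth)
})

test_that("every planted focus lies inside its owner's rendered support", {
  fld <- clean_field(seed = 5, cells_per_field = 6)
  dapi <- get_channel(fld$grid, "dapi")
  inside <- dapi > 50
  for (i in seq_len(nrow(fld$foci))) {
    f <- fld$foci[i, ]
    iy <- 1 + floor(f$cy_um / 0.3); ix <- 1 + floor(f$cx_um / 0.3)
    iz <- 1 + floor(f$cz_um / 1)
    expect_true(inside[iy, ix, iz])
  }
})

test_that("an injected nuclear-volume factor is reproduced by the generator's own truth", {
  # the 48 h P301S nuclear expansion (~15%) used as the injected factor
  d <- phantom_design(c("EV", "mutant-48h"),
                      wells_per_condition = 1, fields_per_well = 10,
                      cells_per_field = 50, image_shape = c(16, 300, 300),
                      noise = list(read_sd = 0, poisson = FALSE),
                      psf_sigma_um = 0, seed = 11,
                      effect_table = data.frame(condition = "mutant-48h",
                                                quantity = "nuclear_volume",
                                                factor = 1.15))
  # truth only: 500 cells per condition
  vols <- list()
  for (cond in d$conditions) {
    v <- c()
    for (f in 1:10) {
      set.seed(1000 + f + 100 * match(cond, d$conditions))
      v <- c(v, simulate_field(d, cond, "W01", f)$cells$volume_um3)
    }
    vols[[cond]] <- v
  }
  ratio <- mean(vols[["mutant-48h"]]) / mean(vols[["EV"]])
  expect_lt(abs(ratio - 1.15), 0.02)
})

test_that("control wells are statistically exchangeable", {
  d <- clean_design(fields = 4, cells_per_field = 6, seed = 3,
                    image_shape = c(14, 160, 160))
  vols <- list()
  for (f in 1:4) {
    set.seed(500 + f)
    vols[[f]] <- simulate_field(d, "EV", "W01", f)$cells$volume_um3
  }
  ks <- suppressWarnings(stats::ks.test(vols[[1]], vols[[2]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("paper presets encode the printed effect sizes", {
  d <- preset_design("SH-SY5Y-1h", "S305N")
  expect_equal(effect_factor(d, "S305N", "focus_amplitude"), 2.4)
  d2 <- preset_design("SH-SY5Y-1h", "P301S")
  expect_equal(effect_factor(d2, "P301S", "focus_area"), 1.10)
  expect_equal(effect_factor(d2, "P301S", "nuclear_volume"), 1.025)
  d3 <- preset_design("iPSC", "IVS10+16")
  expect_equal(effect_factor(d3, "IVS10+16", "nuclear_volume"), 1.45)
  expect_error(preset_design("iPSC", "S305N"), "valid pairs")
})

test_that("synthetic Ct tables follow the stated closed form", {
  d <- qpcr_design(genes = "45S", conditions = c("EV", "mut"),
                   abundance_ratio = data.frame(condition = "mut",
                                                gene = "45S", ratio = 1.51),
                   baseline_ct = c(`45S` = 12), ct_noise_sd = 0, seed = 2)
  tab <- make_ct_table(d)$table
  mut <- tab$ct[tab$gene == "45S" & tab$condition == "mut"]
  expect_equal(unique(mut), 12 - log2(1.51))
  ev <- tab$ct[tab$gene == "45S" & tab$condition == "EV"]
  expect_equal(unique(ev), 12)
  # null case: ratio 1 everywhere collapses conditions
  d0 <- qpcr_design(genes = "45S", conditions = c("EV", "mut"),
                    ct_noise_sd = 0, seed = 2)
  t0 <- make_ct_table(d0)$table
  expect_equal(length(unique(t0$ct[t0$gene == "45S"])), 1L)
})

test_that("qPCR design invariants hold", {
  expect_error(qpcr_design(genes = "45S", conditions = "EV",
                           replicates_per_sample = 1), ">= 2")
  expect_error(qpcr_design(genes = "45S", conditions = "EV",
                           baseline_ct = c(`45S` = 46)), "45")
  expect_error(qpcr_design(genes = "45S", conditions = c("EV", "m"),
                           abundance_ratio = data.frame(condition = "m",
                                                        gene = "ACTB",
                                                        ratio = 2)),
               "reference")
})

test_that("infeasible placement fails with a bounded, informative error", {
  # passes the packing bound but rejection sampling cannot satisfy it
  d <- phantom_design("EV", cells_per_field = 4,
                      image_shape = c(12, 64, 64),
                      min_center_spacing_um = 13,
                      noise = list(read_sd = 0, poisson = FALSE),
                      psf_sigma_um = 0, seed = 1)
  set.seed(1)
  expect_error(simulate_field(d, "EV", "W09", 3), "W09")
})
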