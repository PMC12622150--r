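#' Design for a synthetic high-content plate phantom
#'
#' Describes a plate of multi-channel fluorescence z-stacks with known ground
#' truth: ellipsoidal nuclei in a DAPI-like channel, bright nucleolar foci in
#' a marker channel, an optional dim cytoplasmic shell, condition-dependent
#' multiplicative effects, Gaussian point-spread blur, and Poisson-Gaussian
#' imaging noise. The first condition is the control and must carry effect
#' factors of exactly 1.
#'
#' The `effect_table` maps `(condition, quantity)` to a multiplicative factor,
#' with `quantity` one of `nuclear_volume`, `focus_area`, `focus_amplitude`,
#' `nuclear_marker_amplitude`, `cyto_marker_amplitude`. A `nuclear_volume`
#' factor `f` scales every nuclear radius by `f^(1/3)`; a `focus_area` factor
#' scales focus radii by `sqrt(f)`; amplitude factors scale the corresponding
#' channel amplitudes directly.
#'
#' @param conditions character vector of condition names; the first is the
#'   control.
#' @param wells_per_condition,fields_per_well,cells_per_field counts (>= 1).
#' @param image_shape integer vector `(n_z, n_y, n_x)` in voxels.
#' @param pixel_size_xy,z_step voxel calibration in micrometres.
#' @param nuclear_radius_um `(mean, sd)` of the truncated-normal nuclear
#'   radius (truncated symmetrically at 3 sd, floored above zero).
#' @param foci_per_nucleus `(min, max)` of the uniform-integer foci count.
#' @param focus_radius_um `(mean, sd)` truncated-normal focus radius.
#' @param channel_baselines named list; each entry a list with `background`,
#'   `nucleus_amplitude`, `focus_amplitude`, `cyto_amplitude` (all >= 0).
#' @param effect_table data.frame with columns `condition`, `quantity`,
#'   `factor`; missing entries default to 1.
#' @param noise list with `read_sd` (Gaussian read noise sd, >= 0) and
#'   `poisson` (logical shot-noise flag).
#' @param psf_sigma_um isotropic Gaussian blur scale (0 disables).
#' @param min_center_spacing_um in-plane exclusion distance between nuclear
#'   centres.
#' @param cyto_shell_um width of the rendered cytoplasmic shell.
#' @param intensity_cv lognormal per-cell staining variability (sdlog) applied
#'   multiplicatively to nuclear and focus amplitudes.
#' @param dapi_channel name of the nuclear-stain channel.
#' @param seed integer RNG seed.
#' @return a validated object of class `phantom_design`.
#' @export
phantom_design <- function(conditions,
                           wells_per_condition = 3,
                           fields_per_well = 4,
                           cells_per_field = 12,
                           image_shape = c(16, 224, 224),
                           pixel_size_xy = 0.3,
                           z_step = 1.0,
                           nuclear_radius_um = c(4.0, 0.25),
                           foci_per_nucleus = c(1, 4),
                           focus_radius_um = c(1.0, 0.2),
                           channel_baselines = list(
                             dapi = list(background = 5, nucleus_amplitude = 100,
                                         focus_amplitude = 0, cyto_amplitude = 0),
                             marker = list(background = 0, nucleus_amplitude = 0,
                                           focus_amplitude = 100, cyto_amplitude = 0)),
                           effect_table = NULL,
                           noise = list(read_sd = 2, poisson = TRUE),
                           psf_sigma_um = 0.2,
                           min_center_spacing_um = 9,
                           cyto_shell_um = 1.5,
                           intensity_cv = 0.2,
                           dapi_channel = "dapi",
                           seed = 1L) {
  if (length(conditions) < 1) stop("need at least one condition")
  counts <- c(wells_per_condition, fields_per_well, cells_per_field)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (length(image_shape) != 3 || any(image_shape < 1))
    stop("image_shape must be (n_z, n_y, n_x) with positive entries")
  if (nuclear_radius_um[1] <= 0 || nuclear_radius_um[2] < 0 ||
      focus_radius_um[1] <= 0 || focus_radius_um[2] < 0)
    stop("radii and sds must be positive")
  if (min_center_spacing_um <= 0 || cyto_shell_um <= 0)
    stop("spacing and shell width must be > 0")
  if (foci_per_nucleus[1] < 0 || foci_per_nucleus[2] < foci_per_nucleus[1])
    stop("foci_per_nucleus must be an ordered non-negative range")
  if (!dapi_channel %in% names(channel_baselines))
    stop(sprintf("dapi_channel '%s' missing from channel_baselines", dapi_channel))
  if (is.null(effect_table))
    effect_table <- data.frame(condition = character(), quantity = character(),
                               factor = numeric())
  stopifnot(all(c("condition", "quantity", "factor") %in% names(effect_table)))
  if (any(effect_table$factor <= 0)) stop("every effect factor must be > 0")
  bad_q <- setdiff(effect_table$quantity,
                   c("nuclear_volume", "focus_area", "focus_amplitude",
                     "nuclear_marker_amplitude", "cyto_marker_amplitude"))
  if (length(bad_q)) stop("unknown effect quantities: ", paste(bad_q, collapse = ", "))
  ctrl <- effect_table[effect_table$condition == conditions[1], ]
  if (nrow(ctrl) && any(ctrl$factor != 1))
    stop("control condition (first) must have all effect factors = 1")
  if (noise$read_sd < 0) stop("read_sd must be >= 0")
  # Fail-fast feasibility bound: a hexagonal packing at the exclusion
  # distance must admit at least cells_per_field sites (generation later uses
  # capped rejection sampling, never an unbounded loop).
  ly <- image_shape[2] * pixel_size_xy
  lx <- image_shape[3] * pixel_size_xy
  max_sites <- floor(ly / min_center_spacing_um + 1) *
    floor(lx / min_center_spacing_um + 1)
  if (max_sites < cells_per_field)
    stop(sprintf("image too small: at most ~%d placements at spacing %.3g um, need %d",
                 max_sites, min_center_spacing_um, cells_per_field))
  structure(list(conditions = conditions,
                 wells_per_condition = as.integer(wells_per_condition),
                 fields_per_well = as.integer(fields_per_well),
                 cells_per_field = as.integer(cells_per_field),
                 image_shape = as.integer(image_shape),
                 pixel_size_xy = pixel_size_xy, z_step = z_step,
                 nuclear_radius_um = nuclear_radius_um,
                 foci_per_nucleus = as.integer(foci_per_nucleus),
                 focus_radius_um = focus_radius_um,
                 channel_baselines = channel_baselines,
                 effect_table = effect_table,
                 noise = noise, psf_sigma_um = psf_sigma_um,
                 min_center_spacing_um = min_center_spacing_um,
                 cyto_shell_um = cyto_shell_um,
                 intensity_cv = intensity_cv,
                 dapi_channel = dapi_channel,
                 seed = as.integer(seed)),
            class = "phantom_design")
}

#' Look up a multiplicative effect factor
#'
#' @param design a [phantom_design()].
#' @param condition,quantity keys into the effect table.
#' @return the factor, defaulting to 1 when absent.
#' @export
effect_factor <- function(design, condition, quantity) {
  et <- design$effect_table
  hit <- et$condition == condition & et$quantity == quantity
  if (any(hit)) et$factor[which(hit)[1]] else 1
}

# Symmetric 3-sd truncated normal (keeps the mean exact), floored above zero.
rtrunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- max(mean - 3 * sd, 1e-6)
  hi <- mean + 3 * sd
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# 1-based index range of voxel centres covered by [lo, hi] (um).
idx_range <- function(lo, hi, spacing, n) {
  i0 <- max(1L, as.integer(floor(lo / spacing + 0.5)) + 1L)
  i1 <- min(n, as.integer(ceiling(hi / spacing - 0.5)) + 1L)
  if (i1 < i0) integer(0) else i0:i1
}

#' Simulate one field of view with ground truth
#'
#' Renders `cells_per_field` ellipsoidal nuclei (with mild volume-preserving
#' random anisotropy) and their planted foci into a fresh multi-channel
#' stack, applies the condition's multiplicative effects, then blur and
#' noise. Ground truth (analytic, pre-blur/noise) is returned alongside.
#' The caller is responsible for seeding the RNG; [make_plate_phantom()]
#' derives a deterministic per-field seed.
#'
#' @param design a [phantom_design()].
#' @param condition condition name (must be in `design$conditions`).
#' @param well,field identifiers recorded in the ground truth.
#' @return list with `grid` (a [voxel_grid()]), `cells` and `foci`
#'   data.frames.
#' @export
simulate_field <- function(design, condition, well = "W01", field = 1L) {
  stopifnot(inherits(design, "phantom_design"))
  if (!condition %in% design$conditions)
    stop(sprintf("unknown condition '%s'", condition))
  nz <- design$image_shape[1]; ny <- design$image_shape[2]
  nx <- design$image_shape[3]
  px <- design$pixel_size_xy; dz <- design$z_step
  ly <- ny * px; lx <- nx * px; lz <- nz * dz
  f_vol <- effect_factor(design, condition, "nuclear_volume")
  f_area <- effect_factor(design, condition, "focus_area")
  f_famp <- effect_factor(design, condition, "focus_amplitude")
  f_namp <- effect_factor(design, condition, "nuclear_marker_amplitude")
  f_camp <- effect_factor(design, condition, "cyto_marker_amplitude")

  n_cells <- design$cells_per_field
  # --- sample geometry with capped rejection on the in-plane spacing -------
  radii <- rtrunc_norm(n_cells, design$nuclear_radius_um[1],
                       design$nuclear_radius_um[2]) * f_vol^(1/3)
  axes <- matrix(0, n_cells, 3) # semi-axes (y, x, z) in um
  for (i in seq_len(n_cells)) {
    u <- stats::runif(3, 0.8, 1.2)
    u <- u / prod(u)^(1/3) # volume-preserving anisotropy
    axes[i, ] <- radii[i] * u
  }
  centers <- matrix(NA_real_, n_cells, 3) # (z, y, x) um
  placed <- 0L; attempts <- 0L
  zmid <- lz / 2
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 10000L)
      stop(sprintf("phantom placement failed for well %s field %d after 10000 attempts",
                   well, field))
    i <- placed + 1L
    my <- axes[i, 1] + 0.5; mx <- axes[i, 2] + 0.5; mz <- axes[i, 3] + 0.25
    if (2 * my >= ly || 2 * mx >= lx || 2 * mz >= lz)
      stop(sprintf("nucleus too large for the field (well %s field %d)", well, field))
    cy <- stats::runif(1, my, ly - my)
    cx <- stats::runif(1, mx, lx - mx)
    cz <- min(max(zmid + stats::runif(1, -0.5, 0.5), mz), lz - mz)
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 2] - cy)^2 +
                (centers[seq_len(placed), 3] - cx)^2)
      if (min(d) < design$min_center_spacing_um) next
    }
    centers[i, ] <- c(cz, cy, cx)
    placed <- i
  }
  s_cell <- exp(stats::rnorm(n_cells, 0, design$intensity_cv))

  # --- plant foci -----------------------------------------------------------
  frange <- design$foci_per_nucleus
  n_foci <- if (frange[2] > frange[1])
    sample(seq(frange[1], frange[2]), n_cells, replace = TRUE) else
    rep(frange[1], n_cells)
  marker_ch <- names(design$channel_baselines)[vapply(
    design$channel_baselines, function(b) b$focus_amplitude > 0, logical(1))]
  marker_ch <- if (length(marker_ch)) marker_ch[1] else NA_character_
  foci_list <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (n_foci[i] == 0) next
    # floor at 0.65 z-steps: smaller foci are sub-resolution axially and
    # can fall between slice centres entirely (floored before the area
    # factor, so condition ratios stay exact)
    fr <- pmax(rtrunc_norm(n_foci[i], design$focus_radius_um[1],
                           design$focus_radius_um[2]),
               0.65 * design$z_step) * sqrt(f_area)
    fc <- matrix(0, n_foci[i], 3)
    placed_all <- FALSE
    for (restart in 1:2000) {
      if (restart > 1) # redraw radii: some draws admit no feasible packing
        fr <- pmax(rtrunc_norm(n_foci[i], design$focus_radius_um[1],
                               design$focus_radius_um[2]),
                   0.65 * design$z_step) * sqrt(f_area)
      fr <- pmin(fr, 0.7 * min(axes[i, ]))
      j <- 1L
      while (j <= n_foci[i]) {
        ok <- FALSE
        for (att in 1:100) {
          # uniform inside the ellipsoid shrunk by the focus radius, so the
          # whole focus lies within its owner (ground-truth invariant)
          v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
          t <- stats::runif(1)^(1/3)
          # shrunk semi-axes in (z, y, x) order
          p <- centers[i, ] + t * v * c(axes[i, 3] - fr[j], axes[i, 1] - fr[j],
                                        axes[i, 2] - fr[j])
          if (j == 1) { ok <- TRUE } else {
            prev <- fc[seq_len(j - 1), , drop = FALSE]
            rsum <- fr[j] + fr[seq_len(j - 1)]
            dxy <- sqrt((prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2)
            dzc <- abs(prev[, 1] - p[1])
            # resolvable pairs only: in-plane supports separated by several
            # pixels plus the blur halo, or enough axial clearance that an
            # empty slice lies between the two foci
            xy_margin <- max(0.6, 3 * design$pixel_size_xy) +
              2 * design$psf_sigma_um
            ok <- all(dxy >= rsum + xy_margin |
                      dzc - rsum >= 1.5 * design$z_step)
          }
          if (ok) { fc[j, ] <- p; break }
        }
        if (!ok) break # restart the whole set
        j <- j + 1L
      }
      if (j > n_foci[i]) { placed_all <- TRUE; break }
    }
    if (!placed_all)
      stop(sprintf("could not place %d disjoint foci in cell %d (well %s field %d)",
                   n_foci[i], i, well, field))
    amp <- if (is.na(marker_ch)) rep(0, n_foci[i]) else
      design$channel_baselines[[marker_ch]]$focus_amplitude * f_famp * s_cell[i]
    foci_list[[i]] <- data.frame(cell = i, focus = seq_len(n_foci[i]),
                                 cz_um = fc[, 1], cy_um = fc[, 2],
                                 cx_um = fc[, 3], radius_um = fr,
                                 amplitude = amp)
  }

  # --- render ---------------------------------------------------------------
  chans <- lapply(design$channel_baselines, function(b) array(0, c(ny, nx, nz)))
  ycent <- (seq_len(ny) - 0.5) * px
  xcent <- (seq_len(nx) - 0.5) * px
  zcent <- (seq_len(nz) - 0.5) * dz
  add_ellipsoid <- function(arr, c_zyx, sa_yxz, value) {
    yi <- idx_range(c_zyx[2] - sa_yxz[1], c_zyx[2] + sa_yxz[1], px, ny)
    xi <- idx_range(c_zyx[3] - sa_yxz[2], c_zyx[3] + sa_yxz[2], px, nx)
    zi <- idx_range(c_zyx[1] - sa_yxz[3], c_zyx[1] + sa_yxz[3], dz, nz)
    if (!length(yi) || !length(xi) || !length(zi)) return(arr)
    ey <- ((ycent[yi] - c_zyx[2]) / sa_yxz[1])^2
    ex <- ((xcent[xi] - c_zyx[3]) / sa_yxz[2])^2
    ez <- ((zcent[zi] - c_zyx[1]) / sa_yxz[3])^2
    m <- outer(outer(ey, ex, `+`), ez, `+`) <= 1
    sub <- arr[yi, xi, zi, drop = FALSE]
    sub[m] <- sub[m] + value
    arr[yi, xi, zi] <- sub
    arr
  }
  for (i in seq_len(n_cells)) {
    for (ch in names(chans)) {
      b <- design$channel_baselines[[ch]]
      namp <- b$nucleus_amplitude
      if (ch != design$dapi_channel) namp <- namp * f_namp
      namp <- namp * s_cell[i]
      if (namp > 0)
        chans[[ch]] <- add_ellipsoid(chans[[ch]], centers[i, ], axes[i, ], namp)
      camp <- b$cyto_amplitude * f_camp * s_cell[i]
      if (camp > 0) {
        # dim cytoplasmic shell: enlarged ellipsoid minus the nucleus
        chans[[ch]] <- add_ellipsoid(chans[[ch]], centers[i, ],
                                     axes[i, ] + design$cyto_shell_um, camp)
        chans[[ch]] <- add_ellipsoid(chans[[ch]], centers[i, ], axes[i, ], -camp)
      }
    }
    fl <- foci_list[[i]]
    if (!is.null(fl) && !is.na(marker_ch)) {
      for (j in seq_len(nrow(fl))) {
        chans[[marker_ch]] <- add_ellipsoid(
          chans[[marker_ch]],
          c(fl$cz_um[j], fl$cy_um[j], fl$cx_um[j]),
          rep(fl$radius_um[j], 3), fl$amplitude[j])
      }
    }
  }
  for (ch in names(chans)) {
    b <- design$channel_baselines[[ch]]
    if (b$background != 0) chans[[ch]] <- chans[[ch]] + b$background
    if (design$psf_sigma_um > 0)
      chans[[ch]] <- blur_3d(chans[[ch]], design$psf_sigma_um / px,
                             design$psf_sigma_um / px,
                             design$psf_sigma_um / dz)
    if (isTRUE(design$noise$poisson)) {
      v <- stats::rpois(length(chans[[ch]]), pmax(chans[[ch]], 0))
      chans[[ch]] <- array(as.numeric(v), dim = c(ny, nx, nz))
    }
    if (design$noise$read_sd > 0)
      chans[[ch]] <- chans[[ch]] +
        array(stats::rnorm(ny * nx * nz, 0, design$noise$read_sd), c(ny, nx, nz))
  }

  cells <- data.frame(condition = condition, well = well, field = field,
                      cell = seq_len(n_cells),
                      cz_um = centers[, 1], cy_um = centers[, 2],
                      cx_um = centers[, 3], radius_um = radii,
                      sa_y_um = axes[, 1], sa_x_um = axes[, 2],
                      sa_z_um = axes[, 3],
                      volume_um3 = 4 / 3 * pi * axes[, 1] * axes[, 2] * axes[, 3],
                      n_foci = n_foci, intensity_factor = s_cell)
  foci <- if (any(!vapply(foci_list, is.null, logical(1)))) {
    f <- do.call(rbind, foci_list)
    cbind(data.frame(condition = condition, well = well, field = field),
          f)
  } else {
    data.frame(condition = character(), well = character(), field = integer(),
               cell = integer(), focus = integer(), cz_um = numeric(),
               cy_um = numeric(), cx_um = numeric(), radius_um = numeric(),
               amplitude = numeric())
  }
  list(grid = voxel_grid(chans, px, dz), cells = cells, foci = foci)
}

field_seed <- function(seed, well_index, field_index) {
  as.integer((abs(as.numeric(seed)) * 97 + well_index * 131071 +
              field_index * 8191) %% 2147483647)
}

#' Generate a whole synthetic plate with ground truth
#'
#' Wells are labelled `W01, W02, ...` across conditions in order; fields are
#' numbered within wells. Each field gets a deterministic seed derived from
#' `design$seed`, so the whole plate is reproducible bit-for-bit.
#'
#' @param design a [phantom_design()].
#' @return list with `stacks` (named list of [voxel_grid()], keys
#'   `"W01_F01"`), `truth` (list of `cells`, `foci`, `factors` data.frames)
#'   and `layout` (data.frame well, condition).
#' @export
make_plate_phantom <- function(design) {
  stopifnot(inherits(design, "phantom_design"))
  stacks <- list(); cells <- list(); foci <- list(); layout <- list()
  wi <- 0L
  for (cond in design$conditions) {
    for (w in seq_len(design$wells_per_condition)) {
      wi <- wi + 1L
      well <- sprintf("W%02d", wi)
      layout[[wi]] <- data.frame(well = well, condition = cond)
      for (f in seq_len(design$fields_per_well)) {
        set.seed(field_seed(design$seed, wi, f))
        fld <- simulate_field(design, cond, well, f)
        stacks[[sprintf("%s_F%02d", well, f)]] <- fld$grid
        cells[[length(cells) + 1L]] <- fld$cells
        foci[[length(foci) + 1L]] <- fld$foci
      }
    }
  }
  factors <- design$effect_table
  list(stacks = stacks,
       truth = list(cells = do.call(rbind, cells),
                    foci = do.call(rbind, foci),
                    factors = factors),
       layout = do.call(rbind, layout))
}
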