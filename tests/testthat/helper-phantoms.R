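# Shared fixtures, all generated in code at test time.

# Clean (noise-free, unblurred) design with well-separated nuclei: centre
# spacing 12 um exceeds twice the largest possible nuclear radius
# ((4 + 3 * 0.25) * 1.2 = 5.7 um), so 3D supports never touch.
clean_design <- function(cells_per_field = 5, fields = 1, seed = 1, ...) {
  args <- list(
    conditions = "EV",
    wells_per_condition = 1, fields_per_well = fields,
    cells_per_field = cells_per_field,
    image_shape = c(14, 128, 128),
    channel_baselines = list(
      dapi = list(background = 0, nucleus_amplitude = 100,
                  focus_amplitude = 0, cyto_amplitude = 0),
      marker = list(background = 0, nucleus_amplitude = 0,
                    focus_amplitude = 100, cyto_amplitude = 0)),
    noise = list(read_sd = 0, poisson = FALSE),
    psf_sigma_um = 0,
    min_center_spacing_um = 12,
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_design, args)
}

# Pipeline/linking settings under which slice linking must reproduce plain
# 3D connected components exactly: no smoothing, fixed half-amplitude
# threshold, no size gating, no gap bridging.
oracle_config <- function() {
  pipeline_config(
    segmentation = segmentation_params(smooth_sigma_px = 0, threshold = 50,
                                       min_area_px2 = 1, fill_holes = FALSE),
    linking = link_params(max_link_dist_um = 2, max_z_gap = 0,
                          min_slices = 1, border_policy = "keep"),
    foci = foci_params(channel = "marker", min_area_px2 = 1,
                       max_area_px2 = 2000, scale_px = 2),
    foci_linking = link_params(max_link_dist_um = 2, max_z_gap = 0,
                               min_slices = 1, border_policy = "keep"),
    compute_cytoplasm = FALSE)
}

# One clean field with its ground truth, deterministic in `seed`.
clean_field <- function(seed, cells_per_field = 5, ...) {
  d <- clean_design(cells_per_field = cells_per_field, seed = seed, ...)
  set.seed(seed)
  simulate_field(d, "EV", "W01", 1L)
}

# Draw a filled disc of the given value into a matrix (1-based px centre).
draw_disc <- function(mat, cy, cx, r, value) {
  ys <- seq_len(nrow(mat)); xs <- seq_len(ncol(mat))
  m <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  mat[m] <- mat[m] + value
  mat
}

# label_slice built from synthetic disc images through the public API.
disc_label_slice <- function(z, centers, r, ny = 64, nx = 64, value = 100) {
  img <- matrix(0, ny, nx)
  for (cc in centers) img <- draw_disc(img, cc[1], cc[2], r, value)
  segment_nuclei_slice(img, segmentation_params(smooth_sigma_px = 0,
                                                threshold = value / 2,
                                                min_area_px2 = 1,
                                                fill_holes = FALSE), z = z)
}

# Canonical form of a voxel partition: sorted list of sorted voxel sets.
canonical_partition <- function(sets) {
  sets <- lapply(unname(sets), function(s) sort(as.numeric(s)))
  sets[order(vapply(sets, min, numeric(1)))]
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (independent oracle; assumes no ties).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# The 50-phantom clean suite used by the oracle-equivalence and
# foci-registration acceptance checks; generated once per session.
.suite_cache <- new.env(parent = emptyenv())
get_clean_suite <- function(n = 50) {
  key <- paste0("suite", n)
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  suite <- lapply(seq_len(n), function(i)
    clean_field(seed = 9000 + i, cells_per_field = 5))
  .suite_cache[[key]] <- suite
  suite
}

# Match each truth row to the nearest detected object centroid (um).
nearest_object <- function(objects, cz, cy, cx) {
  d <- vapply(objects, function(o)
    sqrt((o$centroid_um["z"] - cz)^2 + (o$centroid_um["y"] - cy)^2 +
         (o$centroid_um["x"] - cx)^2), numeric(1))
  which.min(d)
}
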