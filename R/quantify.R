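#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects for the cyto-nuclear and foci
#' pipelines.
#'
#' @param segmentation a [segmentation_params()].
#' @param foci a [foci_params()].
#' @param linking a [link_params()] for nuclei.
#' @param foci_linking a [link_params()] for foci (min_slices 1).
#' @param cytoplasm a [cyto_params()].
#' @param dapi_channel nuclear-stain channel name.
#' @param compute_cytoplasm quantify the cytoplasmic shell per nucleus.
#' @param min_cells_per_well wells with fewer contributing cells are flagged
#'   `low_n` in summaries (never dropped).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            foci = foci_params(),
                            linking = link_params(),
                            foci_linking = link_params(min_slices = 1,
                                                       max_z_gap = 0),
                            cytoplasm = cyto_params(),
                            dapi_channel = "dapi",
                            compute_cytoplasm = TRUE,
                            min_cells_per_well = 50) {
  structure(list(segmentation = segmentation, foci = foci, linking = linking,
                 foci_linking = foci_linking, cytoplasm = cytoplasm,
                 dapi_channel = dapi_channel,
                 compute_cytoplasm = compute_cytoplasm,
                 min_cells_per_well = min_cells_per_well),
            class = "pipeline_config")
}

#' Pipeline configuration matched to a phantom design
#'
#' Convenience constructor: fixed DAPI threshold at background plus half the
#' nuclear amplitude (the half-maximum boundary of the blurred edge), area
#' gates scaled from the design's radii, and the detector pointed at the
#' design's foci channel.
#'
#' @param design a [phantom_design()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
preset_pipeline_config <- function(design, ...) {
  b <- design$channel_baselines[[design$dapi_channel]]
  thr <- b$background + b$nucleus_amplitude / 2
  px <- design$pixel_size_xy
  marker <- names(design$channel_baselines)[vapply(
    design$channel_baselines, function(x) x$focus_amplitude > 0, logical(1))]
  marker <- if (length(marker)) marker[1] else "marker"
  min_area <- max(4, 0.05 * pi * (design$nuclear_radius_um[1] / px)^2)
  args <- list(
    segmentation = segmentation_params(smooth_sigma_px = 0.7,
                                       threshold = thr,
                                       min_area_px2 = min_area),
    foci = foci_params(channel = marker, min_area_px2 = 3,
                       max_area_px2 = 10 * pi * (design$focus_radius_um[1] / px)^2,
                       scale_px = max(1.5, design$focus_radius_um[1] / px / 1.5)),
    dapi_channel = design$dapi_channel,
    compute_cytoplasm = FALSE)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

segment_stack <- function(stack, config) {
  if (!config$dapi_channel %in% names(stack$channels))
    stop(sprintf("stack has no DAPI channel '%s'", config$dapi_channel))
  dapi <- get_channel(stack, config$dapi_channel)
  nz <- dim(dapi)[3]
  lapply(seq_len(nz) - 1L, function(z)
    segment_nuclei_slice(dapi[, , z + 1L], config$segmentation, z = z))
}

nuclei_from_slices <- function(slices, stack, config) {
  nuc <- link_slices(slices, c(stack$pixel_size_xy, stack$z_step),
                     config$linking)
  if (config$linking$border_policy == "drop")
    nuc <- nuc[!vapply(nuc, function(n) n$touches_border, logical(1))]
  for (i in seq_along(nuc)) nuc[[i]]$id <- i
  nuc
}

empty_cell_records <- function(channels, with_cyto, with_foci) {
  base <- data.frame(well = character(), field = integer(),
                     nucleus_id = integer(), nuclear_volume_um3 = numeric(),
                     touches_border = logical())
  for (ch in channels) {
    base[[paste0("nuclear_mean_", ch)]] <- numeric()
    base[[paste0("nuclear_integrated_", ch)]] <- numeric()
    if (with_cyto) {
      base[[paste0("cyto_mean_", ch)]] <- numeric()
      base[[paste0("cyto_integrated_", ch)]] <- numeric()
    }
  }
  if (with_foci) {
    base$foci_count <- integer()
    base$foci_mean_area_px2 <- numeric()
    base$foci_mean_area_um2 <- numeric()
    base$foci_total_volume_um3 <- numeric()
    base$nucleolar_mean_intensity <- numeric()
  }
  base
}

nuclear_records <- function(nuclei, stack, config, well, field) {
  chans <- names(stack$channels)
  if (!length(nuclei))
    return(empty_cell_records(chans, config$compute_cytoplasm, FALSE))
  rows <- lapply(nuclei, function(n) {
    r <- data.frame(well = well, field = field, nucleus_id = n$id,
                    nuclear_volume_um3 = n$volume_um3,
                    touches_border = n$touches_border)
    for (ch in chans) {
      m <- integrate_object(n, stack, ch)
      r[[paste0("nuclear_mean_", ch)]] <- m$mean
      r[[paste0("nuclear_integrated_", ch)]] <- m$integrated
    }
    if (config$compute_cytoplasm) {
      shell <- cytoplasm_region(n, nuclei, config$cytoplasm)
      for (ch in chans) {
        v <- get_channel(stack, ch)[shell]
        r[[paste0("cyto_mean_", ch)]] <- if (length(v)) mean(v) else NA_real_
        r[[paste0("cyto_integrated_", ch)]] <- sum(v)
      }
    }
    r
  })
  do.call(rbind, rows)
}

#' Cyto-nuclear analysis of one stack
#'
#' Per-slice nuclear segmentation, 3D linking, per-channel volumetric
#' integration over the nuclear mask and (optionally) over a cytoplasmic
#' shell. Border nuclei are handled per the linking `border_policy`.
#'
#' @param stack a [voxel_grid()] with a DAPI channel.
#' @param config a [pipeline_config()].
#' @param well,field identifiers stamped on the records.
#' @return data.frame of per-cell records.
#' @export
cyto_nuclear_pipeline <- function(stack, config = pipeline_config(),
                                  well = "W01", field = 1L) {
  slices <- segment_stack(stack, config)
  nuclei <- nuclei_from_slices(slices, stack, config)
  nuclear_records(nuclei, stack, config, well, field)
}

#' Foci analysis of one stack
#'
#' Starts from the same nuclear segmentation as the cyto-nuclear pipeline,
#' detects bright foci in the configured marker channel on every axial
#' section, links them in 3D, registers each focus to its host nucleus by
#' centroid containment, and fills the per-cell foci aggregates (unassigned
#' foci are excluded).
#'
#' @inheritParams cyto_nuclear_pipeline
#' @return data.frame of per-cell records including foci metrics.
#' @export
foci_pipeline <- function(stack, config = pipeline_config(), well = "W01",
                          field = 1L) {
  fch <- config$foci$channel
  if (!fch %in% names(stack$channels))
    stop(sprintf("stack has no foci channel '%s'", fch))
  slices <- segment_stack(stack, config)
  nuclei <- nuclei_from_slices(slices, stack, config)
  rec <- nuclear_records(nuclei, stack, config, well, field)
  if (!nrow(rec)) {
    return(empty_cell_records(names(stack$channels),
                              config$compute_cytoplasm, TRUE))
  }
  marker <- get_channel(stack, fch)
  foci2d <- lapply(seq_along(slices), function(i)
    detect_foci_slice(marker[, , i], slices[[i]], config$foci))
  foci3d <- link_foci(foci2d, dim(marker),
                      c(stack$pixel_size_xy, stack$z_step),
                      config$foci_linking)
  foci3d <- assign_foci(foci3d, nuclei)
  px <- stack$pixel_size_xy
  rec$foci_count <- 0L
  rec$foci_mean_area_px2 <- NA_real_
  rec$foci_mean_area_um2 <- NA_real_
  rec$foci_total_volume_um3 <- 0
  rec$nucleolar_mean_intensity <- NA_real_
  if (length(foci3d)) {
    hosts <- vapply(foci3d, function(f) f$host_nucleus_id, integer(1))
    for (i in seq_len(nrow(rec))) {
      mine <- foci3d[hosts == rec$nucleus_id[i]]
      if (!length(mine)) next
      areas <- unlist(lapply(mine, function(f) f$members$area))
      vox <- unlist(lapply(mine, function(f) f$voxels))
      rec$foci_count[i] <- length(mine)
      rec$foci_mean_area_px2[i] <- mean(areas)
      rec$foci_mean_area_um2[i] <- mean(areas) * px * px
      rec$foci_total_volume_um3[i] <- sum(vapply(mine, function(f)
        f$volume_um3, numeric(1)))
      rec$nucleolar_mean_intensity[i] <- mean(marker[vox])
    }
  }
  rec
}

#' Per-well summaries of per-cell metrics
#'
#' @param records data.frame of cell records (one row per cell).
#' @param layout data.frame with columns `well`, `condition`.
#' @param min_cells wells with fewer cells are flagged `low_n`, never
#'   dropped.
#' @return long data.frame: well, condition, n_cells, metric, mean, median,
#'   sd, low_n.
#' @export
summarize_wells <- function(records, layout, min_cells = 50) {
  stopifnot(all(c("well", "condition") %in% names(layout)))
  unknown <- setdiff(unique(records$well), layout$well)
  if (length(unknown))
    stop("wells missing from layout: ", paste(unknown, collapse = ", "))
  metrics <- names(records)[vapply(records, is.numeric, logical(1))]
  metrics <- setdiff(metrics, c("field", "nucleus_id"))
  out <- list()
  for (w in unique(records$well)) {
    sub <- records[records$well == w, , drop = FALSE]
    cond <- layout$condition[match(w, layout$well)]
    for (m in metrics) {
      v <- sub[[m]][is.finite(sub[[m]])]
      out[[length(out) + 1L]] <- data.frame(
        well = w, condition = cond, n_cells = nrow(sub), metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        low_n = nrow(sub) < min_cells)
    }
  }
  do.call(rbind, out)
}

#' Percent change of group means
#'
#' `100 * (mean(treated) - mean(control)) / mean(control)`.
#'
#' @param control,treated numeric vectors.
#' @return percent change.
#' @export
percent_change <- function(control, treated) {
  100 * (mean(treated) - mean(control)) / mean(control)
}

#' Condition-level effect ratio with Monte-Carlo standard error
#'
#' Ratio of per-cell metric means between a condition and the control, with
#' the delta-method standard error used to judge recovery of an injected
#' multiplicative factor.
#'
#' @param records cell records.
#' @param layout well-to-condition map.
#' @param metric metric column name.
#' @param condition,control condition names.
#' @return list with `ratio`, `se`, `n` per group and the two samples.
#' @export
condition_effect <- function(records, layout, metric, condition, control) {
  cond_of <- layout$condition[match(records$well, layout$well)]
  x <- records[[metric]][cond_of == control]
  y <- records[[metric]][cond_of == condition]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  ratio <- mean(y) / mean(x)
  se <- ratio * sqrt(stats::var(y) / (length(y) * mean(y)^2) +
                     stats::var(x) / (length(x) * mean(x)^2))
  list(ratio = ratio, se = se, n = c(control = length(x),
                                     condition = length(y)),
       control_values = x, condition_values = y)
}

#' Simulate and quantify a whole phantom plate, field by field
#'
#' Streams the plate: each field is generated with its deterministic seed,
#' quantified with the chosen pipeline, and discarded, so memory stays
#' bounded regardless of plate size.
#'
#' @param design a [phantom_design()].
#' @param config a [pipeline_config()]; default derives one from the design.
#' @param pipeline `"foci"` or `"cyto"`.
#' @return list with `records` (cell records), `layout`, and `truth_cells`.
#' @export
run_plate <- function(design, config = preset_pipeline_config(design),
                      pipeline = c("foci", "cyto")) {
  pipeline <- match.arg(pipeline)
  records <- list(); layout <- list(); truth <- list()
  wi <- 0L
  for (cond in design$conditions) {
    for (w in seq_len(design$wells_per_condition)) {
      wi <- wi + 1L
      well <- sprintf("W%02d", wi)
      layout[[wi]] <- data.frame(well = well, condition = cond)
      for (f in seq_len(design$fields_per_well)) {
        set.seed(field_seed(design$seed, wi, f))
        fld <- simulate_field(design, cond, well, f)
        rec <- if (pipeline == "foci")
          foci_pipeline(fld$grid, config, well, f) else
          cyto_nuclear_pipeline(fld$grid, config, well, f)
        records[[length(records) + 1L]] <- rec
        truth[[length(truth) + 1L]] <- fld$cells
      }
    }
  }
  list(records = do.call(rbind, records), layout = do.call(rbind, layout),
       truth_cells = do.call(rbind, truth))
}
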