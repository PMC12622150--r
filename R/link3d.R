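#' Parameters for nearest-neighbour z-linking
#'
#' @param max_link_dist_um maximum in-plane centroid distance (micrometres)
#'   for linking components on adjacent (or gap-bridged) slices.
#' @param max_z_gap number of missing slices an object may bridge.
#' @param min_slices minimum member slices for a valid 3D object (use 1 for
#'   foci).
#' @param border_policy `"keep"` or `"drop"` for objects touching the xy
#'   image border (applied by the pipelines, not by the linker itself).
#' @return object of class `link_params`.
#' @export
link_params <- function(max_link_dist_um = 2, max_z_gap = 1, min_slices = 2,
                        border_policy = c("drop", "keep")) {
  if (max_link_dist_um <= 0) stop("max_link_dist_um must be > 0")
  if (max_z_gap < 0) stop("max_z_gap must be >= 0")
  if (min_slices < 1) stop("min_slices must be >= 1")
  structure(list(max_link_dist_um = max_link_dist_um,
                 max_z_gap = as.integer(max_z_gap),
                 min_slices = as.integer(min_slices),
                 border_policy = match.arg(border_policy)),
            class = "link_params")
}

# Generic greedy nearest-neighbour linker over per-slice component lists.
# Each slice entry: list(z = 0-based index, comps = data.frame(label, cy, cx
# [0-based px], area, border), pixels = list of in-slice linear indices).
# Matching between consecutive (or gap-bridged) slices is one-to-one and
# greedy by ascending centroid distance, ties broken by larger 2D pixel
# overlap, then smaller current-slice label, then smaller previous label, so
# the partition is invariant to label permutation except as a final resort.
link_core <- function(slice_comps, calib, params) {
  px <- calib[1]
  zs <- vapply(slice_comps, function(s) s$z, numeric(1))
  if (any(duplicated(zs))) stop("duplicated z among slices")
  if (is.unsorted(zs, strictly = TRUE)) stop("slices must be ordered by z")
  objs <- list() # each: members df, pixels (list by member), last_* cache
  open <- integer(0)
  for (s in slice_comps) {
    z <- s$z
    comps <- s$comps
    # close objects that can no longer be bridged
    if (length(open)) {
      gap <- z - vapply(objs[open], function(o) o$last_z, numeric(1)) - 1
      open <- open[gap <= params$max_z_gap]
    }
    matched_obj <- integer(0); matched_comp <- integer(0)
    if (length(open) && nrow(comps)) {
      oy <- vapply(objs[open], function(o) o$last_cy, numeric(1))
      ox <- vapply(objs[open], function(o) o$last_cx, numeric(1))
      d <- outer(oy, comps$cy, `-`)^2 + outer(ox, comps$cx, `-`)^2
      d <- sqrt(d) * px
      cand <- which(d <= params$max_link_dist_um, arr.ind = TRUE)
      if (nrow(cand)) {
        ov <- numeric(nrow(cand))
        for (r in seq_len(nrow(cand))) {
          o <- objs[[open[cand[r, 1]]]]
          ov[r] <- length(intersect(o$last_pixels, s$pixels[[cand[r, 2]]]))
        }
        ord <- order(d[cand], -ov,
                     comps$label[cand[, 2]],
                     vapply(objs[open[cand[, 1]]], function(o) o$last_label,
                            numeric(1)))
        used_o <- logical(length(open)); used_c <- logical(nrow(comps))
        for (r in ord) {
          io <- cand[r, 1]; ic <- cand[r, 2]
          if (used_o[io] || used_c[ic]) next
          used_o[io] <- TRUE; used_c[ic] <- TRUE
          matched_obj <- c(matched_obj, open[io])
          matched_comp <- c(matched_comp, ic)
        }
      }
    }
    if (length(matched_comp)) {
      for (r in seq_along(matched_comp)) {
        oi <- matched_obj[r]; ic <- matched_comp[r]
        o <- objs[[oi]]
        o$members <- rbind(o$members,
                           data.frame(z = z, label = comps$label[ic],
                                      area = comps$area[ic],
                                      cy = comps$cy[ic], cx = comps$cx[ic],
                                      border = comps$border[ic]))
        o$pixels[[length(o$pixels) + 1L]] <- s$pixels[[ic]]
        o$last_z <- z; o$last_cy <- comps$cy[ic]; o$last_cx <- comps$cx[ic]
        o$last_label <- comps$label[ic]; o$last_pixels <- s$pixels[[ic]]
        objs[[oi]] <- o
      }
    }
    new_c <- setdiff(seq_len(nrow(comps)), matched_comp)
    for (ic in new_c) {
      objs[[length(objs) + 1L]] <- list(
        members = data.frame(z = z, label = comps$label[ic],
                             area = comps$area[ic], cy = comps$cy[ic],
                             cx = comps$cx[ic], border = comps$border[ic]),
        pixels = list(s$pixels[[ic]]),
        last_z = z, last_cy = comps$cy[ic], last_cx = comps$cx[ic],
        last_label = comps$label[ic], last_pixels = s$pixels[[ic]])
      open <- c(open, length(objs))
    }
    open <- unique(c(open, matched_obj))
  }
  objs[vapply(objs, function(o) nrow(o$members), integer(1)) >=
       params$min_slices]
}

slice_to_comps <- function(sl) {
  labs <- sl$labels
  rec <- sl$components
  pix <- if (nrow(rec)) {
    idx <- which(labs > 0)
    split(idx, labs[idx])[as.character(rec$label)]
  } else list()
  list(z = sl$z,
       comps = data.frame(label = rec$label, cy = rec$centroid_y,
                          cx = rec$centroid_x, area = rec$area,
                          border = rec$touches_border),
       pixels = unname(pix))
}

finish_object <- function(o, id, dims, calib) {
  px <- calib[1]; dz <- calib[2]
  ny <- dims[1]; nx <- dims[2]
  vox <- unlist(mapply(function(p, z) p + as.numeric(ny) * nx * z,
                       o$pixels, o$members$z, SIMPLIFY = FALSE),
                use.names = FALSE)
  areas <- o$members$area
  voxel_count <- sum(areas)
  w <- areas / voxel_count
  structure(list(
    id = id,
    members = o$members[, c("z", "label", "area")],
    voxels = as.numeric(vox),
    voxel_count = voxel_count,
    volume_um3 = voxel_count * px^2 * dz,
    centroid_um = c(z = sum(w * (o$members$z + 0.5) * dz),
                    y = sum(w * (o$members$cy + 0.5) * px),
                    x = sum(w * (o$members$cx + 0.5) * px)),
    touches_border = any(o$members$border),
    dims = dims, pixel_size_xy = px, z_step = dz),
    class = "object3d")
}

#' Assemble per-slice nuclear components into 3D objects
#'
#' Greedy one-to-one nearest-neighbour matching of component centroids
#' between consecutive (or gap-bridged) axial sections under a distance cap,
#' followed by volumetric integration. The volume identity
#' `volume_um3 == voxel_count * pixel_size_xy^2 * z_step` holds exactly.
#'
#' @param slices ordered list of `label_slice` objects (strictly increasing
#'   z, no duplicates).
#' @param calib numeric `(pixel_size_xy, z_step)` in micrometres.
#' @param params a [link_params()].
#' @return list of `object3d`: each has `id`, `members` (z, slice label,
#'   area), `voxels` (1-based linear indices into the stack), `voxel_count`,
#'   `volume_um3`, `centroid_um` (z, y, x), `touches_border`, and the grid
#'   geometry.
#' @export
link_slices <- function(slices, calib, params = link_params()) {
  if (!length(slices)) return(list())
  dims <- c(dim(slices[[1]]$labels), length(slices))
  zmax <- max(vapply(slices, function(s) s$z, numeric(1)))
  dims[3] <- max(dims[3], zmax + 1)
  comps <- lapply(slices, slice_to_comps)
  objs <- link_core(comps, calib, params)
  lapply(seq_along(objs), function(i) finish_object(objs[[i]], i, dims, calib))
}

#' Integrate a channel over a 3D object's voxels
#'
#' @param obj an `object3d` (or linked focus) carrying voxel indices.
#' @param stack a [voxel_grid()] whose dimensions match the object's grid.
#' @param channel channel name.
#' @return list with `mean`, `integrated` (exact voxel sum), `peak`,
#'   `voxel_count`.
#' @export
integrate_object <- function(obj, stack, channel) {
  arr <- get_channel(stack, channel)
  if (!identical(dim(arr), as.integer(obj$dims)))
    stop("stack dimensions do not match the object's grid")
  v <- arr[obj$voxels]
  list(mean = sum(v) / length(v), integrated = sum(v), peak = max(v),
       voxel_count = length(v))
}

#' Parameters for the cytoplasmic shell
#'
#' @param shell_width_um dilation width of the cytoplasmic ring around the
#'   nuclear mask (micrometres, > 0).
#' @param exclude_other_nuclei subtract all nuclear masks from the shell
#'   (not just the owner's).
#' @return object of class `cyto_params`.
#' @export
cyto_params <- function(shell_width_um = 1.5, exclude_other_nuclei = TRUE) {
  if (shell_width_um <= 0) stop("shell_width_um must be > 0")
  structure(list(shell_width_um = shell_width_um,
                 exclude_other_nuclei = exclude_other_nuclei),
            class = "cyto_params")
}

#' Cytoplasmic region around a nucleus
#'
#' Morphological 3D dilation of the nuclear mask by an ellipsoidal kernel of
#' physical width `shell_width_um` (anisotropy-aware: the kernel radius in z
#' is `shell_width_um / z_step`), minus nuclear masks, clipped to the image.
#'
#' @param obj the nucleus (`object3d`).
#' @param all_nuclei list of all `object3d` nuclei in the stack.
#' @param params a [cyto_params()].
#' @return numeric vector of 1-based linear voxel indices of the shell.
#' @export
cytoplasm_region <- function(obj, all_nuclei, params = cyto_params()) {
  dims <- as.integer(obj$dims)
  mask <- logical(prod(dims))
  mask[obj$voxels] <- TRUE
  dim(mask) <- dims
  ry <- max(1L, as.integer(round(params$shell_width_um / obj$pixel_size_xy)))
  rz <- as.integer(round(params$shell_width_um / obj$z_step))
  dil <- .dilate_mask_3d(mask, dims, ry, ry, rz)
  shell <- as.logical(dil)
  if (params$exclude_other_nuclei) {
    for (n in all_nuclei) shell[n$voxels] <- FALSE
  } else {
    shell[obj$voxels] <- FALSE
  }
  which(shell)
}

#' Link per-slice 2D foci into 3D foci
#'
#' Same nearest-neighbour algorithm as [link_slices()], applied to focus
#' records; `min_slices` defaults to 1 so a focus visible on a single slice
#' is retained.
#'
#' @param foci_by_slice list of data.frames from [detect_foci_slice()] (one
#'   per slice, ordered by z; empty frames allowed).
#' @param dims stack dimensions `(ny, nx, nz)`.
#' @param calib numeric `(pixel_size_xy, z_step)`.
#' @param params a [link_params()]; `min_slices` is forced to >= 1 only.
#' @return list of linked foci (`object3d` with `host_nucleus_id = 0`).
#' @export
link_foci <- function(foci_by_slice, dims, calib,
                      params = link_params(min_slices = 1)) {
  keep <- vapply(foci_by_slice, nrow, integer(1)) > 0
  fb <- foci_by_slice[keep]
  if (!length(fb)) return(list())
  comps <- lapply(fb, function(f) {
    list(z = f$z[1],
         comps = data.frame(label = f$label, cy = f$centroid_y,
                            cx = f$centroid_x, area = f$area,
                            border = FALSE),
         pixels = f$pixels)
  })
  objs <- link_core(comps, calib, params)
  out <- lapply(seq_along(objs), function(i)
    finish_object(objs[[i]], i, dims, calib))
  for (i in seq_along(out)) out[[i]]$host_nucleus_id <- 0L
  out
}

#' Register foci to their host nuclei
#'
#' A focus is assigned to the unique nucleus whose 3D mask contains the
#' voxel under the focus centroid; otherwise `host_nucleus_id` stays 0 and
#' the focus is excluded from per-cell metrics downstream.
#'
#' @param foci list of linked foci from [link_foci()].
#' @param nuclei list of `object3d` nuclei (disjoint masks).
#' @return `foci` with `host_nucleus_id` set.
#' @export
assign_foci <- function(foci, nuclei) {
  if (!length(foci)) return(foci)
  dims <- as.integer(foci[[1]]$dims)
  labarr <- integer(prod(dims))
  for (n in nuclei) labarr[n$voxels] <- n$id
  px <- foci[[1]]$pixel_size_xy; dz <- foci[[1]]$z_step
  for (i in seq_along(foci)) {
    f <- foci[[i]]
    iy <- min(max(floor(f$centroid_um["y"] / px), 0), dims[1] - 1)
    ix <- min(max(floor(f$centroid_um["x"] / px), 0), dims[2] - 1)
    iz <- min(max(floor(f$centroid_um["z"] / dz), 0), dims[3] - 1)
    idx <- 1 + iy + dims[1] * ix + as.numeric(dims[1]) * dims[2] * iz
    foci[[i]]$host_nucleus_id <- labarr[idx]
  }
  foci
}

#' Brute-force 3D connected-component labelling
#'
#' Direct 26-connected labelling of a boolean stack; the independent oracle
#' route against which slice-wise linking is validated.
#'
#' @param mask 3D logical array.
#' @return integer array of component labels (0 = background).
#' @export
label_3d_components <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  .cc_label_3d(as.logical(mask), dim(mask))
}
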