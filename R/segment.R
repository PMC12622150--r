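#' Parameters for per-slice nuclear segmentation
#'
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels (0 = none);
#'   smoothing informs the boundary only, intensity gates use the raw image.
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param min_area_px2,max_area_px2 component area gate in px^2.
#' @param min_mean_intensity minimum raw mean intensity per component.
#' @param fill_holes fill enclosed background holes in the binary mask.
#' @param split_touching split touching nuclei by distance-transform
#'   watershed.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma_px = 1,
                                threshold = "otsu",
                                min_area_px2 = 50,
                                max_area_px2 = Inf,
                                min_mean_intensity = 0,
                                fill_holes = TRUE,
                                split_touching = FALSE) {
  if (smooth_sigma_px < 0) stop("smooth_sigma_px must be >= 0")
  if (!(min_area_px2 > 0 && min_area_px2 < max_area_px2))
    stop("need 0 < min_area_px2 < max_area_px2")
  if (is.character(threshold)) {
    if (!identical(threshold, "otsu")) stop("threshold must be 'otsu' or numeric")
  } else if (!is.numeric(threshold)) stop("threshold must be 'otsu' or numeric")
  structure(list(smooth_sigma_px = smooth_sigma_px, threshold = threshold,
                 min_area_px2 = min_area_px2, max_area_px2 = max_area_px2,
                 min_mean_intensity = min_mean_intensity,
                 fill_holes = fill_holes, split_touching = split_touching),
            class = "segmentation_params")
}

#' Otsu's threshold on a 256-bin histogram
#'
#' @param x numeric vector or matrix of intensities.
#' @return threshold value; `Inf` for a constant input (nothing to separate).
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(Inf)
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nb), nb)
  w <- cumsum(h)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[nb]; mt <- m[nb]
  w0 <- w[-nb]; m0 <- m[-nb]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nb - 1L)
  between[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * w1[valid] / n) / n^2 * n # (w0*w1)*(mu0-mu1)^2 scaled
  k <- which.max(between)
  br[k + 1L]
}

# Recompute (label, centroid, area, mean) records from a label image; the
# single source of truth used both at construction and for verification.
component_records <- function(labels, raw) {
  k <- max(labels)
  if (k == 0)
    return(data.frame(label = integer(), centroid_y = numeric(),
                      centroid_x = numeric(), area = integer(),
                      mean_intensity = numeric(),
                      touches_border = logical()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  ny <- nrow(labels)
  y0 <- (idx - 1) %% ny          # 0-based row
  x0 <- (idx - 1) %/% ny         # 0-based col
  area <- tabulate(lab, k)
  cy <- as.numeric(rowsum(y0, lab)) / area
  cx <- as.numeric(rowsum(x0, lab)) / area
  mi <- as.numeric(rowsum(raw[idx], lab)) / area
  border <- as.logical(tabulate(lab[y0 == 0 | y0 == ny - 1 |
                                    x0 == 0 | x0 == ncol(labels) - 1], k))
  data.frame(label = seq_len(k), centroid_y = cy, centroid_x = cx,
             area = as.integer(area), mean_intensity = mi,
             touches_border = border)
}

# Relabel 1..K contiguously in raster-scan order of first occurrence.
relabel_contiguous <- function(labels, keep) {
  if (!length(keep)) return(matrix(0L, nrow(labels), ncol(labels)))
  map <- integer(max(labels))
  # order kept labels by first occurrence in column-major scan
  first <- vapply(keep, function(l) which(labels == l)[1], numeric(1))
  ord <- keep[order(first)]
  map[ord] <- seq_along(ord)
  out <- labels
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  out
}

fill_holes_mask <- function(mask) {
  # background components (4-connected) not touching the border are holes
  bg <- .cc_label_2d(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

split_mask_watershed <- function(mask) {
  d <- .chamfer_dist_2d(mask)
  comp <- .cc_label_2d(mask, 8L)
  k <- max(comp)
  if (k == 0) return(comp)
  dmax <- vapply(seq_len(k), function(l) max(d[comp == l]), numeric(1))
  markers_mask <- mask & d >= 0.6 * dmax[pmax(comp, 1L)] & comp > 0
  markers <- .cc_label_2d(markers_mask, 8L)
  if (max(markers) <= k) return(comp) # nothing to split
  .watershed_2d(-d, markers, mask)
}

#' Segment nuclei on one axial slice
#'
#' Smoothing, thresholding (Otsu or fixed), optional hole filling and
#' watershed splitting, then size and raw-intensity gating with contiguous
#' relabelling. Deterministic; 2D connectivity is 8-connected.
#'
#' @param dapi_slice 2D numeric matrix of nuclear-stain intensities.
#' @param params a [segmentation_params()].
#' @param z 0-based slice index recorded in the result.
#' @return a `label_slice`: list with `z`, `labels` (integer matrix, 0 =
#'   background, components labelled 1..K), and `components` (data.frame of
#'   per-component records with 0-based pixel centroids).
#' @export
segment_nuclei_slice <- function(dapi_slice, params = segmentation_params(),
                                 z = 0L) {
  if (!is.matrix(dapi_slice) || !length(dapi_slice))
    stop("dapi_slice must be a non-empty 2D matrix")
  if (any(!is.finite(dapi_slice)))
    stop("dapi_slice contains non-finite pixels")
  sm <- if (params$smooth_sigma_px > 0)
    blur_2d(dapi_slice, params$smooth_sigma_px) else dapi_slice
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(sm) else
    as.numeric(params$threshold)
  mask <- sm > thr
  if (!any(mask))
    return(structure(list(z = as.integer(z),
                          labels = matrix(0L, nrow(dapi_slice), ncol(dapi_slice)),
                          components = component_records(
                            matrix(0L, nrow(dapi_slice), ncol(dapi_slice)),
                            dapi_slice)),
                     class = "label_slice"))
  if (params$fill_holes) mask <- fill_holes_mask(mask)
  labels <- if (params$split_touching) split_mask_watershed(mask) else
    .cc_label_2d(mask, 8L)
  rec <- component_records(labels, dapi_slice)
  keep <- rec$label[rec$area >= params$min_area_px2 &
                    rec$area <= params$max_area_px2 &
                    rec$mean_intensity >= params$min_mean_intensity]
  labels <- relabel_contiguous(labels, keep)
  structure(list(z = as.integer(z), labels = labels,
                 components = component_records(labels, dapi_slice)),
            class = "label_slice")
}

#' Parameters for per-slice focus detection
#'
#' @param channel marker channel name the detector runs on.
#' @param min_area_px2,max_area_px2 focus size gate.
#' @param brightness_factor minimum ratio of focus mean to the host nucleus'
#'   nucleoplasmic median (> 1); nucleoplasm = nuclear mask minus candidate
#'   foci.
#' @param detector `"log"` (difference-of-Gaussians blob response) or
#'   `"tophat"` (grayscale disk top-hat), with `scale_px` the blob scale.
#' @param scale_px detector scale in pixels.
#' @param n_sigma robust noise multiple for the candidate response floor.
#' @param restrict_to_nucleus drop foci outside every nuclear mask.
#' @return object of class `foci_params`.
#' @export
foci_params <- function(channel = "marker",
                        min_area_px2 = 4,
                        max_area_px2 = 500,
                        brightness_factor = 2,
                        detector = "log",
                        scale_px = 2,
                        n_sigma = 3,
                        restrict_to_nucleus = TRUE) {
  if (!(min_area_px2 > 0 && min_area_px2 <= max_area_px2))
    stop("focus size gate must satisfy 0 < min <= max")
  if (brightness_factor <= 1) stop("brightness_factor must be > 1")
  if (!detector %in% c("log", "tophat")) stop("detector must be 'log' or 'tophat'")
  structure(list(channel = channel, min_area_px2 = min_area_px2,
                 max_area_px2 = max_area_px2,
                 brightness_factor = brightness_factor,
                 detector = detector, scale_px = scale_px, n_sigma = n_sigma,
                 restrict_to_nucleus = restrict_to_nucleus),
            class = "foci_params")
}

#' Detect candidate nucleolar foci on one slice
#'
#' Computes a blob response (difference-of-Gaussians or disk top-hat),
#' thresholds it at `n_sigma` robust (MAD) noise units, labels candidates
#' (8-connected), gates them by area and by mean raw intensity at least
#' `brightness_factor` times the nucleoplasmic median of the enclosing
#' nucleus, and annotates each focus with its enclosing nuclear label
#' (majority label over the focus pixels; 0 if outside all nuclei).
#'
#' @param marker_slice 2D numeric matrix of marker intensities.
#' @param nuclear_labels a `label_slice` from [segment_nuclei_slice()] of the
#'   same shape.
#' @param params a [foci_params()].
#' @return data.frame of 2D foci: `z`, `label`, `centroid_y`, `centroid_x`
#'   (0-based px), `area`, `mean_intensity`, `peak_intensity`,
#'   `nucleus_label`, plus a `pixels` list-column of linear pixel indices.
#' @export
detect_foci_slice <- function(marker_slice, nuclear_labels,
                              params = foci_params()) {
  if (!identical(dim(marker_slice), dim(nuclear_labels$labels)))
    stop("marker slice and nuclear label image differ in shape")
  nl <- nuclear_labels$labels
  resp <- if (params$detector == "log") {
    blur_2d(marker_slice, params$scale_px) -
      blur_2d(marker_slice, 2 * params$scale_px)
  } else {
    op <- .gray_morph_disk(.gray_morph_disk(marker_slice, params$scale_px + 1,
                                            FALSE),
                           params$scale_px + 1, TRUE) # opening
    marker_slice - op
  }
  inside <- nl > 0
  # robust response-noise scale over the whole slice: blobs and their halos
  # occupy a small fraction of the field, so the MAD ignores them
  ref <- as.numeric(resp)
  sigma <- stats::mad(ref, center = stats::median(ref))
  floor_ <- max(0, params$n_sigma * sigma)
  cand <- resp > floor_
  if (params$restrict_to_nucleus) cand <- cand & inside
  empty <- data.frame(z = integer(), label = integer(), centroid_y = numeric(),
                      centroid_x = numeric(), area = integer(),
                      mean_intensity = numeric(), peak_intensity = numeric(),
                      nucleus_label = integer())
  empty$pixels <- list()
  if (!any(cand)) return(empty)
  # nucleoplasm medians per nucleus: nuclear mask minus all candidate pixels
  nucleo <- inside & !cand
  meds <- rep(NA_real_, max(nl, 1L))
  if (max(nl) > 0) {
    for (l in seq_len(max(nl))) {
      v <- marker_slice[nucleo & nl == l]
      meds[l] <- if (length(v)) stats::median(v) else stats::median(marker_slice[nl == l])
    }
  }
  bg_med <- stats::median(marker_slice[!inside & !cand])
  # refine each seed component to its half-maximum support above the local
  # nucleoplasmic median: recovers the true blob boundary from the generous
  # detector halo and splits touching foci of comparable brightness
  seed <- .cc_label_2d(cand, 8L)
  refined <- matrix(FALSE, nrow(marker_slice), ncol(marker_slice))
  for (sc in seq_len(max(seed))) {
    pix <- which(seed == sc)
    host_tab <- tabulate(nl[pix] + 1L)
    h <- which.max(host_tab) - 1L
    ref_med <- if (h > 0L) meds[h] else bg_med
    if (!is.finite(ref_med)) ref_med <- 0
    pk <- max(marker_slice[pix])
    thr_half <- ref_med + 0.5 * (pk - ref_med)
    refined[pix[marker_slice[pix] >= thr_half]] <- TRUE
  }
  if (!any(refined)) return(empty)
  clab <- .cc_label_2d(refined, 8L)
  k <- max(clab)
  rec <- component_records(clab, marker_slice)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    pix <- which(clab == f)
    host_tab <- tabulate(nl[pix] + 1L)
    host <- which.max(host_tab) - 1L # majority label, 0 = background
    if (params$restrict_to_nucleus && host == 0L) next
    area <- rec$area[f]
    if (area < params$min_area_px2 || area > params$max_area_px2) next
    mn <- rec$mean_intensity[f]
    ref_med <- if (host > 0L) meds[host] else
      stats::median(marker_slice[!inside & !cand])
    if (is.finite(ref_med) &&
        mn < params$brightness_factor * ref_med) next
    out[[f]] <- data.frame(z = nuclear_labels$z, label = f,
                           centroid_y = rec$centroid_y[f],
                           centroid_x = rec$centroid_x[f],
                           area = area, mean_intensity = mn,
                           peak_intensity = max(marker_slice[pix]),
                           nucleus_label = host)
    out[[f]]$pixels <- list(pix)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$label <- seq_len(nrow(res))
  res
}
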