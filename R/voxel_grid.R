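#' Multi-channel z-stack with physical voxel calibration
#'
#' A `voxel_grid` holds one or more fluorescence channels as 3D numeric
#' arrays with identical dimensions `(ny, nx, nz)` plus the physical
#' calibration needed to convert voxel counts into micrometres. Slices are
#' indexed along the third dimension (`arr[, , z]` is an axial section).
#'
#' Coordinate convention: voxel indices are 0-based in all physical
#' formulas; the centre of voxel `(i, j, k)` (0-based) lies at
#' `((i + 0.5) * pixel_size_xy, (j + 0.5) * pixel_size_xy, (k + 0.5) * z_step)`
#' micrometres. R's 1-based array index `r` therefore maps to physical
#' position `(r - 0.5) * spacing`.
#'
#' @param channels named list of 3D numeric arrays, all the same dim.
#' @param pixel_size_xy in-plane pixel size, micrometres.
#' @param z_step axial spacing between consecutive slices, micrometres.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, pixel_size_xy, z_step) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- dim(channels[[1]])
  if (length(dims) != 3) stop("each channel must be a 3D array")
  for (ch in channels) {
    if (!identical(dim(ch), dims)) stop("all channels must share dimensions")
  }
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0)
    stop("pixel_size_xy must be > 0")
  if (!is.numeric(z_step) || z_step <= 0) stop("z_step must be > 0")
  structure(list(channels = channels,
                 pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = as.numeric(z_step)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<voxel_grid> %d x %d px, %d slices; %.3g um/px, %.3g um z-step\n",
              d[1], d[2], d[3], x$pixel_size_xy, x$z_step))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a channel array from a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name.
#' @return the 3D numeric array for that channel.
#' @export
get_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!channel %in% names(grid$channels))
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(names(grid$channels), collapse = ", ")))
  grid$channels[[channel]]
}

grid_dims <- function(grid) dim(grid$channels[[1]])

# Gaussian kernel (normalised, odd length) for a sigma given in pixels.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur of a 3D array
#'
#' Applies an anisotropic separable Gaussian filter with replicate padding.
#' Sigmas are in voxel units per dimension; a sigma of 0 skips that axis.
#'
#' @param arr 3D numeric array.
#' @param sigma_y,sigma_x,sigma_z standard deviations in voxels.
#' @return blurred array of the same dimensions.
#' @export
blur_3d <- function(arr, sigma_y, sigma_x = sigma_y, sigma_z = 0) {
  stopifnot(length(dim(arr)) == 3)
  if (sigma_y <= 0 && sigma_x <= 0 && sigma_z <= 0) return(arr)
  .conv_sep3d(arr, dim(arr), gaussian_kernel(sigma_y),
              gaussian_kernel(sigma_x), gaussian_kernel(sigma_z))
}

blur_2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  a <- array(mat, dim = c(nrow(mat), ncol(mat), 1L))
  out <- .conv_sep3d(a, dim(a), gaussian_kernel(sigma), gaussian_kernel(sigma), 1)
  matrix(out, nrow(mat), ncol(mat))
}
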