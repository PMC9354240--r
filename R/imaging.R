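#' Frame stack container
#'
#' Pixel data for one or more image planes with physical metadata. Data are
#' stored as a `height x width x planes` array of non-negative intensities
#' in arbitrary units; pixel (1,1) has its centre at
#' (0.5, 0.5) * `pixel_size` so image coordinates map directly to um.
#'
#' @param data numeric matrix (one plane) or 3D array.
#' @param pixel_size um per pixel.
#' @param z_spacing um between planes (stacks only).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, pixel_size, z_spacing = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L, pixel_size > 0)
  if (any(data < 0)) stop("frame_stack: intensities must be non-negative")
  structure(list(data = data, pixel_size = pixel_size, z_spacing = z_spacing),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d x %d px, %d plane(s), %.3g um/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

# pixel-integrated 1D Gaussian profile over n pixels of width `px`,
# centred at coordinate mu (um). Sums to ~1 when the spot is inside the
# field of view.
.gauss_pixel_profile <- function(mu, sigma, px, n) {
  edges <- (0:n) * px
  diff(stats::pnorm(edges, mean = mu, sd = sigma))
}

#' Render a bright-field-like frame
#'
#' Each particle contributes an isotropic 2D Gaussian spot of fixed
#' integrated intensity (pixel-integrated, so total frame intensity is
#' exactly `intensity` per in-field particle and rendering is additive over
#' particles), plus optional additive Gaussian background noise clamped at
#' zero. A stand-in for bright-field acquisition: only spot positions and
#' relative intensities matter downstream, not optics.
#'
#' @param xy_positions n x 2 matrix of particle positions, um.
#' @param psf_sigma spot standard deviation, um.
#' @param pixel_size um per pixel.
#' @param noise_sd background noise standard deviation, a.u.
#' @param fov field of view `c(width, height)`, um.
#' @param intensity integrated intensity per particle, a.u.
#' @return a single-plane [frame_stack()].
#' @export
render_frame <- function(xy_positions, psf_sigma, pixel_size = 0.5,
                         noise_sd = 0, fov = c(32, 32), intensity = 1) {
  if (psf_sigma <= 0) stop("render_frame: psf_sigma must be positive")
  stopifnot(pixel_size > 0, noise_sd >= 0, length(fov) == 2L, all(fov > 0))
  nx <- as.integer(round(fov[1] / pixel_size))
  ny <- as.integer(round(fov[2] / pixel_size))
  img <- matrix(0, nrow = ny, ncol = nx)
  if (!is.null(xy_positions) && NROW(xy_positions) > 0) {
    xy_positions <- matrix(as.numeric(xy_positions), ncol = 2)
    if (any(xy_positions[, 1] < 0 | xy_positions[, 1] > fov[1] |
            xy_positions[, 2] < 0 | xy_positions[, 2] > fov[2])) {
      stop("render_frame: particle positions must lie within the field of view")
    }
    for (i in seq_len(nrow(xy_positions))) {
      gx <- .gauss_pixel_profile(xy_positions[i, 1], psf_sigma, pixel_size, nx)
      gy <- .gauss_pixel_profile(xy_positions[i, 2], psf_sigma, pixel_size, ny)
      img <- img + intensity * (gy %o% gx)  # rows = y, cols = x
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
    img[img < 0] <- 0
  }
  frame_stack(img, pixel_size)
}

#' Render a confocal-like z-stack
#'
#' Each particle contributes a separable 3D Gaussian sampled on the plane
#' grid (default 45 planes, as captured along the z-axis in the
#' concentration-readout experiments). Plane weights are slab-integrated,
#' so the per-particle integrated stack intensity equals `intensity` for
#' particles away from the axial stack edges, making total fluorescence a
#' faithful relative concentration readout.
#'
#' @param positions_3d n x 3 matrix of particle positions, um; z measured
#'   from the bottom of the stack.
#' @param n_planes number of z planes.
#' @param psf_sigma_xy,psf_sigma_z lateral/axial spot standard deviation, um.
#' @param pixel_size um per pixel.
#' @param fov lateral field of view `c(width, height)`, um.
#' @param z_range axial extent of the stack, um.
#' @param noise_sd background noise standard deviation, a.u.
#' @param intensity integrated intensity per particle, a.u.
#' @return a [frame_stack()] with `n_planes` planes (plane order = z order).
#' @export
render_zstack <- function(positions_3d, n_planes = 45, psf_sigma_xy = 0.5,
                          psf_sigma_z = 1.0, pixel_size = 0.5,
                          fov = c(32, 32), z_range = 22.5, noise_sd = 0,
                          intensity = 1) {
  stopifnot(n_planes >= 1, psf_sigma_xy > 0, psf_sigma_z > 0, z_range > 0)
  nx <- as.integer(round(fov[1] / pixel_size))
  ny <- as.integer(round(fov[2] / pixel_size))
  dz <- z_range / n_planes
  arr <- array(0, dim = c(ny, nx, n_planes))
  if (!is.null(positions_3d) && NROW(positions_3d) > 0) {
    positions_3d <- matrix(as.numeric(positions_3d), ncol = 3)
    for (i in seq_len(nrow(positions_3d))) {
      gx <- .gauss_pixel_profile(positions_3d[i, 1], psf_sigma_xy,
                                 pixel_size, nx)
      gy <- .gauss_pixel_profile(positions_3d[i, 2], psf_sigma_xy,
                                 pixel_size, ny)
      gz <- .gauss_pixel_profile(positions_3d[i, 3], psf_sigma_z, dz,
                                 n_planes)
      spot <- intensity * (gy %o% gx)
      for (k in seq_len(n_planes)) {
        if (gz[k] > 0) arr[, , k] <- arr[, , k] + spot * gz[k]
      }
    }
  }
  if (noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), sd = noise_sd), dim = dim(arr))
    arr[arr < 0] <- 0
  }
  frame_stack(arr, pixel_size, z_spacing = dz)
}

#' Total fluorescence of a stack
#'
#' Sum of all pixels over all planes after per-pixel background
#' subtraction (negatives clamped to zero, keeping arbitrary units
#' non-negative). The summed stack fluorescence of a GUV is the relative
#' readout of its coacervate concentration.
#'
#' @param stack a [frame_stack()].
#' @param background constant background level subtracted per pixel, a.u.
#' @return total fluorescence, a.u.
#' @export
total_fluorescence <- function(stack, background = 0) {
  stopifnot(inherits(stack, "frame_stack"), background >= 0)
  sum(pmax(stack$data - background, 0))
}

#' Classify a relative concentration readout
#'
#' Groups a total-fluorescence readout into low / medium / high relative
#' coacervate concentration. Readouts below `low_cut` are low, between the
#' cuts (boundaries included) medium, above `high_cut` high.
#'
#' @param f total fluorescence, a.u. (vectorized).
#' @param low_cut,high_cut group boundaries, a.u. (defaults 100 and 175).
#' @return character vector: `"low"`, `"medium"` or `"high"`.
#' @export
#' @examples
#' classify_concentration(c(50, 150, 200))
classify_concentration <- function(f, low_cut = 100, high_cut = 175) {
  stopifnot(low_cut < high_cut)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("classify_concentration: f must be finite and non-negative")
  }
  ifelse(f < low_cut, "low", ifelse(f <= high_cut, "medium", "high"))
}

#' Write a frame stack to multi-page TIFF (with YAML sidecar)
#'
#' Plane order equals z order. Intensities are rescaled to [0, 1] for
#' 32-bit TIFF storage; the scale factor and the physical metadata
#' (`pixel_size_um`, `z_spacing_um`) go to a `<path>.yaml` sidecar so that
#' [read_stack()] restores the original arbitrary units.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  scale <- max(stack$data, 1e-12)
  planes <- lapply(seq_len(dim(stack$data)[3]), function(k) {
    stack$data[, , k] / scale
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size,
                        z_spacing_um = stack$z_spacing,
                        intensity_scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF file (expects the `<path>.yaml` sidecar next to it).
#' @return a [frame_stack()].
#' @export
read_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(planes)) planes <- list(planes)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else {
    list(pixel_size_um = 1, z_spacing_um = NA_real_, intensity_scale = 1)
  }
  arr <- array(unlist(planes),
               dim = c(dim(planes[[1]]), length(planes)))
  frame_stack(arr * meta$intensity_scale, meta$pixel_size_um,
              z_spacing = meta$z_spacing_um %||% NA_real_)
}
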