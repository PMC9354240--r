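#' Detect particles in one frame
#'
#' Thresholds the frame, labels 4-connected components (via
#' `EBImage::bwlabel`), discards components smaller than `min_area` pixels
#' and returns the intensity-weighted centroid of each remaining component
#' in um. Sub-pixel accuracy comes from the intensity weighting, not from
#' PSF fitting.
#'
#' @param frame a single-plane [frame_stack()] or a numeric matrix
#'   (rows = y, cols = x).
#' @param threshold intensity threshold, a.u. (must be positive).
#' @param min_area minimum component area, px.
#' @param pixel_size um per pixel (taken from the `frame_stack` if given).
#' @return data.frame with columns `x_um, y_um, intensity, area_px`
#'   (zero rows if nothing is detected).
#' @export
detect_particles <- function(frame, threshold, min_area = 2,
                             pixel_size = NULL) {
  if (inherits(frame, "frame_stack")) {
    if (is.null(pixel_size)) pixel_size <- frame$pixel_size
    frame <- frame$data[, , 1]
  }
  if (is.null(pixel_size)) pixel_size <- 1
  stopifnot(is.matrix(frame), pixel_size > 0)
  if (threshold <= 0) stop("detect_particles: threshold must be positive")
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), area_px = integer(0))
  mask <- frame > threshold
  if (!any(mask)) return(empty)
  lab <- as.matrix(EBImage::bwlabel(mask))
  labs <- lab[lab > 0]
  area <- tabulate(labs)
  keep <- which(area >= min_area)
  if (length(keep) == 0L) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  w <- frame[lab > 0]
  out <- do.call(rbind, lapply(keep, function(k) {
    sel <- l == k
    wi <- w[sel]
    rows <- idx[sel, 1]
    cols <- idx[sel, 2]
    data.frame(x_um = sum(wi * (cols - 0.5)) / sum(wi) * pixel_size,
               y_um = sum(wi * (rows - 0.5)) / sum(wi) * pixel_size,
               intensity = sum(wi),
               area_px = as.integer(area[k]))
  }))
  out[order(out$x_um, out$y_um), , drop = FALSE]
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbour linking over consecutive frames: candidate
#' track-to-detection links are accepted in order of increasing
#' displacement (ties broken by lowest track id), links longer than
#' `max_disp` are rejected, unmatched detections start new tracks, and
#' tracks missing a match terminate (no gap closing — particles stay in
#' focus throughout a video). Each detection joins at most one trajectory.
#'
#' @param detections list of per-frame data.frames as returned by
#'   [detect_particles()], in frame order.
#' @param max_disp maximum allowed frame-to-frame displacement, um.
#' @param frame_dt frame interval, s.
#' @param min_length drop tracks shorter than this many frames.
#' @return list of [trajectory()] objects (ids in order of track creation).
#' @export
link_detections <- function(detections, max_disp, frame_dt = 0.2,
                            min_length = 2L) {
  stopifnot(is.list(detections), max_disp > 0, frame_dt > 0)
  tracks <- list()     # each: list(frames = int vec, x = num vec, y = num vec)
  active <- integer(0) # indices into `tracks` alive in the previous frame
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    matched_det <- rep(FALSE, nd)
    next_active <- integer(0)
    if (length(active) > 0L && nd > 0L) {
      ends <- t(vapply(tracks[active], function(tr) {
        c(tr$x[length(tr$x)], tr$y[length(tr$y)])
      }, numeric(2)))
      dmat <- outer(ends[, 1], det$x_um, "-")^2 +
              outer(ends[, 2], det$y_um, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        if (all(!is.finite(dmat)) || min(dmat, na.rm = TRUE) > max_disp) break
        best <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)
        best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
        ti <- active[best[1]]
        di <- best[2]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x_um[di])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y_um[di])
        matched_det[di] <- TRUE
        next_active <- c(next_active, ti)
        dmat[best[1], ] <- Inf
        dmat[, best[2]] <- Inf
      }
    }
    if (nd > 0L) {
      for (di in which(!matched_det)) {
        tracks[[length(tracks) + 1L]] <- list(frames = f, x = det$x_um[di],
                                              y = det$y_um[di])
        next_active <- c(next_active, length(tracks))
      }
    }
    active <- sort(next_active)
  }
  keep <- which(vapply(tracks, function(tr) length(tr$frames), 0L) >=
                  max(min_length, 2L))
  lapply(seq_along(keep), function(i) {
    tr <- tracks[[keep[i]]]
    trajectory(times = (tr$frames - 1L) * frame_dt,
               xy = cbind(tr$x, tr$y), particle_id = i)
  })
}

#' Track particles through a rendered movie
#'
#' Convenience wrapper: [detect_particles()] on every frame, then
#' [link_detections()].
#'
#' @param frames list of single-plane [frame_stack()]s or matrices.
#' @param threshold,min_area passed to [detect_particles()].
#' @param max_disp,frame_dt,min_length passed to [link_detections()].
#' @param pixel_size um per pixel for bare matrices.
#' @return list of [trajectory()] objects.
#' @export
track_movie <- function(frames, threshold, max_disp, frame_dt = 0.2,
                        min_area = 2, min_length = 2L, pixel_size = NULL) {
  dets <- lapply(frames, detect_particles, threshold = threshold,
                 min_area = min_area, pixel_size = pixel_size)
  link_detections(dets, max_disp = max_disp, frame_dt = frame_dt,
                  min_length = min_length)
}
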