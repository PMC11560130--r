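# Kymograph construction and trace normalization.
#
# Longitudinal kymographs sample a band along the midpiece midline
# (time x arclength); cross-section kymographs sample perpendicular
# crosslines at fixed positions (default every 2.5 um), giving a
# positions x time x radial-offset stack per channel.

#' Construct a longitudinal kymograph container
#'
#' @param values Matrix, time (rows) x arclength (cols).
#' @param arclength_step_um,frame_interval_s Axis calibrations (> 0).
#' @param channel Channel name.
#' @param baseline_window Integer frame range `(first, last)` used as the
#'   pre-stimulus baseline; must lie within the record.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(values, arclength_step_um, frame_interval_s,
                      channel = "membrane", baseline_window = NULL) {
  values <- as.matrix(values)
  if (arclength_step_um <= 0 || frame_interval_s <= 0)
    stopf("calibrations must be > 0")
  if (!is.null(baseline_window)) {
    if (baseline_window[1] < 1 || baseline_window[2] > nrow(values) ||
        baseline_window[1] > baseline_window[2])
      stopf("baseline window outside the record")
  }
  structure(list(values = values, arclength_step_um = arclength_step_um,
                 frame_interval_s = frame_interval_s, channel = channel,
                 baseline_window = baseline_window),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %s: %d frames x %d positions (step %.3f um, dt %.2f s)\n",
              x$channel, nrow(x$values), ncol(x$values),
              x$arclength_step_um, x$frame_interval_s))
  invisible(x)
}

#' Construct a cross-section kymograph container
#'
#' @param channels Named list of arrays, each positions x times x offsets.
#' @param positions_um Crossline positions (um).
#' @param times_s Frame times (s).
#' @param offsets_um Radial offset grid (um), symmetric about 0.
#' @param truth Optional ground-truth list (synthetic renders).
#' @return Object of class `cross_section_kymograph`.
#' @export
cross_section_kymograph <- function(channels, positions_um, times_s,
                                    offsets_um, truth = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  step <- diff(offsets_um)
  if (any(step <= 0)) stopf("offsets must be strictly increasing")
  if (abs(offsets_um[1] + offsets_um[length(offsets_um)]) > 1e-9)
    stopf("offsets must be symmetric about 0")
  for (a in channels) {
    if (!all(dim(a) == c(length(positions_um), length(times_s),
                         length(offsets_um))))
      stopf("channel array dimensions do not match the axes")
  }
  structure(list(channels = channels, positions_um = positions_um,
                 times_s = times_s, offsets_um = offsets_um,
                 offset_step_um = step[1], truth = truth),
            class = "cross_section_kymograph")
}

#' @export
print.cross_section_kymograph <- function(x, ...) {
  cat(sprintf("<cross_section_kymograph> %d positions x %d frames x %d offsets; channels: %s\n",
              length(x$positions_um), length(x$times_s),
              length(x$offsets_um),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Resample stack intensity at (x_um, y_um) image coordinates for one frame.
sample_at <- function(stack, frame, channel, x_um, y_um) {
  ci <- match(channel, stack$channels)
  if (is.na(ci)) stopf("channel '%s' not in stack", channel)
  img <- stack$data[frame, , , ci]
  bilinear(img, row = y_um / stack$pixel_size_um + 0.5,
           col = x_um / stack$pixel_size_um + 0.5)
}

#' Build a longitudinal fluorescence kymograph from an image stack
#'
#' Draws a line along the midpiece: at each arclength step, intensity is
#' averaged over a band of width `width_um` perpendicular to the midline
#' (bilinear interpolation), for every frame.
#'
#' @param stack An [image_stack()].
#' @param midline Two-column matrix of (x_um, y_um) vertices of the midline
#'   polyline, in image coordinates (um from the top-left corner).
#' @param width_um Band width (um).
#' @param channel Channel name.
#' @param arclength_step_um Sampling step along the midline; defaults to the
#'   pixel size.
#' @param baseline_window Optional baseline frame range carried into the
#'   result.
#' @return A [kymograph()] (rows = frames, cols = arclength samples).
#' @export
build_longitudinal_kymograph <- function(stack, midline, width_um = 0.3,
                                         channel = stack$channels[1],
                                         arclength_step_um = stack$pixel_size_um,
                                         baseline_window = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  midline <- as.matrix(midline)
  if (ncol(midline) != 2L || nrow(midline) < 2L)
    stopf("midline must be a polyline of >= 2 (x, y) points in um")
  d <- dim(stack$data)
  lims <- c(d[3], d[2]) * stack$pixel_size_um
  if (any(midline < 0) || any(midline[, 1] > lims[1]) ||
      any(midline[, 2] > lims[2]))
    stopf("midline outside image bounds")
  pts <- resample_polyline(midline, arclength_step_um)
  # band: offsets perpendicular to local direction
  n_off <- max(1L, round(width_um / stack$pixel_size_um))
  offs <- if (n_off == 1L) 0 else
    seq(-width_um / 2, width_um / 2, length.out = n_off)
  n_frames <- d[1]
  out <- matrix(NA_real_, n_frames, nrow(pts$xy))
  for (t in seq_len(n_frames)) {
    acc <- 0
    for (o in offs) {
      acc <- acc + sample_at(stack, t, channel,
                             pts$xy[, 1] + o * pts$normal[, 1],
                             pts$xy[, 2] + o * pts$normal[, 2])
    }
    out[t, ] <- acc / length(offs)
  }
  if (all(is.na(out))) stopf("empty band: midline produced no samples")
  kymograph(out, arclength_step_um, stack$frame_interval_s, channel,
            baseline_window)
}

# Resample a polyline at a fixed arclength step; returns points and unit
# normals (perpendicular to the local direction).
resample_polyline <- function(midline, step) {
  seg <- diff(midline)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  xy <- cbind(stats::approx(cum, midline[, 1], s)$y,
              stats::approx(cum, midline[, 2], s)$y)
  seg_idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                  nrow(seg))
  dir <- seg[seg_idx, , drop = FALSE] / seg_len[seg_idx]
  list(xy = xy, s = s, normal = cbind(-dir[, 2], dir[, 1]))
}

#' Build cross-section kymographs from an image stack
#'
#' For each requested arclength position, samples the intensity profile
#' along the crossline perpendicular to the midline at every frame,
#' resampled on a uniform radial-offset grid by bilinear interpolation.
#' A `cross_section_kymograph` input is passed through unchanged.
#'
#' @param stack An [image_stack()] (or a `cross_section_kymograph`, returned
#'   as is).
#' @param midline Midline polyline as in [build_longitudinal_kymograph()].
#' @param positions_um Crossline positions along the midline arclength
#'   (default every 2.5 um over the midline extent).
#' @param halfwidth_um Crossline half-length (um).
#' @param channel Channel name.
#' @param offset_step_um Radial sampling step.
#' @return A [cross_section_kymograph()].
#' @export
build_cross_section_kymograph <- function(stack, midline = NULL,
                                          positions_um = NULL,
                                          halfwidth_um = 1,
                                          channel = NULL,
                                          offset_step_um = NULL) {
  if (inherits(stack, "cross_section_kymograph")) return(stack)
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(midline)) stopf("midline required for image-stack input")
  if (is.null(channel)) channel <- stack$channels[1]
  if (is.null(offset_step_um)) offset_step_um <- stack$pixel_size_um / 2
  midline <- as.matrix(midline)
  pts <- resample_polyline(midline, offset_step_um)
  total <- max(pts$s)
  if (is.null(positions_um)) positions_um <- seq(0, total, by = 2.5)
  if (any(positions_um < 0 | positions_um > total))
    stopf("positions outside midline extent [0, %.2f]", total)
  offsets <- seq(-halfwidth_um, halfwidth_um, by = offset_step_um)
  n_frames <- dim(stack$data)[1]
  arr <- array(NA_real_, dim = c(length(positions_um), n_frames,
                                 length(offsets)))
  for (i in seq_along(positions_um)) {
    k <- which.min(abs(pts$s - positions_um[i]))
    cx <- pts$xy[k, 1] + offsets * pts$normal[k, 1]
    cy <- pts$xy[k, 2] + offsets * pts$normal[k, 2]
    for (t in seq_len(n_frames)) {
      prof <- sample_at(stack, t, channel, cx, cy)
      if (all(is.na(prof))) stopf("crossline exits the image at %.2f um",
                                  positions_um[i])
      arr[i, t, ] <- prof
    }
  }
  ch <- list(arr); names(ch) <- channel
  cross_section_kymograph(ch, positions_um,
                          (seq_len(n_frames) - 1L) * stack$frame_interval_s,
                          offsets)
}

#' Baseline-normalize a fluorescence trace: (F - F0) / F0
#'
#' `F0` is the mean over the baseline window (the frames before stimulus
#' application). If a scalar `background` is supplied it is subtracted from
#' the whole trace first.
#'
#' @param trace Numeric vector.
#' @param baseline_window Integer frame range `(first, last)`.
#' @param background Optional scalar background to subtract first.
#' @return Numeric vector of the same length, zero-mean over the baseline.
#' @export
normalize_trace <- function(trace, baseline_window, background = NULL) {
  if (baseline_window[1] < 1 || baseline_window[2] > length(trace) ||
      baseline_window[1] > baseline_window[2])
    stopf("baseline window outside the record")
  if (!is.null(background)) trace <- trace - background
  f0 <- mean(trace[baseline_window[1]:baseline_window[2]])
  if (!is.finite(f0) || f0 <= 0)
    stopf("baseline mean must be positive after background subtraction")
  (trace - f0) / f0
}

#' Label a midpiece position as proximal, central, or distal
#'
#' Regions partition the midpiece as proximal `[0, 7)`, central `[7, 14)`,
#' distal `[14, 21]` um from the head-midpiece junction; positions beyond
#' 21 um (up to the midpiece length) clamp to distal.
#'
#' @param position_um Numeric vector of positions (um, >= 0).
#' @return Factor with levels `proximal`, `central`, `distal`.
#' @export
segment_region <- function(position_um) {
  if (any(position_um < 0)) stopf("position must be >= 0")
  lab <- ifelse(position_um < 7, "proximal",
                ifelse(position_um < 14, "central", "distal"))
  factor(lab, levels = c("proximal", "central", "distal"))
}

#' Construct a named ROI trace set
#'
#' @param traces Matrix (frames x ROIs) of raw fluorescence, with column
#'   names.
#' @param channels Character vector of channel roles per ROI (same length as
#'   columns): `"calcium"`, `"membrane"`, `"nuclear"`, or `"other"`.
#' @param baseline_window Integer frame range preceding the stimulus.
#' @param stimulus_frame Stimulus frame (must follow the baseline window).
#' @param frame_interval_s Frame interval (s).
#' @param truth Optional ground-truth list (synthetic traces).
#' @return Object of class `trace_set`.
#' @export
trace_set <- function(traces, channels, baseline_window, stimulus_frame,
                      frame_interval_s = 1, truth = NULL) {
  traces <- as.matrix(traces)
  if (is.null(colnames(traces))) stopf("traces must have ROI names")
  if (length(channels) != ncol(traces))
    stopf("one channel role per ROI required")
  if (baseline_window[2] >= stimulus_frame)
    stopf("baseline window must precede the stimulus frame")
  if (baseline_window[1] < 1 || baseline_window[2] > nrow(traces))
    stopf("baseline window outside the record")
  structure(list(traces = traces, channels = stats::setNames(channels, colnames(traces)),
                 baseline_window = baseline_window,
                 stimulus_frame = stimulus_frame,
                 frame_interval_s = frame_interval_s, truth = truth),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d frames, ROIs: %s\n", nrow(x$traces),
              paste(sprintf("%s (%s)", colnames(x$traces), x$channels),
                    collapse = ", ")))
  invisible(x)
}
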