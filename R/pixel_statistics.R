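# Manders colocalization coefficients and moment-based number & brightness
# with detector correction.

#' Manders colocalization coefficients M1 and M2
#'
#' `M1` is the fraction of channel-1 intensity falling on pixels where
#' channel 2 exceeds its threshold; `M2` is the symmetric quantity. By
#' default per-channel thresholds are chosen by Otsu's method on the
#' analyzed region; explicit thresholds may be supplied for
#' reproducibility.
#'
#' @param ch1,ch2 Numeric matrices (same shape), nonnegative intensities.
#' @param thresholds Either `"otsu"` or a numeric length-2 vector
#'   `c(T1, T2)` (a pixel participates when intensity strictly exceeds its
#'   channel threshold).
#' @return Object of class `manders_result`: `M1`, `M2` (both in `[0, 1]`),
#'   `thresholds`, `n_pixels`.
#' @export
manders <- function(ch1, ch2, thresholds = "otsu") {
  ch1 <- as.matrix(ch1); ch2 <- as.matrix(ch2)
  if (!all(dim(ch1) == dim(ch2))) stopf("channel shapes differ")
  if (any(ch1 < 0, na.rm = TRUE) || any(ch2 < 0, na.rm = TRUE))
    stopf("intensities must be nonnegative")
  s1 <- sum(ch1); s2 <- sum(ch2)
  if (s1 == 0 || s2 == 0) stopf("zero total intensity in a channel")
  th <- if (identical(thresholds, "otsu"))
    c(otsu_threshold(ch1), otsu_threshold(ch2))
  else as.numeric(thresholds)
  if (length(th) != 2L) stopf("thresholds must be length 2")
  m1 <- sum(ch1[ch2 > th[2]]) / s1
  m2 <- sum(ch2[ch1 > th[1]]) / s2
  structure(list(M1 = m1, M2 = m2, thresholds = th,
                 n_pixels = length(ch1)),
            class = "manders_result")
}

#' @export
print.manders_result <- function(x, ...) {
  cat(sprintf("<manders_result> M1 = %.3f, M2 = %.3f (thresholds %.3g / %.3g, %d px)\n",
              x$M1, x$M2, x$thresholds[1], x$thresholds[2], x$n_pixels))
  invisible(x)
}

#' Number & brightness maps from an intensity-fluctuation stack
#'
#' For each consecutive non-overlapping segment of `segment_frames` frames,
#' computes the per-pixel temporal mean and variance, applies the detector
#' correction when supplied (`mu' = mu - offset`,
#' `var' = var - read_noise_var`), and forms the moment maps
#' `N = mu'^2 / var'` (apparent molecule number) and `B = var' / mu'`
#' (apparent brightness, counts per molecule per frame; the shot-noise `+1`
#' is not added — the convention is recorded in the result). Pixels with
#' nonpositive corrected mean or variance are masked to `NA`.
#'
#' @param stack An [image_stack()] (single channel).
#' @param segment_frames Segment length (default 100 frames).
#' @param detector Optional [detector_model()] holding `offset_counts` and
#'   `read_noise_var` (scalar or per-pixel matrix).
#' @return Object of class `nb_maps`: arrays `mean`, `variance`, `number`,
#'   `brightness` of shape segments x Y x X, `segment_frames`, and the
#'   brightness convention.
#' @export
nb_maps <- function(stack, segment_frames = 100L, detector = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (segment_frames > d[1]) stopf("segment longer than the stack")
  if (segment_frames < 2L) stopf("segment_frames must be >= 2")
  n_seg <- d[1] %/% segment_frames
  offset <- if (is.null(detector)) 0 else detector$offset_counts
  rn_var <- if (is.null(detector)) 0 else detector$read_noise_var
  mu <- va <- nn <- bb <- array(NA_real_, dim = c(n_seg, d[2], d[3]))
  for (k in seq_len(n_seg)) {
    fr <- ((k - 1L) * segment_frames + 1L):(k * segment_frames)
    seg <- stack$data[fr, , , 1, drop = FALSE]
    m <- apply(seg, c(2, 3), mean)
    v <- apply(seg, c(2, 3), stats::var)
    mu[k, , ] <- m
    va[k, , ] <- v
    mc <- m - offset
    vc <- v - rn_var
    bad <- !(is.finite(mc) & is.finite(vc)) | mc <= 0 | vc <= 0
    N <- mc^2 / vc; B <- vc / mc
    N[bad] <- NA_real_; B[bad] <- NA_real_
    nn[k, , ] <- N; bb[k, , ] <- B
  }
  structure(list(mean = mu, variance = va, number = nn, brightness = bb,
                 segment_frames = segment_frames, n_segments = n_seg,
                 pixel_size_um = stack$pixel_size_um,
                 brightness_convention = "B = var/mean (no +1 shot-noise term)"),
            class = "nb_maps")
}

#' @export
print.nb_maps <- function(x, ...) {
  d <- dim(x$number)
  cat(sprintf("<nb_maps> %d segment(s) of %d frames, %d x %d px\n",
              d[1], x$segment_frames, d[2], d[3]))
  cat(sprintf("  median N = %.2f, median B = %.3f (%s)\n",
              stats::median(x$number, na.rm = TRUE),
              stats::median(x$brightness, na.rm = TRUE),
              x$brightness_convention))
  invisible(x)
}

#' Per-ROI number & brightness summaries
#'
#' Averages the N and B maps over square ROIs (1 um^2 by default) for each
#' segment, the summary used to compare actin number/brightness across
#' enrichment zones over time.
#'
#' @param maps An [nb_maps()] result.
#' @param rois data.frame with columns `name`, `y_px`, `x_px` (top-left
#'   corner, 1-based) and optionally `size_px` (side length; default
#'   corresponds to 1 um at the map's pixel size).
#' @return data.frame with one row per ROI x segment: `roi`, `segment`,
#'   `mean_number`, `mean_brightness`, `mean_intensity`, `n_pixels`.
#' @export
roi_nb <- function(maps, rois) {
  stopifnot(inherits(maps, "nb_maps"))
  d <- dim(maps$number)
  default_size <- max(1L, round(1 / maps$pixel_size_um))
  out <- list()
  for (i in seq_len(nrow(rois))) {
    sz <- if ("size_px" %in% names(rois)) rois$size_px[i] else default_size
    ys <- rois$y_px[i]:(rois$y_px[i] + sz - 1L)
    xs <- rois$x_px[i]:(rois$x_px[i] + sz - 1L)
    if (min(ys) < 1 || max(ys) > d[2] || min(xs) < 1 || max(xs) > d[3])
      stopf("ROI '%s' outside map bounds", rois$name[i])
    for (k in seq_len(d[1])) {
      nk <- maps$number[k, ys, xs]
      if (all(is.na(nk))) stopf("ROI '%s' is empty in segment %d",
                                rois$name[i], k)
      out[[length(out) + 1L]] <- data.frame(
        roi = rois$name[i], segment = k,
        mean_number = mean(nk, na.rm = TRUE),
        mean_brightness = mean(maps$brightness[k, ys, xs], na.rm = TRUE),
        mean_intensity = mean(maps$mean[k, ys, xs]),
        n_pixels = length(nk))
    }
  }
  do.call(rbind, out)
}
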