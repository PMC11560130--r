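# Trace-level event analysis: onset detection, cross-channel event
# ordering, midpiece calcium pattern classification, and Fourier beat
# frequency.

#' Detect an event onset in a normalized trace
#'
#' The baseline window defines a mean and SD; the onset is the first frame
#' at which the trace deviates from the baseline mean by more than
#' `k_sigma` baseline SDs in the stated direction for at least
#' `persistence` consecutive frames. The persistence run uses hysteresis:
#' it is triggered above `k_sigma` SDs and sustained above `k_sigma / 2`
#' SDs, so single noise frames near the threshold do not fragment a
#' genuine event.
#'
#' @param normalized Normalized trace ((F-F0)/F0).
#' @param baseline_window Integer frame range (>= 10 frames).
#' @param k_sigma Deviation threshold in baseline SDs.
#' @param persistence Minimum run length (frames).
#' @param direction `"rise"` or `"fall"`.
#' @param min_sigma Floor on the baseline SD, guarding noise-free traces
#'   (where SD would be 0); expressed in normalized units.
#' @return Integer onset frame or `NA_integer_`.
#' @export
detect_event_onset <- function(normalized, baseline_window,
                               k_sigma = 3, persistence = 5L,
                               direction = c("rise", "fall"),
                               min_sigma = 1e-3) {
  direction <- match.arg(direction)
  if (diff(baseline_window) + 1L < 10L)
    stopf("baseline window must span >= 10 frames")
  bw <- baseline_window[1]:baseline_window[2]
  mu <- mean(normalized[bw])
  sigma <- max(stats::sd(normalized[bw]), min_sigma)
  dev_of <- function(k) {
    d <- if (direction == "rise") normalized > mu + k * sigma
         else normalized < mu - k * sigma
    d & !is.na(d)
  }
  high <- dev_of(k_sigma)
  low <- dev_of(k_sigma / 2)
  n <- length(normalized)
  starts <- which(high & seq_len(n) <= n - persistence + 1L)
  for (i in starts) {
    if (all(low[i:(i + persistence - 1L)])) return(i)
  }
  NA_integer_
}

#' Cross-channel event ordering verdicts for a trace set
#'
#' Normalizes every ROI trace, detects per-channel onsets, and evaluates
#' the two orderings of interest: for acrosomal exocytosis, whether the
#' midpiece calcium rise precedes the membrane-dye rise; for gamete fusion,
#' whether the nuclear-dye rise precedes the midpiece calcium decrease,
#' which in turn precedes the membrane-dye rise. A verdict is `NA`
#' (undefined, not false) when a required onset or channel is missing.
#'
#' @param traces A [trace_set()].
#' @param k_sigma,persistence Passed to [detect_event_onset()].
#' @return Object of class `event_report`: per-ROI onsets (frames) with
#'   directions, and verdict flags `calcium_precedes_membrane`,
#'   `fusion_ordering` (logical or `NA`).
#' @export
order_events <- function(traces, k_sigma = 3, persistence = 5L) {
  stopifnot(inherits(traces, "trace_set"))
  bw <- traces$baseline_window
  roi_names <- colnames(traces$traces)
  norm <- apply(traces$traces, 2, normalize_trace, baseline_window = bw)
  onset_for <- function(channel, direction) {
    i <- which(traces$channels == channel)
    if (!length(i)) return(NA_integer_)
    detect_event_onset(norm[, i[1]], bw, k_sigma, persistence, direction)
  }
  ca_rise <- onset_for("calcium", "rise")
  ca_fall <- onset_for("calcium", "fall")
  fm_rise <- onset_for("membrane", "rise")
  nuc_rise <- onset_for("nuclear", "rise")
  both <- function(a, b) !is.na(a) && !is.na(b)
  calcium_precedes_membrane <-
    if (both(ca_rise, fm_rise)) ca_rise < fm_rise else NA
  fusion_ordering <-
    if (both(nuc_rise, ca_fall) && !is.na(fm_rise))
      (nuc_rise < ca_fall) && (ca_fall < fm_rise) else NA
  onsets <- data.frame(
    roi = roi_names, channel = unname(traces$channels),
    rise_frame = vapply(seq_along(roi_names), function(j)
      detect_event_onset(norm[, j], bw, k_sigma, persistence, "rise"),
      integer(1)),
    fall_frame = vapply(seq_along(roi_names), function(j)
      detect_event_onset(norm[, j], bw, k_sigma, persistence, "fall"),
      integer(1)))
  structure(list(onsets = onsets,
                 calcium_precedes_membrane = calcium_precedes_membrane,
                 fusion_ordering = fusion_ordering),
            class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  cat("<event_report>\n")
  print(x$onsets)
  cat(sprintf("  calcium precedes membrane: %s; fusion ordering: %s\n",
              format(x$calcium_precedes_membrane),
              format(x$fusion_ordering)))
  invisible(x)
}

#' Classify the midpiece calcium pattern of a normalized trace
#'
#' Three patterns are distinguished in the post-stimulus record:
#' `decrease` — a sustained negative deviation (below `-k_decrease` baseline
#' SDs for at least `sustained_frac` of the post-stimulus frames);
#' `transient_increase` — a positive excursion above `k_transient` SDs that
#' returns to within `k_return` SDs of baseline before the record ends;
#' `no_change` — neither.
#'
#' @param normalized Normalized calcium trace.
#' @param baseline_window Integer frame range.
#' @param stimulus_frame First post-baseline frame considered.
#' @param k_decrease,k_transient,k_return Thresholds in baseline SDs.
#' @param sustained_frac Fraction of the post-stimulus record the decrease
#'   must occupy.
#' @param min_sigma Floor on the baseline SD (normalized units; default 1%
#'   of baseline, a realistic indicator noise floor, so noise-free traces
#'   classify sensibly).
#' @return One of `"decrease"`, `"transient_increase"`, `"no_change"`.
#' @export
classify_midpiece_pattern <- function(normalized, baseline_window,
                                      stimulus_frame = baseline_window[2] + 1L,
                                      k_decrease = 3, k_transient = 3,
                                      k_return = 2,
                                      sustained_frac = 0.2,
                                      min_sigma = 0.01) {
  bw <- baseline_window[1]:baseline_window[2]
  mu <- mean(normalized[bw])
  sigma <- max(stats::sd(normalized[bw]), min_sigma)
  post <- normalized[stimulus_frame:length(normalized)]
  if (mean(post < mu - k_decrease * sigma, na.rm = TRUE) >= sustained_frac)
    return("decrease")
  up <- which(post > mu + k_transient * sigma)
  if (length(up)) {
    after_peak <- post[seq(max(up), length(post))]
    if (any(abs(after_peak - mu) <= k_return * sigma, na.rm = TRUE))
      return("transient_increase")
  }
  "no_change"
}

#' Flagellar beat frequency from an orientation time series
#'
#' Removes the mean, applies a Hann window, and takes the discrete Fourier
#' transform of the mean flagellar orientation; the dominant non-DC
#' spectral peak gives the beat frequency. Peak significance is assessed
#' with Fisher's g test (the largest periodogram ordinate against the sum);
#' when the peak is not significant, `NA` is returned (no dominant beat —
#' e.g. motility arrest).
#'
#' @param orientation_rad Orientation series (radians).
#' @param fps Sampling rate (frames per second); must exceed twice the
#'   expected beat frequency.
#' @param alpha Significance level of Fisher's g test.
#' @return List: `frequency_hz` (or `NA`), `resolution_hz` (= fps/N),
#'   `g`, `p_value`.
#' @export
beat_frequency <- function(orientation_rad, fps, alpha = 0.01) {
  n <- length(orientation_rad)
  if (n < 2 * fps) stopf("need >= 2 s of samples")
  y <- orientation_rad - mean(orientation_rad)
  if (all(y == 0))
    return(list(frequency_hz = NA_real_, resolution_hz = fps / n,
                g = NA_real_, p_value = NA_real_))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))   # Hann
  sp <- Mod(stats::fft(y * w))^2
  half <- 2:floor(n / 2)
  pgram <- sp[half]
  freq <- (half - 1) * fps / n
  g <- max(pgram) / sum(pgram)
  m <- length(pgram)
  # Fisher's g: P(G > g) ~ m (1 - g)^(m - 1) (first term; conservative)
  p <- min(1, m * (1 - g)^(m - 1))
  i <- which.max(pgram)
  f_hat <- stats::approx(seq_along(freq), freq,
                         xout = refine_peak(pgram, i))$y
  list(frequency_hz = if (p < alpha) f_hat else NA_real_,
       resolution_hz = fps / n, g = g, p_value = p)
}

#' Beat frequency over a sliding window (motility-cessation profile)
#'
#' Applies [beat_frequency()] in sliding windows; a window without a
#' significant dominant peak reports `NA`, so gradual arrest appears as a
#' frequency decline ending in `NA`s.
#'
#' @param orientation_rad Orientation series (radians).
#' @param fps Sampling rate.
#' @param window_s,step_s Window length and hop (s).
#' @param ... Passed to [beat_frequency()].
#' @return data.frame with `t_center_s` and `frequency_hz`.
#' @export
beat_frequency_profile <- function(orientation_rad, fps, window_s = 2,
                                   step_s = 1, ...) {
  n <- length(orientation_rad)
  win <- round(window_s * fps)
  hop <- max(1L, round(step_s * fps))
  starts <- seq(1L, n - win + 1L, by = hop)
  data.frame(
    t_center_s = (starts + win / 2 - 1) / fps,
    frequency_hz = vapply(starts, function(i)
      beat_frequency(orientation_rad[i:(i + win - 1L)], fps,
                     ...)$frequency_hz, numeric(1)))
}
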