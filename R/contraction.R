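# Midpiece contraction analytics: ACF diameter, normalized diameter
# kymographs, onset detection, initiation foci, derivative-based peak
# tracking with velocity fits, and the fluorescence <-> diameter transform.

#' Midpiece diameter from a radial intensity profile (autocorrelation)
#'
#' The cross-section profile of the midpiece membrane shows two fluorescence
#' maxima, one on each side of the tube. Their separation — the diameter —
#' appears in the profile autocorrelation as the largest maximum at nonzero
#' lag. The background (profile median — the membrane peaks occupy a
#' minority of the crossline) is removed before correlating: correlating
#' the raw background produces finite-window cross terms that kink the
#' secondary maximum when the crossline is not much longer than the
#' diameter. The search is restricted to physiological lags
#' (`lag_range_um`, default 0.2–1.5 um) to avoid secondary structure; the
#' winning lag is refined to sub-step accuracy (unbiased-normalization and
#' local linear-tilt correction, then a three-point parabola).
#'
#' The estimate is invariant to global intensity scaling and additive
#' offsets (background removal plus correlation normalization).
#'
#' @param profile Numeric vector of intensities along the crossline.
#' @param offset_step_um Radial sampling step (um).
#' @param lag_range_um Search band for the diameter (um).
#' @param min_acf Noise floor: the secondary autocorrelation maximum must
#'   exceed this value, or the diameter is undetermined (a genuine membrane
#'   peak pair correlates far above this; weak ripples from a single peak
#'   or pure noise do not).
#' @return Diameter in um, or `NA_real_` when no secondary autocorrelation
#'   maximum exists in the band (diameter undetermined).
#' @export
diameter_from_profile <- function(profile, offset_step_um,
                                  lag_range_um = c(0.2, 1.5),
                                  min_acf = 0.1) {
  n <- length(profile)
  if (n < 4L || !any(is.finite(profile))) return(NA_real_)
  y <- profile - stats::median(profile)
  if (stats::sd(y) == 0) return(NA_real_)
  a <- stats::acf(y, lag.max = n - 1L, plot = FALSE,
                  demean = FALSE)$acf[, 1, 1]
  lo <- max(2L, floor(lag_range_um[1] / offset_step_um))
  hi <- min(n - 1L, ceiling(lag_range_um[2] / offset_step_um))
  if (hi - lo < 2L) return(NA_real_)
  band <- (lo + 1L):(hi + 1L)           # acf[1] is lag 0
  # local maxima within the band, strictly above their neighbours
  cand <- band[a[band] > a[band - 1L] & a[band] >= a[band + 1L]]
  cand <- cand[a[cand] > min_acf]
  if (length(cand) == 0L) return(NA_real_)
  best <- cand[which.max(a[cand])]
  # Refine the winning lag on locally corrected values: undo the biased
  # estimator's 1/n taper, remove the residual linear tilt (the chord
  # through the window endpoints), then fit the three-point parabola.
  # One recentering iteration keeps the window symmetric about the vertex.
  au <- a * n / (n - seq_len(n) + 1L)
  vertex <- as.numeric(best)
  for (iter in 1:2) {
    win <- max(2L, best - 3L):min(n, best + 3L)
    local <- au[win]
    m <- length(local)
    chord <- local[1] + (local[m] - local[1]) * (seq_len(m) - 1) / (m - 1)
    resid <- local - chord
    i <- which.max(resid)
    vertex <- refine_peak(resid, i) + win[1] - 1
    best <- as.integer(round(vertex))
  }
  (vertex - 1) * offset_step_um
}

#' Diameter series with baseline normalization from cross-section kymographs
#'
#' Runs [diameter_from_profile()] at every position and frame of a
#' cross-section kymograph and normalizes each position's series by its
#' baseline mean (frames prior to stimulus application), giving the
#' normalized diameter (1 = baseline).
#'
#' @param csk A [cross_section_kymograph()].
#' @param baseline_window Integer frame range preceding the stimulus.
#' @param channel Channel used for the measurement.
#' @param lag_range_um Passed to [diameter_from_profile()].
#' @return Object of class `diameter_series`: matrices `diameter_um` and
#'   `normalized` (positions x frames), plus axes and the baseline window.
#' @export
normalized_diameter_kymograph <- function(csk, baseline_window,
                                          channel = "membrane",
                                          lag_range_um = c(0.2, 1.5)) {
  stopifnot(inherits(csk, "cross_section_kymograph"))
  arr <- csk$channels[[channel]]
  if (is.null(arr)) stopf("channel '%s' not present", channel)
  n_t <- length(csk$times_s)
  if (baseline_window[1] < 1 || baseline_window[2] > n_t)
    stopf("baseline window outside the record")
  d <- t(apply(arr, 1, function(m)
    apply(m, 1, diameter_from_profile, offset_step_um = csk$offset_step_um,
          lag_range_um = lag_range_um)))
  bw <- baseline_window[1]:baseline_window[2]
  base <- apply(d[, bw, drop = FALSE], 1, function(x) {
    if (mean(is.na(x)) > 0.5)
      stopf("diameter undetermined at > 50%% of baseline frames")
    mean(x, na.rm = TRUE)
  })
  structure(list(diameter_um = d, normalized = d / base,
                 positions_um = csk$positions_um, times_s = csk$times_s,
                 baseline_window = baseline_window),
            class = "diameter_series")
}

#' @export
print.diameter_series <- function(x, ...) {
  cat(sprintf("<diameter_series> %d positions x %d frames; baseline frames %d-%d\n",
              nrow(x$diameter_um), ncol(x$diameter_um),
              x$baseline_window[1], x$baseline_window[2]))
  cat(sprintf("  baseline diameter %.3f um (mean over positions)\n",
              mean(x$diameter_um[, x$baseline_window[1]:x$baseline_window[2]],
                   na.rm = TRUE)))
  invisible(x)
}

#' Detect the contraction onset in a normalized diameter series
#'
#' Returns the first frame at which the normalized diameter drops below
#' `1 - drop_threshold` and stays depressed for at least
#' `persistence_frames` consecutive frames, or `NA` when no such sustained
#' drop occurs. The persistence run uses hysteresis (sustained below
#' `1 - drop_threshold / 2`) so single noisy frames near the threshold do
#' not fragment a genuine contraction.
#'
#' @param normalized Numeric vector (1 = baseline).
#' @param drop_threshold Fractional drop that counts as contraction.
#' @param persistence_frames Minimum run length.
#' @return Integer frame index or `NA_integer_`.
#' @export
detect_contraction_onset <- function(normalized, drop_threshold = 0.10,
                                     persistence_frames = 5L) {
  ok <- !is.na(normalized)
  trigger <- ok & normalized < 1 - drop_threshold
  sustain <- ok & normalized < 1 - drop_threshold / 2
  n <- length(normalized)
  for (i in which(trigger & seq_len(n) <= n - persistence_frames + 1L)) {
    if (all(sustain[i:(i + persistence_frames - 1L)])) return(i)
  }
  NA_integer_
}

#' Locate contraction initiation foci from per-position onset times
#'
#' Initiation foci are local minima of onset time over arclength position
#' (contraction starts there and propagates outward). Minima closer than
#' `min_separation_um` are merged, keeping the earliest onset (ties broken
#' by the smallest position). Each focus is labelled with its midpiece
#' region via [segment_region()].
#'
#' @param positions_um Arclength positions (um).
#' @param onset_s Onset time per position (s; `NA` = no onset detected).
#' @param min_separation_um Merge radius (um; default one crossline
#'   spacing).
#' @return data.frame with columns `position_um`, `onset_s`, `region`.
#' @export
find_initiation_foci <- function(positions_um, onset_s,
                                 min_separation_um = 2.5) {
  ok <- !is.na(onset_s)
  if (sum(ok) < 3L) stopf("need >= 3 positions with defined onsets")
  p <- positions_um[ok]; o <- onset_s[ok]
  ord <- order(p); p <- p[ord]; o <- o[ord]
  n <- length(p)
  is_min <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1L || o[i] <= o[i - 1L]
    right_ok <- i == n || o[i] <= o[i + 1L]
    left_ok && right_ok
  }, logical(1))
  # collapse plateaus (runs of equal onset that are jointly minimal)
  keep <- is_min & !(c(FALSE, is_min[-n]) & c(FALSE, o[-n] == o[-1]))
  cand <- which(keep)
  # greedy merge: earliest onset wins, ties to the smallest position
  cand <- cand[order(o[cand], p[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || all(abs(p[i] - p[sel]) >= min_separation_um))
      sel <- c(sel, i)
  }
  sel <- sel[order(p[sel])]
  data.frame(position_um = p[sel], onset_s = o[sel],
             region = segment_region(p[sel]))
}

#' Full contraction report from a cross-section kymograph
#'
#' Convenience composition: diameter series, per-position onset detection,
#' initiation foci with region labels and counts.
#'
#' @param csk A [cross_section_kymograph()].
#' @param baseline_window Integer frame range preceding the stimulus.
#' @param drop_threshold,persistence_frames Passed to
#'   [detect_contraction_onset()].
#' @param min_separation_um Passed to [find_initiation_foci()].
#' @param channel Measurement channel.
#' @return Object of class `contraction_report`: `diameters`
#'   (a `diameter_series`), `onset_s` per position, `foci`, `focus_count`,
#'   and `region_counts`.
#' @export
analyze_contraction <- function(csk, baseline_window,
                                drop_threshold = 0.10,
                                persistence_frames = 5L,
                                min_separation_um = 2.5,
                                channel = "membrane") {
  ds <- normalized_diameter_kymograph(csk, baseline_window, channel)
  onset_frame <- apply(ds$normalized, 1, detect_contraction_onset,
                       drop_threshold = drop_threshold,
                       persistence_frames = persistence_frames)
  onset_s <- ifelse(is.na(onset_frame), NA_real_,
                    ds$times_s[onset_frame])
  foci <- if (sum(!is.na(onset_s)) >= 3L)
    find_initiation_foci(ds$positions_um, onset_s, min_separation_um)
  else data.frame(position_um = numeric(0), onset_s = numeric(0),
                  region = segment_region(numeric(0)))
  structure(list(diameters = ds, onset_s = onset_s, foci = foci,
                 focus_count = nrow(foci),
                 region_counts = table(foci$region)),
            class = "contraction_report")
}

#' @export
print.contraction_report <- function(x, ...) {
  cat(sprintf("<contraction_report> %d focus/foci\n", x$focus_count))
  if (x$focus_count) print(x$foci)
  invisible(x)
}

#' Locate membrane fluorescence peaks in a cross-section profile
#'
#' Peaks are found where the spatial derivative of the (Gaussian-smoothed)
#' profile changes sign from positive to negative; the outermost
#' sufficiently prominent maximum on each side of the profile midpoint is
#' taken as the membrane peak pair, and refined to sub-step accuracy by
#' log-parabolic interpolation (exact for Gaussian peaks).
#'
#' @param profile Numeric intensity vector along the crossline.
#' @param offset_step_um Radial step (um).
#' @param offsets_um Optional offset grid; defaults to a symmetric grid
#'   about 0.
#' @param smooth_sigma_steps Gaussian smoothing SD in steps (default 1).
#' @param min_prominence Minimum peak height as a fraction of the profile
#'   range.
#' @return Named numeric `c(left, right)` peak offsets (um); errors when
#'   fewer than two qualifying sign changes exist.
#' @export
find_membrane_peaks <- function(profile, offset_step_um,
                                offsets_um = NULL,
                                smooth_sigma_steps = 1,
                                min_prominence = 0.1) {
  n <- length(profile)
  if (is.null(offsets_um))
    offsets_um <- (seq_len(n) - (n + 1) / 2) * offset_step_um
  y <- gaussian_smooth(profile, smooth_sigma_steps)
  d <- diff(y)
  # derivative transitions + -> - : local maxima at index i
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  floor_y <- min(y)
  idx <- idx[(y[idx] - floor_y) >= min_prominence * (max(y) - floor_y)]
  mid <- (n + 1) / 2
  left <- idx[idx < mid]
  right <- idx[idx > mid]
  if (!length(left) || !length(right))
    stopf("fewer than two membrane peaks found")
  li <- min(left); ri <- max(right)     # outermost pair
  ref <- function(i) {
    pos <- refine_peak(y - floor_y, i, log_scale = TRUE)
    stats::approx(seq_len(n), offsets_um, xout = pos)$y
  }
  c(left = ref(li), right = ref(ri))
}

#' Track membrane (and actin) peak positions over time
#'
#' Per frame, finds the membrane peak pair at one crossline position,
#' defines the cell center as the mean of the two membrane peaks
#' (normalized to 0), and re-expresses all peak offsets relative to that
#' center. Following the symmetric geometry, downstream velocity analysis
#' uses the right-side peak distances.
#'
#' @param csk A [cross_section_kymograph()] with a `membrane` channel and
#'   optionally an `actin` channel.
#' @param position Index into `csk$positions_um` (default 1).
#' @param max_lost Maximum tolerated fraction of frames without a peak pair.
#' @param ... Passed to [find_membrane_peaks()].
#' @return Object of class `peak_track`: data.frame with `time_s`,
#'   `center_um`, `mem_left_um`, `mem_right_um` (center-relative),
#'   and when actin is present `actin_left_um`, `actin_right_um`.
#' @export
track_peaks <- function(csk, position = 1L, max_lost = 0.2, ...) {
  stopifnot(inherits(csk, "cross_section_kymograph"))
  if (!"membrane" %in% names(csk$channels))
    stopf("membrane channel required")
  has_actin <- "actin" %in% names(csk$channels)
  n_t <- length(csk$times_s)
  res <- data.frame(time_s = csk$times_s, center_um = NA_real_,
                    mem_left_um = NA_real_, mem_right_um = NA_real_)
  if (has_actin) res$actin_left_um <- res$actin_right_um <- NA_real_
  for (t in seq_len(n_t)) {
    pk <- tryCatch(find_membrane_peaks(csk$channels$membrane[position, t, ],
                                       csk$offset_step_um,
                                       offsets_um = csk$offsets_um, ...),
                   error = function(e) NULL)
    if (is.null(pk)) next
    center <- mean(pk)
    res$center_um[t] <- center
    res$mem_left_um[t] <- pk["left"] - center
    res$mem_right_um[t] <- pk["right"] - center
    if (has_actin) {
      ak <- tryCatch(find_membrane_peaks(csk$channels$actin[position, t, ],
                                         csk$offset_step_um,
                                         offsets_um = csk$offsets_um, ...),
                     error = function(e) NULL)
      if (!is.null(ak)) {
        res$actin_left_um[t] <- ak["left"] - center
        res$actin_right_um[t] <- ak["right"] - center
      }
    }
  }
  lost <- mean(is.na(res$mem_right_um))
  if (lost > max_lost)
    stopf("peak track lost in %.0f%% of frames (> %.0f%% allowed)",
          100 * lost, 100 * max_lost)
  structure(res, class = c("peak_track", "data.frame"))
}

#' Velocity of a peak-distance series by linear regression
#'
#' Ordinary least squares of distance-to-center against time; the slope is
#' reported in um/min as an unsigned magnitude (`velocity_um_min`), with the
#' signed slope retained in the diagnostics (negative = contraction).
#'
#' @param distance_um Numeric vector of distances (um).
#' @param times_s Time axis (s), same length.
#' @return List: `velocity_um_min`, `slope_um_min` (signed), `se_um_min`,
#'   `r_squared`, `n`.
#' @export
fit_velocity <- function(distance_um, times_s) {
  ok <- is.finite(distance_um) & is.finite(times_s)
  if (sum(ok) < 5L) stopf("need >= 5 frames for a velocity fit")
  if (stats::sd(times_s[ok]) == 0) stopf("degenerate time axis")
  fit <- stats::lm(distance_um[ok] ~ times_s[ok])
  s <- summary(fit)
  slope_min <- unname(stats::coef(fit)[2]) * 60
  list(velocity_um_min = abs(slope_min), slope_um_min = slope_min,
       se_um_min = unname(s$coefficients[2, 2]) * 60,
       r_squared = s$r.squared, n = sum(ok))
}

#' Distance between membrane and actin right-side peaks
#'
#' @param membrane_right_um,actin_right_um Center-relative right-peak
#'   offsets (um), scalars or vectors of equal length (e.g. columns of a
#'   [track_peaks()] result).
#' @return `|membrane - actin|`, elementwise; `NA` where either is missing.
#' @export
membrane_actin_distance <- function(membrane_right_um, actin_right_um) {
  if (length(membrane_right_um) != length(actin_right_um))
    stopf("membrane and actin series must have equal length")
  abs(membrane_right_um - actin_right_um)
}

#' Linear model between normalized diameter and normalized fluorescence
#'
#' OLS fit of `normalized_fluorescence ~ normalized_diameter` (x = diameter,
#' y = fluorescence), the axis convention of the fluorescence-to-diameter
#' transform.
#'
#' @param pairs data.frame with columns `normalized_diameter` and
#'   `normalized_fluorescence` (>= 3 rows).
#' @return Object of class `regression_model`: `slope`, `intercept`,
#'   `r_squared`, standard errors, `n`, and the axis convention tag.
#' @export
fit_fluorescence_diameter <- function(pairs) {
  need <- c("normalized_diameter", "normalized_fluorescence")
  if (!all(need %in% names(pairs))) stopf("pairs must have columns %s",
                                          paste(need, collapse = ", "))
  if (nrow(pairs) < 3L) stopf("need >= 3 pairs")
  if (stats::sd(pairs$normalized_diameter) == 0)
    stopf("zero variance in normalized diameter")
  fit <- stats::lm(normalized_fluorescence ~ normalized_diameter,
                   data = pairs)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 se_slope = unname(s$coefficients[2, 2]),
                 se_intercept = unname(s$coefficients[1, 2]),
                 n = nrow(pairs),
                 axes = "x = normalized diameter, y = normalized fluorescence"),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> y = %.3f x + %.3f (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(" ", x$axes, "\n")
  invisible(x)
}

#' Approximate normalized diameter from a fluorescence value
#'
#' Inverse prediction through the fluorescence-diameter linear model:
#' `x_hat = (f - intercept) / slope`. The estimate is approximate — the
#' model explains only part of the fluorescence variance — and is flagged
#' as such.
#'
#' @param normalized_fluorescence Numeric vector of (F-F0)/F0 values.
#' @param model A [fit_fluorescence_diameter()] result (or a list with
#'   `slope` and `intercept`).
#' @return Numeric vector of approximate normalized diameters, with
#'   `attr(, "approximate") = TRUE`.
#' @export
diameter_from_fluorescence <- function(normalized_fluorescence, model) {
  if (model$slope == 0) stopf("model slope must be nonzero")
  structure((normalized_fluorescence - model$intercept) / model$slope,
            approximate = TRUE)
}
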