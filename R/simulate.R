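#' Camera/detector model for synthetic renders
#'
#' Describes the acquisition device applied on top of the photon signal:
#' an additive per-pixel offset, Gaussian read noise, a linear gain, and the
#' spatial/temporal calibration. `read_noise_var` may be a scalar or a
#' per-pixel matrix (sCMOS-style variance map).
#'
#' @param offset_counts Additive per-pixel baseline (counts).
#' @param read_noise_var Read-noise variance (counts^2); scalar or matrix.
#' @param gain Counts per photon (> 0).
#' @param pixel_size_um Pixel size (um, > 0).
#' @param frame_interval_s Frame interval (s).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(offset_counts = 100, read_noise_var = 4,
                           gain = 1, pixel_size_um = 0.1,
                           frame_interval_s = 1) {
  if (gain <= 0) stopf("gain must be > 0")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (any(read_noise_var < 0)) stopf("read_noise_var must be >= 0")
  structure(list(offset_counts = offset_counts,
                 read_noise_var = read_noise_var, gain = gain,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "detector_model")
}

#' Construct an image stack container
#'
#' @param data Numeric array `T x Y x X x C` (trailing channel dimension may
#'   be dropped for a single channel; it is restored internally).
#' @param pixel_size_um,frame_interval_s Calibrations (> 0).
#' @param channels Character vector of channel names, length `C`.
#' @param metadata Optional named list carried along (ground truth, flags).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_s, channels,
                        metadata = list()) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stopf("data must be a T x Y x X x C array")
  if (dim(data)[4] != length(channels))
    stopf("channel names do not match the channel dimension")
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stopf("calibrations must be > 0")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channels = channels, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames, %d x %d px, channels: %s\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  cat(sprintf("  pixel %.3f um, frame interval %.3f s\n",
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Render super-resolved cross-section profiles of the midpiece
#'
#' For each requested arclength position and time point, renders the
#' intensity profile along a crossline perpendicular to the midpiece axis:
#' two membrane peaks at the tube surface (+/- radius(s, t)) and, when the
#' actin channel is requested, two actin peaks displaced inwards by the
#' membrane-actin gap. Peaks are Gaussians of width `psf_sigma_um`
#' (the point-spread function folded into the peak shape analytically);
#' optional i.i.d. Gaussian noise is added on top. The generating radius
#' series is attached as ground truth.
#'
#' @param geom A [make_geometry()] model.
#' @param psf_sigma_um Peak width (um, >= 0).
#' @param positions_um Crossline positions (um) within `[0, length_um]`.
#' @param times_s Frame times (s).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param channels Subset of `c("membrane", "actin")`.
#' @param offset_step_um Radial sampling step (um).
#' @param halfwidth_um Crossline half-length (um).
#' @return A `cross_section_kymograph`: positions x times x offsets arrays,
#'   one per channel, with ground truth in `$truth`.
#' @export
render_cross_profiles <- function(geom, psf_sigma_um = 0.05,
                                  positions_um = seq(0, 20, by = 2.5),
                                  times_s = seq(0, 180, by = 2),
                                  noise_sd = 0, seed = 1L,
                                  channels = "membrane",
                                  offset_step_um = 0.02,
                                  halfwidth_um = 1) {
  stopifnot(inherits(geom, "midpiece_geometry"))
  if (psf_sigma_um < 0) stopf("psf_sigma_um must be >= 0")
  if (any(positions_um < 0 | positions_um > geom$length_um))
    stopf("positions outside [0, %.2f]", geom$length_um)
  channels <- match.arg(channels, c("membrane", "actin"),
                        several.ok = TRUE)
  offsets <- seq(-halfwidth_um, halfwidth_um, by = offset_step_um)
  truth <- true_radius(geom, positions_um, times_s)
  sig <- max(psf_sigma_um, offset_step_um / 4)   # delta-like when psf = 0
  peak_pair <- function(r) {
    stats::dnorm(offsets, mean = -r, sd = sig) +
      stats::dnorm(offsets, mean = r, sd = sig)
  }
  arrs <- lapply(channels, function(ch) {
    a <- array(0, dim = c(length(positions_um), length(times_s),
                          length(offsets)))
    for (i in seq_along(positions_um)) {
      for (j in seq_along(times_s)) {
        r <- truth$radius_um[i, j]
        if (ch == "actin") r <- max(r - geom$gap_membrane_actin_um,
                                    offset_step_um)
        a[i, j, ] <- peak_pair(r) * sig * sqrt(2 * pi)  # unit peak height
      }
    }
    a
  })
  names(arrs) <- channels
  if (noise_sd > 0) {
    arrs <- with_seed(seed, lapply(arrs, function(a)
      a + stats::rnorm(length(a), sd = noise_sd)))
  }
  cross_section_kymograph(channels = arrs, positions_um = positions_um,
                          times_s = times_s, offsets_um = offsets,
                          truth = truth)
}

#' Render a synthetic wide-field time-lapse of a midpiece
#'
#' Places a straight midpiece horizontally in the field and renders up to
#' three channels: a membrane dye whose midpiece intensity rises after
#' `fm_onset_s` in proportion to the local fractional contraction (scaled by
#' the slope of the fluorescence-diameter model, so the downstream regression
#' stage is self-consistent), a calcium indicator showing a transient that
#' starts at `ca_onset_s`, and a dim constant nuclear channel. Photon shot
#' noise (Poisson) and detector offset/read noise are applied per pixel.
#'
#' @param geom A [make_geometry()] model.
#' @param channels Subset of `c("membrane", "calcium", "nuclear")`.
#' @param detector A [detector_model()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param fm_slope Coupling between fractional contraction and the
#'   membrane-dye (F-F0)/F0 rise; default is the slope magnitude of the
#'   fluorescence-diameter model.
#' @param base_photons Peak photon rate of the midpiece ridge at baseline.
#' @return An `image_stack` with ground truth (normalized diameter over the
#'   midline, event onsets, midline coordinates) in `$metadata$truth`.
#' @export
render_timelapse <- function(geom, channels = c("membrane", "calcium"),
                             detector = detector_model(),
                             n_frames = 120L, seed = 1L,
                             fm_slope = 8.90, base_photons = 200) {
  stopifnot(inherits(geom, "midpiece_geometry"),
            inherits(detector, "detector_model"))
  channels <- match.arg(channels, c("membrane", "calcium", "nuclear"),
                        several.ok = TRUE)
  if (length(channels) < 1L) stopf("at least one channel required")
  px <- detector$pixel_size_um
  times_s <- (seq_len(n_frames) - 1L) * detector$frame_interval_s
  margin_px <- 5L
  nx <- as.integer(ceiling(geom$length_um / px)) + 2L * margin_px
  ny <- as.integer(ceiling(2 / px))  # 2 um tall field
  y0 <- (ny + 1) / 2
  x_um <- ((seq_len(nx)) - margin_px - 0.5) * px   # arclength of each column
  on_mid <- x_um >= 0 & x_um <= geom$length_um
  pos_mid <- pmin(pmax(x_um, 0), geom$length_um)
  truth <- true_radius(geom, pos_mid, times_s)
  ridge <- exp(-((seq_len(ny) - y0) * px)^2 / (2 * 0.15^2))  # cross profile
  ca_trace <- ca_transient(times_s, geom$ca_onset_s)

  rate <- array(0, dim = c(n_frames, ny, nx, length(channels)))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    for (t in seq_len(n_frames)) {
      amp <- rep(0, nx)
      if (ch == "membrane") {
        dff <- fm_slope * (1 - truth$normalized_diameter[, t])
        amp[on_mid] <- base_photons * 0.3 * (1 + dff[on_mid])
      } else if (ch == "calcium") {
        amp[on_mid] <- base_photons * 0.15 * (1 + ca_trace[t])
      } else {
        amp[on_mid] <- base_photons * 0.05
      }
      rate[t, , , ci] <- outer(ridge, amp)
    }
  }
  rn_sd <- sqrt(mean(detector$read_noise_var))
  data <- with_seed(seed, {
    counts <- detector$gain *
      array(stats::rpois(length(rate), rate), dim = dim(rate))
    counts + detector$offset_counts +
      array(stats::rnorm(length(rate), sd = rn_sd), dim = dim(rate))
  })
  image_stack(data, px, detector$frame_interval_s, channels,
              metadata = list(truth = c(truth, list(
                midline_y_um = y0 * px, x0_um = (margin_px + 0.5) * px,
                times_s = times_s,
                ca_onset_s = geom$ca_onset_s, fm_onset_s = geom$fm_onset_s))))
}

# Calcium transient: logistic rise at onset, slow exponential decay.
ca_transient <- function(times_s, onset_s, amplitude = 1.5,
                         rise_rate = 0.5, decay_s = 60) {
  rise <- 1 / (1 + exp(-rise_rate * (times_s - onset_s)))
  decay <- exp(-pmax(times_s - onset_s, 0) / decay_s)
  amplitude * rise * decay
}

#' Render a cross-section kymograph with peaks moving at a fixed rate
#'
#' Noise-free single-position cross-section kymograph in which the peak
#' pair contracts symmetrically toward the center: the distance from each
#' peak to the center decreases linearly at `rate_um_min`. Used to exercise
#' derivative-based peak tracking and the velocity fit against a known
#' ground truth.
#'
#' @param rate_um_min Contraction rate of the peak-to-center distance
#'   (um/min).
#' @param duration_s Record length (s).
#' @param fps Frames per second.
#' @param r0_um Initial peak offset from the center (um).
#' @param channel Channel name for the rendered peaks (`"membrane"` or
#'   `"actin"`).
#' @param psf_sigma_um Peak width (um).
#' @param offset_step_um,halfwidth_um Radial grid.
#' @return A [cross_section_kymograph()] with the true peak-offset series
#'   in `$truth$r_um`.
#' @export
render_peak_motion_profiles <- function(rate_um_min, duration_s = 3,
                                        fps = 20, r0_um = 0.9,
                                        channel = "membrane",
                                        psf_sigma_um = 0.05,
                                        offset_step_um = 0.02,
                                        halfwidth_um = 1.2) {
  times_s <- seq(0, duration_s, by = 1 / fps)
  r <- r0_um - (rate_um_min / 60) * times_s
  if (any(r <= 2 * psf_sigma_um))
    stopf("peaks reach the center within the record; increase r0_um")
  offsets <- seq(-halfwidth_um, halfwidth_um, by = offset_step_um)
  arr <- array(0, dim = c(1L, length(times_s), length(offsets)))
  for (t in seq_along(times_s)) {
    arr[1L, t, ] <- exp(-(offsets - r[t])^2 / (2 * psf_sigma_um^2)) +
      exp(-(offsets + r[t])^2 / (2 * psf_sigma_um^2))
  }
  ch <- list(arr); names(ch) <- channel
  cross_section_kymograph(ch, positions_um = 0, times_s = times_s,
                          offsets_um = offsets,
                          truth = list(r_um = r, rate_um_min = rate_um_min))
}

#' Simulate single-molecule localizations on a multi-start helix
#'
#' Samples `n_points` localizations uniformly along arclength, assigns each
#' to one of `n_strands` helix strands (phase-offset by `2*pi/n_strands`),
#' places it on the strand at the geometry's pitch and radius, and perturbs
#' all coordinates by isotropic Gaussian noise of SD `precision_nm`. The
#' helix axis lies along x.
#'
#' @param geom A [make_geometry()] model.
#' @param n_points Number of localizations (> 0).
#' @param precision_nm Localization precision (nm, >= 0).
#' @param z_included If `FALSE`, the z coordinate is omitted (2-D table).
#' @param seed Integer seed.
#' @return A `localization_table` data.frame with columns `x_nm, y_nm,
#'   z_nm (optional), frame, precision_nm`; ground truth in
#'   `attr(, "truth")`.
#' @export
simulate_localizations <- function(geom, n_points = 5e4, precision_nm = 15,
                                   z_included = TRUE, seed = 1L) {
  stopifnot(inherits(geom, "midpiece_geometry"))
  if (n_points <= 0) stopf("n_points must be > 0")
  if (precision_nm < 0) stopf("precision_nm must be >= 0")
  L_nm <- geom$length_um * 1000
  tab <- with_seed(seed, {
    s <- stats::runif(n_points, 0, L_nm)
    strand <- sample.int(geom$n_strands, n_points, replace = TRUE) - 1L
    phase <- 2 * pi * s / geom$helix_pitch_nm +
      2 * pi * strand / geom$n_strands
    x <- s
    y <- geom$helix_radius_nm * cos(phase)
    z <- geom$helix_radius_nm * sin(phase)
    if (precision_nm > 0) {
      x <- x + stats::rnorm(n_points, sd = precision_nm)
      y <- y + stats::rnorm(n_points, sd = precision_nm)
      z <- z + stats::rnorm(n_points, sd = precision_nm)
    }
    d <- data.frame(x_nm = x, y_nm = y, z_nm = z,
                    frame = seq_len(n_points),
                    precision_nm = precision_nm)
    attr(d, "strand") <- strand
    d
  })
  strand <- attr(tab, "strand")
  if (!z_included) tab$z_nm <- NULL
  structure(tab, class = c("localization_table", "data.frame"),
            truth = list(pitch_nm = geom$helix_pitch_nm,
                         radius_nm = geom$helix_radius_nm,
                         n_strands = geom$n_strands,
                         length_um = geom$length_um,
                         strand = strand))
}

#' Simulate an intensity-fluctuation stack for number & brightness
#'
#' Per frame and pixel, the count is `brightness * Poisson(M) + offset +
#' read noise`, where `M` is the per-pixel mean molecule number. Under this
#' model the temporal variance over mean (after detector correction) is the
#' molecular brightness and mean^2 over variance the molecule number.
#'
#' @param n_molecules_map Matrix (Y x X) of mean molecule numbers; a scalar
#'   is recycled to a 1 x 1 map.
#' @param brightness_counts Counts per molecule per frame.
#' @param n_frames Number of frames (>= 2).
#' @param detector A [detector_model()] or `NULL` for an ideal detector.
#' @param seed Integer seed.
#' @return An `image_stack` (single channel `"nb"`); metadata records the
#'   generating parameters and a `low_confidence` flag when `n_frames < 10`.
#' @export
simulate_nb_stack <- function(n_molecules_map, brightness_counts = 1,
                              n_frames = 1000L, detector = NULL,
                              seed = 1L) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (!is.matrix(n_molecules_map))
    n_molecules_map <- matrix(n_molecules_map, 1, 1)
  ny <- nrow(n_molecules_map); nx <- ncol(n_molecules_map)
  offset <- if (is.null(detector)) 0 else detector$offset_counts
  rn_var <- if (is.null(detector)) 0 else detector$read_noise_var
  data <- with_seed(seed, {
    arr <- array(0, dim = c(n_frames, ny, nx))
    for (t in seq_len(n_frames)) {
      fr <- brightness_counts *
        matrix(stats::rpois(ny * nx, n_molecules_map), ny, nx)
      if (any(rn_var > 0))
        fr <- fr + matrix(stats::rnorm(ny * nx, sd = sqrt(rn_var)), ny, nx)
      arr[t, , ] <- fr + offset
    }
    arr
  })
  image_stack(data,
              pixel_size_um = if (is.null(detector)) 0.1 else detector$pixel_size_um,
              frame_interval_s = if (is.null(detector)) 1 else detector$frame_interval_s,
              channels = "nb",
              metadata = list(true_n = n_molecules_map,
                              true_brightness = brightness_counts,
                              low_confidence = n_frames < 10L))
}

#' Simulate (normalized diameter, normalized fluorescence) pairs
#'
#' Draws `x` uniformly on `diameter_range` and sets
#' `y = slope * x + intercept + e`, with the noise SD chosen analytically so
#' the expected coefficient of determination equals `target_r2`:
#' `sd^2 = slope^2 * var(x) * (1 - R2) / R2` with `var(x)` the population
#' variance of the uniform draw.
#'
#' @param slope,intercept Linear-model parameters.
#' @param target_r2 Expected R^2 in `(0, 1]` (1 gives an exact line).
#' @param n Number of pairs (>= 3).
#' @param diameter_range Length-2 range of normalized diameter.
#' @param seed Integer seed.
#' @return data.frame with columns `normalized_diameter`,
#'   `normalized_fluorescence`; the analytic noise SD in `attr(, "noise_sd")`.
#' @export
simulate_regression_pairs <- function(slope = 8.90, intercept = -8.05,
                                      target_r2 = 0.32, n = 2000L,
                                      diameter_range = c(0.55, 1.05),
                                      seed = 1L) {
  if (n < 3) stopf("n must be >= 3")
  if (target_r2 <= 0 || target_r2 > 1) stopf("target_r2 must be in (0, 1]")
  if (diff(range(diameter_range)) <= 0) stopf("degenerate diameter_range")
  var_x <- diff(range(diameter_range))^2 / 12
  sd_noise <- if (target_r2 == 1) 0 else
    sqrt(slope^2 * var_x * (1 - target_r2) / target_r2)
  d <- with_seed(seed, {
    x <- stats::runif(n, diameter_range[1], diameter_range[2])
    y <- slope * x + intercept +
      if (sd_noise > 0) stats::rnorm(n, sd = sd_noise) else 0
    data.frame(normalized_diameter = x, normalized_fluorescence = y)
  })
  attr(d, "noise_sd") <- sd_noise
  d
}

#' Simulate named ROI fluorescence traces
#'
#' Builds piecewise traces (flat baseline plus step, transient, or ramp
#' events) for a set of named ROIs, each tagged with a channel role, on a
#' common baseline level, with optional Gaussian noise. Event amplitudes are
#' expressed as fractions of the baseline so the normalized (F-F0)/F0 trace
#' reaches the stated amplitude.
#'
#' @param spec List of ROI specs; each element is a list with fields
#'   `name`, `channel` (one of `"calcium"`, `"membrane"`, `"nuclear"`,
#'   `"other"`), and `events` — a list of event lists with `type`
#'   (`"flat"`, `"step"`, `"ramp"`, `"transient"`), `onset` (frame),
#'   `amplitude` (fraction of baseline; negative allowed), and for
#'   transients `decay` (frames). See [ae_trace_spec()] and
#'   [fusion_trace_spec()].
#' @param n_frames Record length.
#' @param noise_sd Gaussian noise SD as a fraction of baseline.
#' @param seed Integer seed.
#' @param baseline_window Integer range (frames) used as F0 window.
#' @param frame_interval_s Frame interval (s).
#' @return A `trace_set`: matrix of raw traces (frames x ROIs), channel
#'   roles, baseline window, stimulus frame, and ground-truth onsets.
#' @export
simulate_traces <- function(spec, n_frames = 200L, noise_sd = 0,
                            seed = 1L, baseline_window = c(1L, 30L),
                            frame_interval_s = 1) {
  base_level <- 100
  t <- seq_len(n_frames)
  truth_onsets <- list()
  traces <- sapply(spec, function(roi) {
    y <- rep(base_level, n_frames)
    for (ev in roi$events) {
      type <- ev$type
      if (type == "flat") next
      if (ev$onset < 1 || ev$onset > n_frames)
        stopf("event onset outside record for ROI '%s'", roi$name)
      after <- t >= ev$onset
      if (type == "step") {
        y[after] <- y[after] + base_level * ev$amplitude
      } else if (type == "ramp") {
        y[after] <- y[after] +
          base_level * ev$amplitude * (t[after] - ev$onset) /
          max(n_frames - ev$onset, 1)
      } else if (type == "transient") {
        y[after] <- y[after] + base_level * ev$amplitude *
          exp(-(t[after] - ev$onset) / ev$decay)
      } else stopf("unknown event type '%s'", type)
    }
    y
  })
  colnames(traces) <- vapply(spec, `[[`, character(1), "name")
  truth_onsets <- lapply(spec, function(roi) {
    on <- vapply(roi$events, function(ev)
      if (ev$type == "flat") NA_real_ else ev$onset, numeric(1))
    if (all(is.na(on))) NA_real_ else min(on, na.rm = TRUE)
  })
  names(truth_onsets) <- colnames(traces)
  if (noise_sd > 0)
    traces <- with_seed(seed, traces +
      matrix(stats::rnorm(length(traces), sd = base_level * noise_sd),
             nrow(traces)))
  trace_set(traces,
            channels = vapply(spec, `[[`, character(1), "channel"),
            baseline_window = baseline_window,
            stimulus_frame = baseline_window[2] + 1L,
            frame_interval_s = frame_interval_s,
            truth = list(onsets = truth_onsets))
}

#' Canonical event specs for the acrosomal-exocytosis and fusion scenarios
#'
#' `ae_trace_spec()` describes the acrosomal-exocytosis scenario: a midpiece
#' calcium transient followed by a sustained membrane-dye rise.
#' `fusion_trace_spec()` describes the gamete-fusion scenario: nuclear-dye
#' rise (dye transfer), then a midpiece calcium decrease, then the
#' membrane-dye rise that accompanies contraction.
#'
#' @param ca_onset,fm_onset,hoechst_onset Event frames.
#' @return A spec list for [simulate_traces()].
#' @export
ae_trace_spec <- function(ca_onset = 50L, fm_onset = 80L) {
  list(
    list(name = "midpiece_ca", channel = "calcium",
         events = list(list(type = "transient", onset = ca_onset,
                            amplitude = 1.5, decay = 60))),
    list(name = "midpiece_fm", channel = "membrane",
         events = list(list(type = "step", onset = fm_onset,
                            amplitude = 1.0)))
  )
}

#' @rdname ae_trace_spec
#' @export
fusion_trace_spec <- function(hoechst_onset = 40L, ca_onset = 70L,
                              fm_onset = 100L) {
  list(
    list(name = "head_hoechst", channel = "nuclear",
         events = list(list(type = "step", onset = hoechst_onset,
                            amplitude = 2.0))),
    list(name = "midpiece_ca", channel = "calcium",
         events = list(list(type = "step", onset = ca_onset,
                            amplitude = -0.5))),
    list(name = "midpiece_fm", channel = "membrane",
         events = list(list(type = "step", onset = fm_onset,
                            amplitude = 1.0)))
  )
}
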