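# Synthetic-data generators: geometry defaults, closed-form reductions,
# reproducibility, and statistical structure.

test_that("geometry defaults describe the intact midpiece and validate overrides", {
  g <- make_geometry()
  expect_equal(g$length_um, 21.2)
  expect_equal(g$helix_pitch_nm, 244)
  expect_equal(g$helix_radius_nm, 300)
  expect_equal(round(1000 * g$length_um / g$helix_pitch_nm), 87)

  gr <- make_geometry(list(helix_pitch_nm = 159, helix_radius_nm = 252))
  expect_equal(gr$helix_pitch_nm, 159)

  expect_error(make_geometry(list(not_a_field = 1)), "unknown")
  expect_error(make_geometry(list(contraction_amplitude = 1.2)), "amplitude")
  expect_error(make_geometry(list(foci = data.frame(
    position_um = 30, onset_s = 60, spread_um = 1))), "positions")
  expect_error(make_geometry(list(ca_onset_s = 100, fm_onset_s = 50)),
               "precede")
})

test_that("static noise-free profiles reduce to the closed-form tube", {
  g <- make_geometry()   # amplitude 0: static
  csk <- static_csk(g, n_frames = 3)
  prof <- csk$channels$membrane[1, 1, ]
  sep <- argmax_pair_separation(prof, csk$offset_step_um)
  expect_lt(abs(sep - 0.731), 2 * csk$offset_step_um)
  # constant in time
  expect_equal(csk$channels$membrane[1, 1, ], csk$channels$membrane[1, 3, ])
  expect_true(all(csk$truth$normalized_diameter == 1))
})

test_that("contraction amplitude sets the late-time separation", {
  g <- make_geometry(list(contraction_amplitude = 0.2))
  t_late <- 600   # far beyond onset + propagation
  csk <- render_cross_profiles(g, positions_um = 3, times_s = c(0, t_late),
                               noise_sd = 0)
  expect_equal(csk$truth$normalized_diameter[1, 2], 0.8, tolerance = 1e-6)
  d0 <- diameter_from_profile(csk$channels$membrane[1, 1, ],
                              csk$offset_step_um)
  d1 <- diameter_from_profile(csk$channels$membrane[1, 2, ],
                              csk$offset_step_um)
  expect_equal(d1 / d0, 0.8, tolerance = 0.05)
})

test_that("renders are bit-reproducible given the seed", {
  g <- make_geometry()
  a <- render_cross_profiles(g, positions_um = 5, times_s = 0:5,
                             noise_sd = 0.1, seed = 42)
  b <- render_cross_profiles(g, positions_um = 5, times_s = 0:5,
                             noise_sd = 0.1, seed = 42)
  c <- render_cross_profiles(g, positions_um = 5, times_s = 0:5,
                             noise_sd = 0.1, seed = 43)
  expect_identical(a$channels, b$channels)
  expect_false(identical(a$channels, c$channels))

  l1 <- simulate_localizations(g, 500, 15, seed = 9)
  l2 <- simulate_localizations(g, 500, 15, seed = 9)
  expect_identical(l1$x_nm, l2$x_nm)
})

test_that("noise-free single-strand localizations sit exactly on the helix", {
  g <- make_geometry(list(n_strands = 1L))
  locs <- simulate_localizations(g, 2000, precision_nm = 0, seed = 3)
  r <- sqrt(locs$y_nm^2 + locs$z_nm^2)
  expect_equal(r, rep(g$helix_radius_nm, nrow(locs)), tolerance = 1e-9)
})

test_that("localization cloud spans the midpiece length", {
  g <- make_geometry()
  locs <- simulate_localizations(g, 10000, 15, seed = 4)
  expect_equal(diff(range(locs$x_nm)) / 1000, 21.2, tolerance = 0.3 / 21.2)
})

test_that("noise-free strand coordinates are periodic at the pitch", {
  g <- make_geometry(list(helix_pitch_nm = 500))
  locs <- simulate_localizations(g, 20000, precision_nm = 0, seed = 5)
  strand <- attr(locs, "truth")$strand
  s0 <- locs$x_nm[strand == 0]
  y0 <- locs$y_nm[strand == 0]
  # independent period oracle: autocorrelation of the binned strand signal
  bin <- 10   # nm
  grid <- seq(0, max(s0), by = bin)
  sig <- tapply(y0, cut(s0, grid), mean)
  sig <- sig[is.finite(sig)]
  a <- stats::acf(sig, lag.max = length(sig) - 1, plot = FALSE,
                  na.action = stats::na.pass)$acf[, 1, 1]
  lags <- 2:(length(a) - 1)
  peaks <- lags[a[lags] > a[lags - 1] & a[lags] >= a[lags + 1] & a[lags] > 0.5]
  period_nm <- (peaks[1] - 1) * bin
  expect_lte(abs(period_nm - 500), bin)   # oracle quantized to the bin
})

test_that("fluctuation stacks have Poisson moment structure", {
  st <- simulate_nb_stack(matrix(50, 3, 3), brightness_counts = 1,
                          n_frames = 1000, seed = 6)
  m <- apply(st$data[, , , 1], c(2, 3), mean)
  v <- apply(st$data[, , , 1], c(2, 3), var)
  # variance ~ mean for pure Poisson, within 3 SE of the variance estimate
  se_v <- sqrt(2 / 999) * v
  expect_true(all(abs(v - m) < 3 * (se_v + sqrt(v / 1000))))

  st2 <- simulate_nb_stack(matrix(50, 2, 2), brightness_counts = 4,
                           n_frames = 1000, seed = 7)
  m2 <- mean(st2$data)
  expect_equal(m2, 200, tolerance = 3 * sqrt(16 * 50 / 1000) / 200)

  st3 <- simulate_nb_stack(matrix(5, 2, 2), n_frames = 2, seed = 8)
  expect_true(st3$metadata$low_confidence)
  expect_error(simulate_nb_stack(matrix(5, 2, 2), n_frames = 1), "n_frames")
})

test_that("regression pairs reach the requested R-squared in expectation", {
  exact <- simulate_regression_pairs(slope = 2, intercept = 1,
                                     target_r2 = 1, n = 100, seed = 10)
  fit <- suppressWarnings(fit_fluorescence_diameter(exact))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # analytic noise-sd formula, checked empirically over replicates
  r2 <- vapply(1:100, function(s) {
    p <- simulate_regression_pairs(n = 500, seed = s)
    summary(lm(normalized_fluorescence ~ normalized_diameter, p))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.32, tolerance = 0.03)

  expect_error(simulate_regression_pairs(n = 2), "n must")
  expect_error(simulate_regression_pairs(target_r2 = 0), "target_r2")
  expect_error(simulate_regression_pairs(diameter_range = c(1, 1)),
               "degenerate")
})

test_that("trace generator produces flat, step, and ordered fusion traces", {
  flat <- simulate_traces(list(list(name = "roi", channel = "other",
                                    events = list(list(type = "flat")))),
                          n_frames = 100)
  norm <- normalize_trace(flat$traces[, "roi"], flat$baseline_window)
  expect_equal(max(abs(norm)), 0)

  stepped <- simulate_traces(list(list(
    name = "roi", channel = "membrane",
    events = list(list(type = "step", onset = 50, amplitude = 1)))),
    n_frames = 100, noise_sd = 0.02, seed = 11)
  norm <- normalize_trace(stepped$traces[, "roi"], stepped$baseline_window)
  on <- detect_event_onset(norm, stepped$baseline_window)
  expect_lte(abs(on - 50), 2)

  fus <- simulate_traces(fusion_trace_spec(), noise_sd = 0.02, seed = 12)
  expect_identical(
    unname(unlist(fus$truth$onsets[c("head_hoechst", "midpiece_ca",
                                     "midpiece_fm")])),
    c(40, 70, 100))
  expect_error(simulate_traces(list(list(
    name = "r", channel = "other",
    events = list(list(type = "step", onset = 999, amplitude = 1)))),
    n_frames = 100), "onset outside")
})

test_that("timelapse render obeys the event clock and detector model", {
  g <- make_geometry(list(contraction_amplitude = 0.3, ca_onset_s = 20,
                          fm_onset_s = 35,
                          foci = data.frame(position_um = 10, onset_s = 35,
                                            spread_um = 1),
                          propagation_um_s = 2))
  det <- detector_model(offset_counts = 0, read_noise_var = 0, gain = 1,
                        pixel_size_um = 0.2, frame_interval_s = 1)
  st <- render_timelapse(g, c("membrane", "calcium"), det, n_frames = 80,
                         seed = 13)
  # ROI trace over the midpiece ridge for each channel
  truth <- st$metadata$truth
  ys <- round(truth$midline_y_um / det$pixel_size_um) + (-1:1)
  roi_trace <- function(ci) apply(st$data[, ys, , ci], 1, mean)
  bw <- c(1L, 15L)
  ca_on <- detect_event_onset(normalize_trace(roi_trace(2), bw), bw,
                              k_sigma = 5)
  fm_on <- detect_event_onset(normalize_trace(roi_trace(1), bw), bw,
                              k_sigma = 5)
  expect_false(is.na(ca_on))
  expect_false(is.na(fm_on))
  expect_lt(ca_on, fm_on)

  # static tube: membrane trace flat within shot noise
  g0 <- make_geometry()
  st0 <- render_timelapse(g0, "membrane", det, n_frames = 40, seed = 14)
  tr <- normalize_trace(apply(st0$data[, ys, , 1], 1, mean), bw)
  expect_lt(max(abs(tr)), 0.05)

  # detector offset shifts the mean image by exactly that offset
  det_o <- detector_model(offset_counts = 100, read_noise_var = 0, gain = 1,
                          pixel_size_um = 0.2, frame_interval_s = 1)
  st_o <- render_timelapse(g0, "membrane", det_o, n_frames = 5, seed = 15)
  st_z <- render_timelapse(g0, "membrane",
                           detector_model(0, 0, 1, 0.2, 1),
                           n_frames = 5, seed = 15)
  expect_equal(st_o$data - st_z$data,
               array(100, dim = dim(st_o$data)))
})
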