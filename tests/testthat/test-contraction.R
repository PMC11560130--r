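# Diameter estimation, onset/foci analysis, peak tracking, velocity fits,
# and the fluorescence-diameter transform.

test_that("ACF diameter recovers impulse and Gaussian peak separations", {
  # two unit impulses at +/- 0.35 um
  offsets <- seq(-1, 1, by = 0.01)
  y <- numeric(length(offsets))
  y[match(c(-0.35, 0.35), round(offsets, 10))] <- 1
  expect_equal(diameter_from_profile(y, 0.01), 0.70, tolerance = 0.01)

  # two Gaussians on a flat background, oracle = direct argmax pair
  p <- two_peak_profile(0.50, sigma_um = 0.05, background = 0.2)
  d <- diameter_from_profile(p$y, p$step)
  oracle <- argmax_pair_separation(p$y, p$step)
  expect_lte(abs(d - oracle), p$step)

  # intact-geometry render
  g <- make_geometry()
  csk <- static_csk(g)
  d <- diameter_from_profile(csk$channels$membrane[1, 1, ],
                             csk$offset_step_um)
  expect_equal(d, 0.731, tolerance = 0.02 / 0.731)
})

test_that("ACF diameter equals the argmax-pair oracle on random profiles", {
  set.seed(20)
  for (i in 1:100) {
    sep <- runif(1, 0.3, 1.2)
    p <- two_peak_profile(sep, sigma_um = runif(1, 0.03, 0.08),
                          background = runif(1, 0, 0.3),
                          amplitude = runif(1, 0.5, 2))
    d <- diameter_from_profile(p$y, p$step)
    oracle <- argmax_pair_separation(p$y, p$step)
    expect_lte(abs(d - oracle), p$step)
  }
})

test_that("diameter estimate is invariant to intensity scaling and offsets", {
  p <- two_peak_profile(0.6)
  d0 <- diameter_from_profile(p$y, p$step)
  expect_equal(diameter_from_profile(5 * p$y + 3, p$step), d0)
  # flat profile: undetermined
  expect_true(is.na(diameter_from_profile(rep(1, 101), 0.02)))
  # single central peak: no secondary maximum in the physiological band
  one <- exp(-seq(-1, 1, by = 0.02)^2 / (2 * 0.03^2))
  expect_true(is.na(diameter_from_profile(one, 0.02)))
})

test_that("normalized diameter kymograph is 1 for a static tube and tracks contraction", {
  g0 <- make_geometry()
  csk0 <- render_cross_profiles(g0, positions_um = c(5, 10),
                                times_s = seq(0, 18, by = 2), noise_sd = 0)
  ds0 <- normalized_diameter_kymograph(csk0, c(1, 5))
  expect_true(all(abs(ds0$normalized - 1) < 1e-9))

  g <- make_geometry(list(contraction_amplitude = 0.2))
  times <- seq(0, 400, by = 5)
  csk <- render_cross_profiles(g, positions_um = c(3), times_s = times,
                               noise_sd = 0)
  ds <- normalized_diameter_kymograph(csk, c(1, 5))
  # plateau matches the generator amplitude
  expect_equal(ds$normalized[1, length(times)], 0.8, tolerance = 0.03)
  # monotone decline after induction (noise-free)
  expect_true(all(diff(ds$normalized[1, ]) < 1e-6))
  # baseline mean ~ 1 by construction
  expect_equal(mean(ds$normalized[1, 1:5]), 1, tolerance = 1e-9)
})

test_that("contraction onset detection honours threshold and persistence", {
  expect_true(is.na(detect_contraction_onset(rep(1, 50))))
  stepped <- c(rep(1, 39), rep(0.8, 21))
  expect_equal(detect_contraction_onset(stepped, 0.1, 5), 40)
  # a blip shorter than the persistence does not trigger
  blip <- rep(1, 60); blip[20:22] <- 0.7
  expect_true(is.na(detect_contraction_onset(blip, 0.1, 5)))
})

test_that("noisy contraction onsets land within 3 frames of the noise-free answer", {
  g <- make_geometry(list(contraction_amplitude = 0.3))
  positions <- seq(0, 20, by = 2.5)
  times <- seq(0, 240, by = 2)
  ref_csk <- render_cross_profiles(g, positions_um = positions,
                                   times_s = times, noise_sd = 0)
  ref <- apply(normalized_diameter_kymograph(ref_csk, c(1, 25))$normalized,
               1, detect_contraction_onset)
  for (s in 1:10) {   # peak height 1, noise sd 0.2: SNR 5
    csk <- render_cross_profiles(g, positions_um = positions,
                                 times_s = times, noise_sd = 0.2, seed = s)
    on <- apply(normalized_diameter_kymograph(csk, c(1, 25))$normalized,
                1, detect_contraction_onset)
    expect_lte(max(abs(on - ref), na.rm = TRUE), 3)
  }
})

test_that("initiation foci are local onset minima with region labels", {
  pos <- seq(0, 20, by = 2.5)
  # single focus at 3 um, onset propagating outward
  onset1 <- 60 + abs(pos - 3) / 0.2
  f1 <- find_initiation_foci(pos, onset1)
  expect_equal(nrow(f1), 1)
  expect_equal(f1$position_um, 2.5)
  expect_equal(as.character(f1$region), "proximal")

  # two foci at 3 and 16 um
  onset2 <- 60 + pmin(abs(pos - 3), abs(pos - 16)) / 0.2
  f2 <- find_initiation_foci(pos, onset2)
  expect_equal(nrow(f2), 2)
  expect_setequal(as.character(f2$region), c("proximal", "distal"))

  # simultaneous onset everywhere: one focus at the smallest position
  f3 <- find_initiation_foci(pos, rep(60, length(pos)))
  expect_equal(nrow(f3), 1)
  expect_equal(f3$position_um, 0)

  expect_error(find_initiation_foci(pos, rep(NA_real_, length(pos))),
               ">= 3 positions")
})

test_that("membrane peaks are found at derivative sign changes, sub-step refined", {
  p <- two_peak_profile(0.70, sigma_um = 0.06)
  pk <- find_membrane_peaks(p$y, p$step)
  expect_equal(unname(pk["left"]), -0.35, tolerance = 1e-3)
  expect_equal(unname(pk["right"]), 0.35, tolerance = 1e-3)
  # agreement with the ACF diameter within one offset step
  d <- diameter_from_profile(p$y, p$step)
  expect_lte(abs((pk["right"] - pk["left"]) - d), p$step)

  # four peaks (membrane + actin): outermost pair wins
  off <- seq(-1, 1, by = 0.02)
  y4 <- exp(-(off - 0.37)^2 / (2 * 0.05^2)) +
    exp(-(off + 0.37)^2 / (2 * 0.05^2)) +
    exp(-(off - 0.19)^2 / (2 * 0.05^2)) +
    exp(-(off + 0.19)^2 / (2 * 0.05^2))
  pk4 <- find_membrane_peaks(y4, 0.02)
  expect_equal(unname(pk4["right"]), 0.37, tolerance = 0.02)
  expect_error(find_membrane_peaks(exp(-off^2 / 0.005), 0.02),
               "fewer than two")
})

test_that("peak tracking centers on the membrane pair and survives translation", {
  g <- make_geometry()
  csk <- static_csk(g, channels = c("membrane", "actin"), n_frames = 6)
  tr <- track_peaks(csk)
  # symmetric tube: center at 0, right peak at the membrane radius
  expect_true(all(abs(tr$center_um) < 1e-6))
  expect_equal(mean(tr$mem_right_um), 0.731 / 2, tolerance = 0.01)

  # rigid translation: center moves, center-relative distances unchanged
  shift_bins <- 5
  shifted <- csk
  for (ch in names(shifted$channels)) {
    a <- shifted$channels[[ch]]
    n_off <- dim(a)[3]
    a2 <- a
    a2[, , (shift_bins + 1):n_off] <- a[, , 1:(n_off - shift_bins)]
    a2[, , 1:shift_bins] <- 0
    shifted$channels[[ch]] <- a2
  }
  tr2 <- track_peaks(shifted)
  expect_equal(mean(tr2$center_um), shift_bins * csk$offset_step_um,
               tolerance = 1e-3)
  expect_equal(tr2$mem_right_um, tr$mem_right_um, tolerance = 1e-3)
})

test_that("velocity fits recover generator rates exactly on noise-free input", {
  m <- render_peak_motion_profiles(14, r0_um = 0.9)
  tr <- track_peaks(m)
  v <- suppressWarnings(fit_velocity(tr$mem_right_um, tr$time_s))
  expect_equal(v$velocity_um_min, 14, tolerance = 1e-6)
  expect_lt(v$slope_um_min, 0)   # contraction: negative slope

  # constant distance: zero slope
  v0 <- suppressWarnings(fit_velocity(rep(0.4, 20), seq_len(20)))
  expect_equal(v0$velocity_um_min, 0, tolerance = 1e-12)

  expect_error(fit_velocity(1:3, 1:3), ">= 5 frames")
  expect_error(fit_velocity(rep(1, 6), rep(2, 6)), "degenerate")
})

test_that("velocity recovery under noise stays within 2 SE over replicates", {
  true_rate <- 10
  times <- seq(0, 3, by = 0.05)
  r <- 0.9 - true_rate / 60 * times
  misses <- 0
  for (s in 1:50) {
    set.seed(s)
    v <- fit_velocity(r + rnorm(length(r), sd = 0.02), times)
    if (abs(v$velocity_um_min - true_rate) > 2 * v$se_um_min)
      misses <- misses + 1
  }
  expect_lte(misses, 6)   # ~5% expected outside 2 SE
})

test_that("membrane-actin distance recovers the geometric gap", {
  expect_equal(membrane_actin_distance(0.4, 0.4), 0)
  g <- make_geometry()
  csk <- static_csk(g, channels = c("membrane", "actin"))
  tr <- track_peaks(csk)
  gap <- membrane_actin_distance(tr$mem_right_um, tr$actin_right_um)
  expect_equal(mean(gap), 0.180, tolerance = 0.01 / 0.180)

  g2 <- make_geometry(list(gap_membrane_actin_um = 0.074))
  tr2 <- track_peaks(static_csk(g2, channels = c("membrane", "actin"),
                                psf = 0.03))
  gap2 <- membrane_actin_distance(tr2$mem_right_um, tr2$actin_right_um)
  expect_lt(mean(gap2), mean(gap))
  expect_equal(mean(gap2), 0.074, tolerance = 0.015 / 0.074)
  expect_error(membrane_actin_distance(1:3, 1:2), "equal length")
})

test_that("fluorescence-diameter fit and inverse prediction are consistent", {
  x <- seq(0, 2, by = 0.1)
  exact <- data.frame(normalized_diameter = x,
                      normalized_fluorescence = 2 * x + 1)
  m <- suppressWarnings(fit_fluorescence_diameter(exact))
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  three <- data.frame(normalized_diameter = c(0, 1, 2),
                      normalized_fluorescence = c(0, 1, 2))
  m3 <- suppressWarnings(fit_fluorescence_diameter(three))
  expect_equal(m3$slope, 1, tolerance = 1e-12)
  expect_equal(m3$intercept, 0, tolerance = 1e-12)

  # inverse prediction: f = b + m -> x_hat = 1; round trip is identity
  expect_equal(as.numeric(diameter_from_fluorescence(m$intercept + m$slope,
                                                     m)),
               1, tolerance = 1e-12)
  xh <- diameter_from_fluorescence(exact$normalized_fluorescence, m)
  expect_equal(as.numeric(xh), x, tolerance = 1e-12)
  expect_true(attr(xh, "approximate"))
  # monotone for positive slope
  expect_true(all(diff(as.numeric(
    diameter_from_fluorescence(seq(-5, 5, 0.5),
                               list(slope = 8.90, intercept = -8.05)))) > 0))

  expect_error(fit_fluorescence_diameter(exact[1:2, ]), ">= 3")
  expect_error(fit_fluorescence_diameter(
    data.frame(normalized_diameter = rep(1, 5),
               normalized_fluorescence = 1:5)), "zero variance")
  expect_error(diameter_from_fluorescence(1, list(slope = 0, intercept = 0)),
               "nonzero")
})
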