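# Helix geometry estimation from localization tables.

test_that("axis center fit is unbiased and shift-equivariant", {
  g <- make_geometry()
  locs <- simulate_localizations(g, 5000, 15, seed = 1)
  fit <- fit_axis_center(locs)
  # generator centers the helix on the x axis
  expect_lt(abs(fit$center["y_nm"]), 10)
  expect_lt(abs(fit$center["z_nm"]), 10)
  # translation equivariance
  t_vec <- c(100, -50, 30)
  locs2 <- locs
  locs2$x_nm <- locs2$x_nm + t_vec[1]
  locs2$y_nm <- locs2$y_nm + t_vec[2]
  locs2$z_nm <- locs2$z_nm + t_vec[3]
  fit2 <- fit_axis_center(locs2)
  expect_equal(unname(fit2$center - fit$center), t_vec, tolerance = 1e-6)
})

test_that("transverse center recovery stays within a few nm over seeds", {
  g <- make_geometry()
  errs <- vapply(1:10, function(s) {
    locs <- simulate_localizations(g, 5000, 15, seed = s)
    locs$y_nm <- locs$y_nm + 100
    locs$z_nm <- locs$z_nm - 50
    fit <- fit_axis_center(locs)
    max(abs(unname(fit$center[c("y_nm", "z_nm")]) - c(100, -50)))
  }, numeric(1))
  expect_lt(max(errs), 15)
})

test_that("curved ROIs are rejected by the straightness check", {
  g <- make_geometry()
  locs <- simulate_localizations(g, 5000, 15, seed = 2)
  locs$y_nm <- locs$y_nm + 1e-5 * (locs$x_nm - mean(locs$x_nm))^2  # bend
  expect_error(fit_axis_center(locs), "not straight")
})

test_that("cylindrical transform is exact and invertible", {
  fit <- list(transverse = matrix(c(3, 4), 1), s_nm = 0)
  cyl <- to_cylindrical(data.frame(), fit)
  expect_equal(cyl$r_nm, 5)

  g <- make_geometry()
  locs <- simulate_localizations(g, 2000, precision_nm = 0, seed = 3)
  # with the exact axis, all points sit on the cylinder surface
  exact <- list(transverse = cbind(locs$y_nm, locs$z_nm), s_nm = locs$x_nm)
  cyl0 <- to_cylindrical(locs, exact)
  expect_equal(cyl0$r_nm, rep(300, nrow(locs)), tolerance = 1e-12)

  fit <- fit_axis_center(locs)
  cyl <- to_cylindrical(locs, fit)
  expect_equal(nrow(cyl), nrow(locs))
  expect_true(all(cyl$r_nm >= 0))
  expect_true(all(cyl$theta_rad > -pi & cyl$theta_rad <= pi))
  # estimated axis: on the surface to within a few nm of center error
  expect_lt(max(abs(cyl$r_nm - 300)), 10)
  # inverse transform reproduces the transverse coordinates
  back <- cbind(cyl$r_nm * cos(cyl$theta_rad), cyl$r_nm * sin(cyl$theta_rad))
  expect_equal(back, unname(fit$transverse), tolerance = 1e-9)
})

test_that("radial distribution peak is the refined histogram argmax", {
  rd <- radial_distribution(rep(300, 500), bin_nm = 10)
  expect_equal(rd$R_nm, 300)   # point mass reports its own value
  expect_error(radial_distribution(rep(300, 50)), ">= 100")

  g <- make_geometry()
  errs <- vapply(1:10, function(s) {
    locs <- simulate_localizations(g, 20000, 15, seed = s)
    cyl <- to_cylindrical(locs)
    radial_distribution(cyl$r_nm)$R_nm - 300
  }, numeric(1))
  expect_lt(max(abs(errs)), 10)
})

test_that("reacted-geometry radius is smaller than intact", {
  intact <- analyze_helix(simulate_localizations(
    make_geometry(), 20000, 15, seed = 4))
  reacted <- analyze_helix(simulate_localizations(
    make_geometry(list(helix_pitch_nm = 159, helix_radius_nm = 252)),
    20000, 15, seed = 4))
  expect_lt(reacted$R_nm, intact$R_nm)
  expect_lt(reacted$pitch_nm, intact$pitch_nm)
})

test_that("pitch frequency matches closed-form and the autocorrelation oracle", {
  # noise-free single-strand signal with period 250 nm
  set.seed(5)
  s <- sort(runif(5000, 0, 10))     # um
  theta <- ((2 * pi * s / 0.25 + pi) %% (2 * pi)) - pi
  pf <- pitch_frequency(data.frame(theta_rad = theta, s_um = s),
                        n_strands = 1)
  expect_equal(pf$f0_um, 4.0, tolerance = 1e-4)
  expect_equal(pf$pitch_nm, 250, tolerance = 1e-2)

  # dual-estimator oracle on a noise-free strand: acf period of binned y(s)
  g <- make_geometry(list(helix_pitch_nm = 400))
  locs <- simulate_localizations(g, 30000, precision_nm = 0, seed = 6)
  strand <- attr(locs, "truth")$strand
  s0 <- locs$x_nm[strand == 0]; y0 <- locs$y_nm[strand == 0]
  bin <- 10
  grid <- seq(0, max(s0), by = bin)
  sig <- tapply(y0, cut(s0, grid), mean)
  sig <- sig[is.finite(sig)]
  a <- stats::acf(sig, lag.max = length(sig) - 1, plot = FALSE)$acf[, 1, 1]
  lags <- 2:(length(a) - 1)
  peaks <- lags[a[lags] > a[lags - 1] & a[lags] >= a[lags + 1] &
                  a[lags] > 0.5]
  acf_pitch_nm <- (peaks[1] - 1) * bin
  fft_pitch_nm <- pitch_frequency(locs)$pitch_nm
  expect_equal(fft_pitch_nm, acf_pitch_nm, tolerance = 0.02)

  # white-phase noise: no dominant peak
  set.seed(7)
  junk <- data.frame(theta_rad = runif(2000, -pi, pi),
                     s_um = runif(2000, 0, 10))
  expect_error(pitch_frequency(junk, n_strands = 2), "no dominant")
})

test_that("gyre count is the rounded extent-frequency product", {
  expect_equal(count_gyres(21.2, 1000 / 244), 87)
  expect_equal(count_gyres(1, 1 / 0.5), 2)
  set.seed(8)
  for (i in 1:50) {
    L <- runif(1, 1, 30); l_um <- runif(1, 0.1, 0.5)
    expect_equal(count_gyres(L, 1 / l_um), round(L / l_um))
  }
  expect_error(count_gyres(10, 0), "> 0")
})

test_that("full helix analysis recovers intact and reacted parameters", {
  g <- make_geometry()
  hp <- analyze_helix(simulate_localizations(g, 50000, 15, seed = 9))
  expect_equal(hp$pitch_nm, 244, tolerance = 0.02)
  expect_equal(hp$gyres, 87)
  expect_equal(hp$axial_extent_um, 21.2, tolerance = 0.3 / 21.2)
  expect_equal(hp$R_nm, 300, tolerance = 10 / 300)
  # structural unit consistency
  expect_equal(hp$pitch_nm * hp$f0_um / 1000, 1, tolerance = 1e-12)

  gr <- make_geometry(list(helix_pitch_nm = 159, helix_radius_nm = 252,
                           length_um = 21))
  hpr <- analyze_helix(simulate_localizations(gr, 50000, 15, seed = 10))
  expect_equal(hpr$f0_um, 6.29, tolerance = 0.02)

  expect_error(analyze_helix(structure(
    data.frame(x_nm = numeric(0), y_nm = numeric(0)),
    class = c("localization_table", "data.frame"))), "empty")
})

test_that("estimators are invariant to rigid rotation and translation", {
  g <- make_geometry()
  locs <- simulate_localizations(g, 20000, 15, seed = 11)
  hp0 <- analyze_helix(locs)
  # rotate by arbitrary angles and translate
  ang <- c(0.4, -0.7, 1.1)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  m <- as.matrix(as.data.frame(locs)[, c("x_nm", "y_nm", "z_nm")]) %*%
    t(Rz %*% Rx)
  locs2 <- locs
  locs2$x_nm <- m[, 1] + 500
  locs2$y_nm <- m[, 2] - 200
  locs2$z_nm <- m[, 3] + 100
  hp1 <- analyze_helix(locs2)
  expect_equal(hp1$pitch_nm, hp0$pitch_nm, tolerance = 0.01)
  expect_equal(hp1$R_nm, hp0$R_nm, tolerance = 0.05)
  expect_equal(hp1$gyres, hp0$gyres)
})

test_that("2-D tables are analyzed with the projected-radius flag", {
  g <- make_geometry()
  locs <- simulate_localizations(g, 20000, 15, z_included = FALSE,
                                 seed = 12)
  expect_false("z_nm" %in% names(locs))
  hp <- analyze_helix(locs)
  expect_true(hp$projected)
  expect_equal(hp$pitch_nm, 244, tolerance = 0.02)
})
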