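# Actin double-helix geometry from single-molecule localization tables:
# axis fit, cylindrical transform, radial distribution, pitch frequency,
# gyre count.

#' Fit the flagellar axis from a localization table
#'
#' The axis direction is the first principal component of the coordinates
#' (least-squares line). The center of the cross-section is found, as in
#' the cylindrical-transform procedure, by Gaussian fits to the histograms
#' of the transverse coordinates (nonlinear least squares on 5 nm bins,
#' falling back to the coordinate mean when the fit does not converge). A
#' straightness check rejects curved ROIs: the RMS residual of a quadratic
#' trend of the transverse coordinate along the axis must not exceed
#' `curvature_tol_nm`.
#'
#' @param locs A `localization_table` (columns `x_nm`, `y_nm`, optionally
#'   `z_nm`).
#' @param curvature_tol_nm Straightness tolerance (nm).
#' @return List: `center` (named vector in the original coordinates),
#'   `axis` (unit vector), `transverse` (matrix of centered transverse
#'   coordinates, 1 or 2 columns), `s_nm` (axial coordinate per point).
#' @export
fit_axis_center <- function(locs, curvature_tol_nm = 150) {
  xyz <- loc_matrix(locs)
  if (nrow(xyz) < 10L) stopf("too few localizations to fit an axis")
  mu <- colMeans(xyz)
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  if (axis[1] < 0) axis <- -axis          # orient along +x for stability
  s <- as.numeric(scale(xyz, center = mu, scale = FALSE) %*% axis)
  trans <- pc$x[, -1, drop = FALSE]
  # straightness: quadratic bend of each transverse coordinate along s
  for (j in seq_len(ncol(trans))) {
    fit <- stats::lm(trans[, j] ~ s + I(s^2))
    bend <- stats::sd(stats::fitted(fit))
    if (is.finite(bend) && bend > curvature_tol_nm)
      stopf("ROI is not straight (transverse bend %.0f nm > %.0f nm)",
            bend, curvature_tol_nm)
  }
  # refine the transverse center by Gaussian histogram fits
  shift <- vapply(seq_len(ncol(trans)), function(j)
    gaussian_center(trans[, j]), numeric(1))
  center <- mu + as.numeric(pc$rotation[, -1, drop = FALSE] %*% shift)
  names(center) <- colnames(xyz)
  trans <- sweep(trans, 2, shift)
  list(center = center, axis = axis, transverse = trans, s_nm = s)
}

# Gaussian fit to a coordinate histogram; returns the fitted mean.
gaussian_center <- function(v, bin_nm = 5) {
  h <- graphics::hist(v, breaks = seq(min(v) - bin_nm, max(v) + bin_nm,
                                      by = bin_nm), plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
               start = list(a = max(df$y), m = mean(v), s = stats::sd(v)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(mean(v))
  m <- stats::coef(fit)[["m"]]
  if (!is.finite(m) || abs(m - mean(v)) > 3 * stats::sd(v)) mean(v) else m
}

loc_matrix <- function(locs) {
  need <- c("x_nm", "y_nm")
  if (!all(need %in% names(locs))) stopf("localization table needs x_nm, y_nm")
  cols <- c(need, if ("z_nm" %in% names(locs)) "z_nm")
  m <- as.matrix(as.data.frame(locs)[, cols])
  if (!all(is.finite(m))) stopf("localization coordinates must be finite")
  m
}

#' Transform localizations to cylindrical coordinates about a fitted axis
#'
#' @param locs A `localization_table`.
#' @param fit Result of [fit_axis_center()]; computed when omitted.
#' @return data.frame with `r_nm` (radial position, >= 0), `theta_rad`
#'   (azimuth in `(-pi, pi]`; for 2-D tables the sign of the single
#'   transverse coordinate, flagged `projected`), and `s_um` (axial
#'   arclength). Row count equals the input point count.
#' @export
to_cylindrical <- function(locs, fit = fit_axis_center(locs)) {
  trans <- fit$transverse
  if (ncol(trans) == 2L) {
    r <- sqrt(rowSums(trans^2))
    theta <- atan2(trans[, 2], trans[, 1])
    projected <- FALSE
  } else {
    r <- abs(trans[, 1])
    theta <- ifelse(trans[, 1] >= 0, 0, pi)
    projected <- TRUE
  }
  theta[theta <= -pi] <- theta[theta <= -pi] + 2 * pi
  out <- data.frame(r_nm = r, theta_rad = theta,
                    s_um = (fit$s_nm - min(fit$s_nm)) / 1000)
  attr(out, "projected") <- projected
  out
}

#' Radial distribution of localization radii and its peak R
#'
#' Histogram of radial positions in `bin_nm` bins (raw counts); the peak R
#' is the parabolically refined argmax. No 1/r density reweighting is
#' applied by default (set `jacobian = TRUE` for the density-corrected
#' variant).
#'
#' @param r_nm Radial positions (nm), >= 100 points.
#' @param bin_nm Bin width (nm).
#' @param jacobian Divide counts by bin radius before locating the peak.
#' @return List: `R_nm` (refined peak), `breaks_nm`, `counts`, `mids_nm`.
#' @export
radial_distribution <- function(r_nm, bin_nm = 10, jacobian = FALSE) {
  r_nm <- r_nm[is.finite(r_nm)]
  if (length(r_nm) < 100L) stopf("need >= 100 localizations")
  # bin centers on multiples of bin_nm, so a point mass reports its value
  breaks <- seq(-bin_nm / 2, max(r_nm) + bin_nm, by = bin_nm)
  h <- graphics::hist(r_nm, breaks = breaks, plot = FALSE)
  y <- if (jacobian) h$counts / pmax(h$mids, bin_nm / 2) else h$counts
  i <- which.max(y)
  R <- stats::approx(seq_along(h$mids), h$mids,
                     xout = refine_peak(y, i))$y
  list(R_nm = R, breaks_nm = breaks, counts = h$counts, mids_nm = h$mids)
}

#' Helical pitch frequency f0 from the azimuthal strand signal
#'
#' For an `n_strands`-start helix, each strand satisfies
#' `theta = 2*pi*f0*s + phase_k` with the strand phases equally spaced by
#' `2*pi/n_strands`, so `n*theta - 2*pi*(n*f0)*s` is constant (mod 2*pi)
#' across all strands regardless of strand identity. The estimator therefore
#' maximizes the phase-coherence periodogram
#' `|sum_j exp(i*n*theta_j - i*2*pi*nu*s_j)|^2` over frequency `nu`; the
#' per-strand fundamental is `f0 = nu_hat / n`. The grid search (resolution
#' ~0.4/extent) is followed by golden-section refinement, so f0 is not
#' quantized to the grid. This extracts the strand fundamental directly and
#' does not report the n-th harmonic of the total projected density.
#'
#' @param cyl Cylindrical coordinates from [to_cylindrical()] (needs
#'   `theta_rad`, `s_um`), or a `localization_table` (transformed
#'   internally).
#' @param n_strands Number of helix strands (default 2).
#' @param f0_range_um Physiological search band for f0 (turns per um).
#' @param min_coherence Minimum squared coherence (peak power normalized by
#'   n_points^2) below which no dominant peak is declared.
#' @return List: `f0_um` (turns per um), `pitch_nm` (= 1000/f0),
#'   `coherence` (in `[0, 1]`). Errors when no dominant peak exists.
#' @export
pitch_frequency <- function(cyl, n_strands = 2L,
                            f0_range_um = c(1, 10),
                            min_coherence = 0.05) {
  if (inherits(cyl, "localization_table")) cyl <- to_cylindrical(cyl)
  stopifnot(all(c("theta_rad", "s_um") %in% names(cyl)))
  s <- cyl$s_um
  extent <- diff(range(s))
  if (isTRUE(attr(cyl, "projected"))) {
    # 2-D table: the azimuth collapses to a sign, so use the signed
    # transverse coordinate; its n-th power oscillates at n*f0 for an
    # n-start helix (e.g. u^2 ~ cos(4*pi*s/l) for a two-start helix)
    u <- cyl$r_nm * cos(cyl$theta_rad)
    w <- (u / stats::sd(u))^n_strands
    w <- w - mean(w)
  } else {
    w <- exp(1i * n_strands * cyl$theta_rad)
  }
  # handedness of the fitted transverse basis is arbitrary (PCA sign),
  # so test both chiralities and keep the stronger one
  power <- function(nu) {
    e <- exp(-2i * pi * nu * s)
    max(Mod(sum(w * e)), Mod(sum(Conj(w) * e)))^2 / length(s)^2
  }
  # search over nu = n_strands * f0
  nu_lo <- n_strands * f0_range_um[1]
  nu_hi <- n_strands * f0_range_um[2]
  grid <- seq(nu_lo, nu_hi, by = 0.4 / max(extent, 1))
  pw <- vapply(grid, power, numeric(1))
  i <- which.max(pw)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(power, c(lo, hi), maximum = TRUE, tol = 1e-7)
  coh <- opt$objective
  if (coh < min_coherence)
    stopf("no dominant pitch-frequency peak (coherence %.3f)", coh)
  f0 <- opt$maximum / n_strands
  list(f0_um = f0, pitch_nm = 1000 / f0, coherence = coh)
}

#' Number of gyres over an axial extent
#'
#' @param length_um Axial extent (um).
#' @param f0_um Pitch frequency (turns per um, > 0).
#' @return Integer `round(length_um * f0_um)`.
#' @export
count_gyres <- function(length_um, f0_um) {
  if (f0_um <= 0) stopf("f0 must be > 0")
  as.integer(round(length_um * f0_um))
}

#' Full helix-geometry analysis of a localization table
#'
#' Composition of [fit_axis_center()], [to_cylindrical()],
#' [radial_distribution()], [pitch_frequency()], and [count_gyres()].
#'
#' @param locs A `localization_table`.
#' @param n_strands Number of helix strands.
#' @param bin_nm Radial histogram bin (nm).
#' @param extent_trim Fraction of extreme axial coordinates trimmed on each
#'   end before measuring the axial extent (robustness to stray points;
#'   0 = raw range).
#' @param ... Passed to [pitch_frequency()].
#' @return Object of class `helix_params`: `f0_um`, `pitch_nm`
#'   (`pitch_nm * f0_um / 1000 = 1` by construction), `R_nm`, `gyres`,
#'   `axial_extent_um`, `n_points`, `projected`.
#' @export
analyze_helix <- function(locs, n_strands = 2L, bin_nm = 10,
                          extent_trim = 0, ...) {
  if (nrow(locs) == 0L) stopf("empty localization table")
  fit <- fit_axis_center(locs)
  cyl <- to_cylindrical(locs, fit)
  extent <- if (extent_trim > 0) {
    q <- stats::quantile(cyl$s_um, c(extent_trim, 1 - extent_trim))
    diff(q) / (1 - 2 * extent_trim)
  } else diff(range(cyl$s_um))
  pf <- pitch_frequency(cyl, n_strands = n_strands, ...)
  if (extent < 5 * pf$pitch_nm / 1000)
    stopf("axial extent (%.2f um) spans fewer than 5 pitches", extent)
  rd <- radial_distribution(cyl$r_nm, bin_nm = bin_nm)
  structure(list(f0_um = pf$f0_um, pitch_nm = pf$pitch_nm,
                 R_nm = rd$R_nm,
                 gyres = count_gyres(extent, pf$f0_um),
                 axial_extent_um = extent,
                 coherence = pf$coherence,
                 n_points = nrow(locs),
                 projected = isTRUE(attr(cyl, "projected"))),
            class = "helix_params")
}

#' @export
print.helix_params <- function(x, ...) {
  cat(sprintf("<helix_params> pitch %.1f nm (f0 %.3f /um), R %.1f nm, %d gyres over %.2f um\n",
              x$pitch_nm, x$f0_um, x$R_nm, x$gyres, x$axial_extent_um))
  if (x$projected) cat("  (2-D table: radial coordinate is projected)\n")
  invisible(x)
}
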