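#' Parametric ground-truth model of the sperm midpiece
#'
#' `make_geometry()` builds the parametric model from which every synthetic
#' render derives: a tube of baseline radius `membrane_radius_um` running
#' along arclength `[0, length_um]`, wrapped by an `n_strands`-start actin
#' helix of axial pitch `helix_pitch_nm` and radius `helix_radius_nm`, and a
#' contraction program in which the tube diameter falls by fraction
#' `contraction_amplitude` following a logistic time course whose onset is
#' delayed with distance from the nearest initiation focus.
#'
#' Defaults describe the acrosome-intact mouse midpiece: 21.2 um long,
#' 0.731 um outer diameter, an actin double helix of 244 nm pitch and 300 nm
#' radius (87 gyres over the midpiece), and a 0.180 um gap between the
#' membrane and the actin peak. The acrosome-reacted state is obtained by
#' overriding `helix_pitch_nm = 159`, `helix_radius_nm = 252` (and optionally
#' a nonzero `contraction_amplitude`).
#'
#' @param overrides Named list of fields to override. Unknown names are an
#'   error. Fields:
#' \describe{
#'   \item{length_um}{arclength extent of the midpiece (um).}
#'   \item{membrane_radius_um}{baseline tube radius (um).}
#'   \item{contraction_amplitude}{fractional diameter decrease at plateau,
#'     in `[0, 1)`; 0 gives a static tube.}
#'   \item{foci}{data.frame with columns `position_um`, `onset_s`,
#'     `spread_um` — contraction initiation sites.}
#'   \item{onset_rate_s}{logistic steepness (1/s) of the contraction time
#'     course at a fixed position.}
#'   \item{propagation_um_s}{speed (um/s) at which contraction onset
#'     propagates away from the nearest focus.}
#'   \item{helix_pitch_nm, helix_radius_nm, n_strands}{actin helix axial
#'     period per strand (nm), strand radius (nm), number of strands.}
#'   \item{gap_membrane_actin_um}{membrane-to-actin peak distance (um).}
#'   \item{ca_onset_s, fm_onset_s}{event times of the calcium transient and
#'     the membrane-dye rise; `ca_onset_s < fm_onset_s` is enforced.}
#' }
#' @return An object of class `midpiece_geometry` (a validated named list).
#' @examples
#' g <- make_geometry()
#' g$length_um                     # 21.2
#' gr <- make_geometry(list(helix_pitch_nm = 159, helix_radius_nm = 252))
#' @export
make_geometry <- function(overrides = list()) {
  geom <- list(
    length_um = 21.2,
    membrane_radius_um = 0.731 / 2,
    contraction_amplitude = 0,
    foci = data.frame(position_um = 3, onset_s = 60, spread_um = 1),
    onset_rate_s = 0.25,
    propagation_um_s = 0.2,
    helix_pitch_nm = 244,
    helix_radius_nm = 300,
    n_strands = 2L,
    gap_membrane_actin_um = 0.180,
    ca_onset_s = 45,
    fm_onset_s = 60
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stopf("geometry overrides must be a named list")
    unknown <- setdiff(names(overrides), names(geom))
    if (length(unknown))
      stopf("unknown geometry field(s): %s", paste(unknown, collapse = ", "))
    geom[names(overrides)] <- overrides
  }
  validate_geometry(geom)
}

validate_geometry <- function(geom) {
  if (!is.numeric(geom$length_um) || geom$length_um <= 0)
    stopf("length_um must be > 0")
  if (geom$membrane_radius_um <= 0)
    stopf("membrane_radius_um must be > 0")
  if (geom$contraction_amplitude < 0 || geom$contraction_amplitude >= 1)
    stopf("contraction_amplitude must be in [0, 1)")
  foci <- geom$foci
  if (!is.data.frame(foci) ||
      !all(c("position_um", "onset_s", "spread_um") %in% names(foci)))
    stopf("foci must be a data.frame with position_um, onset_s, spread_um")
  if (nrow(foci) && (any(foci$position_um < 0) ||
                     any(foci$position_um > geom$length_um)))
    stopf("focus positions must lie in [0, length_um]")
  if (geom$helix_pitch_nm <= 0) stopf("helix_pitch_nm must be > 0")
  if (geom$helix_radius_nm <= 0) stopf("helix_radius_nm must be > 0")
  if (geom$n_strands < 1) stopf("n_strands must be >= 1")
  if (geom$ca_onset_s >= geom$fm_onset_s)
    stopf("ca_onset_s must precede fm_onset_s")
  structure(geom, class = "midpiece_geometry")
}

#' @export
print.midpiece_geometry <- function(x, ...) {
  cat("<midpiece_geometry>\n")
  cat(sprintf("  length %.1f um, radius %.3f um, contraction amplitude %.2f\n",
              x$length_um, x$membrane_radius_um, x$contraction_amplitude))
  cat(sprintf("  helix: %d strand(s), pitch %.0f nm, radius %.0f nm (%d gyres)\n",
              x$n_strands, x$helix_pitch_nm, x$helix_radius_nm,
              round(1000 * x$length_um / x$helix_pitch_nm)))
  cat(sprintf("  %d contraction focus/foci; Ca onset %.0f s, FM onset %.0f s\n",
              nrow(x$foci), x$ca_onset_s, x$fm_onset_s))
  invisible(x)
}

#' Ground-truth tube radius over arclength and time
#'
#' Evaluates the contraction program of a [make_geometry()] model: at
#' position `s` the normalized diameter follows a falling logistic
#' `1 - a / (1 + exp(-k (t - t_on(s))))` where `t_on(s)` is the focus onset
#' plus the propagation delay `dist_to_nearest_focus / propagation_um_s`.
#' With no foci or zero amplitude the tube is static.
#'
#' @param geom A `midpiece_geometry`.
#' @param positions_um Numeric vector of arclength positions (um).
#' @param times_s Numeric vector of times (s).
#' @return List with matrices `radius_um` and `normalized_diameter`
#'   (positions x times), plus `onset_s` — the per-position time at which the
#'   noise-free normalized diameter first falls below 1 minus half the
#'   amplitude (the logistic midpoint), NA when static.
#' @export
true_radius <- function(geom, positions_um, times_s) {
  stopifnot(inherits(geom, "midpiece_geometry"))
  if (any(positions_um < 0 | positions_um > geom$length_um))
    stopf("positions outside [0, %.2f]", geom$length_um)
  a <- geom$contraction_amplitude
  n_p <- length(positions_um); n_t <- length(times_s)
  if (a == 0 || nrow(geom$foci) == 0L) {
    nd <- matrix(1, n_p, n_t)
    onset <- rep(NA_real_, n_p)
  } else {
    dist <- vapply(positions_um, function(p)
      min(abs(p - geom$foci$position_um)), numeric(1))
    nearest <- vapply(positions_um, function(p)
      which.min(abs(p - geom$foci$position_um)), integer(1))
    t_on <- geom$foci$onset_s[nearest] + dist / geom$propagation_um_s
    nd <- 1 - a / (1 + exp(-geom$onset_rate_s *
                             outer(-t_on, times_s, `+`)))
    onset <- t_on
  }
  list(radius_um = geom$membrane_radius_um * nd,
       normalized_diameter = nd,
       onset_s = onset)
}
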