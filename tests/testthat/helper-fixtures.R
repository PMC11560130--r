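# Shared fixtures, built in code at test time.

# Symmetric two-peak (membrane-like) radial profile on a uniform grid.
two_peak_profile <- function(sep_um, sigma_um = 0.05, step_um = 0.02,
                             halfwidth_um = 1, background = 0,
                             amplitude = 1) {
  offsets <- seq(-halfwidth_um, halfwidth_um, by = step_um)
  y <- amplitude * (exp(-(offsets - sep_um / 2)^2 / (2 * sigma_um^2)) +
                    exp(-(offsets + sep_um / 2)^2 / (2 * sigma_um^2))) +
    background
  list(offsets = offsets, y = y, step = step_um)
}

# Direct argmax-pair oracle for the peak separation of a symmetric profile.
# Peak positions are refined with a three-point parabola so the oracle is
# not quantized to the sampling grid.
argmax_pair_separation <- function(y, step_um) {
  n <- length(y)
  mid <- ceiling(n / 2)
  refine <- function(i) {
    if (i <= 1 || i >= n) return(i)
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom >= 0) return(i)
    i + 0.5 * (y[i - 1] - y[i + 1]) / denom
  }
  li <- refine(which.max(y[1:(mid - 1)]))
  ri <- refine(mid + which.max(y[(mid + 1):n]))
  (ri - li) * step_um
}

# Single-position static cross-section kymograph for one or two channels.
static_csk <- function(geom, channels = "membrane", psf = 0.05,
                       n_frames = 10) {
  render_cross_profiles(geom, psf_sigma_um = psf, positions_um = 5,
                        times_s = seq(0, n_frames - 1), noise_sd = 0,
                        channels = channels)
}
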