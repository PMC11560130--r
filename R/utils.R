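# Internal numerical helpers shared across modules.

#' Run code with a fixed RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Parabolic (three-point) refinement of a discrete argmax
#'
#' Fits a parabola through (i-1, i, i+1) around the discrete maximum and
#' returns the fractional index of its vertex. At either edge the discrete
#' index is returned unchanged. If `log_scale` the fit is done on log(y),
#' which is exact for Gaussian-shaped peaks (a Gaussian is a parabola in
#' log-intensity); falls back to the linear fit when a neighbour is not
#' strictly positive.
#' @noRd
refine_peak <- function(y, i, log_scale = FALSE) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  y3 <- y[(i - 1L):(i + 1L)]
  if (log_scale && all(y3 > 0)) y3 <- log(y3)
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (!is.finite(denom) || denom >= 0) return(as.numeric(i))
  delta <- 0.5 * (y3[1] - y3[3]) / denom
  as.numeric(i) + max(-0.5, min(0.5, delta))
}

#' Discrete 1-D Gaussian smoothing with reflected boundaries
#' @noRd
gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  # reflect-pad so edges are not dimmed
  yp <- c(y[pmin(n, (half + 1L):2L)], y, y[pmax(1L, (n - 1L):(n - half))])
  as.numeric(stats::filter(yp, k, sides = 2))[(half + 1L):(half + n)]
}

#' Otsu threshold on a 256-bin histogram
#'
#' Maximizes between-class variance over bin boundaries; returns a threshold
#' on the intensity scale of `x`.
#' @noRd
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # well-separated modes give a plateau of optimal cuts; take its midpoint
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-9))
  mean(mids[best])
}

#' Bilinear interpolation of a 2-D image at arbitrary (row, col) positions
#'
#' Positions are in fractional pixel units (1-based, matching R indexing).
#' Points outside the image return NA.
#' @noRd
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # clamp exact upper edge into the last cell
  at_r_edge <- row == nr & c0 >= 1 & c0 + 1 <= nc
  at_c_edge <- col == nc & r0 >= 1 & r0 + 1 <= nr
  out <- rep(NA_real_, length(row))
  idx <- which(ok | (at_r_edge & at_c_edge) | at_r_edge | at_c_edge)
  if (length(idx)) {
    r0i <- pmin(r0[idx], nr - 1L); c0i <- pmin(c0[idx], nc - 1L)
    fri <- row[idx] - r0i; fci <- col[idx] - c0i
    out[idx] <- img[cbind(r0i, c0i)] * (1 - fri) * (1 - fci) +
      img[cbind(r0i + 1L, c0i)] * fri * (1 - fci) +
      img[cbind(r0i, c0i + 1L)] * (1 - fri) * fci +
      img[cbind(r0i + 1L, c0i + 1L)] * fri * fci
  }
  out
}

#' First index where a logical run of length >= persistence starts, or NA
#' @noRd
first_sustained <- function(flag, persistence) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
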