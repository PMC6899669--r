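#' Spatial Ram-Lak kernel
#'
#' The band-limited spatial-domain ramp kernel for detector spacing `tau`
#' (mm), following the classical closed form: `h(0) = 1/(4 tau^2)`,
#' `h(k) = -1/(k^2 pi^2 tau^2)` for odd `k`, and `h(k) = 0` for even
#' `k != 0`.
#'
#' @param n total number of taps, odd; taps run over lags `-m..m` with
#'   `m = (n-1)/2`.
#' @param tau detector spacing in mm (> 0).
#' @return numeric vector of length `n`, named by lag.
#' @examples
#' ramlak_kernel(5, 1)  # -1/pi^2, 0, 1/4, 0, -1/pi^2
#' @export
ramlak_kernel <- function(n, tau = 1) {
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("n must be a positive odd tap count")
  if (tau <= 0) stop("tau must be > 0")
  m <- (n - 1L) %/% 2L
  k <- seq(-m, m)
  h <- ifelse(k == 0, 1 / (4 * tau^2),
              ifelse(k %% 2L == 0L, 0, -1 / (k^2 * pi^2 * tau^2)))
  names(h) <- k
  h
}

#' Frequency-domain ramp filter
#'
#' The ideal ramp `|omega|` sampled on the non-negative DFT frequencies of
#' a length-`n_pad` transform, in cycles/mm: weight `k` is
#' `k / (n_pad * tau)`, so DC is zero and the Nyquist weight is
#' `1/(2 tau)`.  With this scaling, filtered backprojection of a parallel
#' sinogram (with the angular increment applied in the back projection)
#' reconstructs absolute attenuation values.
#'
#' @param n_pad padded row length (>= 2); weights cover frequencies
#'   `0..n_pad/2` (half spectrum).
#' @param tau detector spacing in mm.
#' @return object of class `frequency_filter` with fields `weights`
#'   (length `floor(n_pad/2) + 1`), `pad_length`, `detector_spacing`.
#' @export
ramp_frequency_filter <- function(n_pad, tau = 1) {
  n_pad <- as.integer(n_pad)
  if (n_pad < 2L) stop("n_pad must be >= 2")
  if (tau <= 0) stop("tau must be > 0")
  frequency_filter(seq(0, n_pad %/% 2) / (n_pad * tau), n_pad, tau)
}

#' Frequency filter container
#'
#' Half-spectrum diagonal Fourier weights `K` applied per detector row;
#' the negative frequencies are implied by conjugate symmetry (the filter
#' is real and even).
#'
#' @param weights non-negative per-frequency coefficients, DC first,
#'   length `floor(pad_length/2) + 1`.
#' @param pad_length padded row length the weights refer to.
#' @param detector_spacing mm.
#' @return object of class `frequency_filter`.
#' @export
frequency_filter <- function(weights, pad_length, detector_spacing = 1) {
  pad_length <- as.integer(pad_length)
  weights <- as.numeric(weights)
  if (length(weights) != pad_length %/% 2L + 1L)
    stop("need floor(pad_length/2) + 1 half-spectrum weights")
  structure(list(weights = weights, pad_length = pad_length,
                 detector_spacing = as.numeric(detector_spacing)),
            class = "frequency_filter")
}

# mirror a half spectrum onto the full DFT length
full_spectrum <- function(filt) {
  n <- filt$pad_length
  w <- numeric(n)
  half <- filt$weights
  w[seq_along(half)] <- half
  if (n > 2L) w[n:(n %/% 2L + 2L)] <- half[2:((n + 1L) %/% 2L)]
  w
}

#' Smallest power of two >= x
#' @param x positive number.
#' @return integer power of two.
#' @export
next_pow2 <- function(x) as.integer(2^ceiling(log2(max(1, x))))

#' Default padded length for row filtering
#' @param n detector row length.
#' @return next power of two >= `2 * n`.
#' @export
default_pad_length <- function(n) next_pow2(2 * n)

# filter a set of rows (rows along columns of `m`: n_det x n_rows) in the
# Fourier domain with zero padding; returns same shape
filter_rows <- function(m, filt) {
  nd <- nrow(m)
  n <- filt$pad_length
  if (n < nd) stop("filter pad_length shorter than detector row")
  padded <- matrix(0, n, ncol(m))
  padded[seq_len(nd), ] <- m
  w <- full_spectrum(filt)
  out <- Re(stats::mvfft(stats::mvfft(padded) * w, inverse = TRUE)) / n
  out[seq_len(nd), , drop = FALSE]
}

#' Fourier-domain filtering of projections
#'
#' Zero-pads each detector row to the filter's `pad_length`, transforms,
#' multiplies by the diagonal weights, inverse-transforms and crops, i.e.
#' applies `F^H K F` row-wise.  For cone stacks the rows run along the
#' detector `u` axis of every (view, v) pair.
#'
#' @param stack a [projection_stack()].
#' @param filt a [frequency_filter()]; default: ramp at the stack's
#'   detector spacing and the default padding.
#' @return a filtered [projection_stack()].
#' @export
filter_projections <- function(stack, filt = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  geom <- stack$geometry
  nd <- geom$detector$shape[1]
  if (is.null(filt))
    filt <- ramp_frequency_filter(default_pad_length(nd),
                                  geom$detector$spacing[1])
  vals <- stack$values
  if (geom$beam == "cone3d") {
    # rows along u: permute to (u, views*v)
    m <- matrix(aperm(vals, c(2, 1, 3)), nrow = nd)
    f <- filter_rows(m, filt)
    out <- aperm(array(f, dim = dim(vals)[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    out <- t(filter_rows(t(vals), filt))
  }
  projection_stack(out, geom)
}

#' Cosine (geometric) pre-weights
#'
#' Per-(view, pixel) multiplicative weights compensating divergent-beam
#' obliquity before ramp filtering.  Fan beam: `cos(gamma) =
#' SID / sqrt(SID^2 + s_iso^2)` with `s_iso = s * SID/SDD` the detector
#' coordinate rescaled to the isocenter plane.  Cone beam:
#' `SDD / sqrt(SDD^2 + u^2 + v^2)` with `(u, v)` the physical detector
#' offsets from the principal point.
#'
#' @param geom a fan/cone [scan_geometry()].
#' @return weight array shaped like the projection stack values.
#' @export
cosine_weights <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (geom$beam == "parallel2d")
    stop("cosine weights undefined for the parallel beam")
  if (geom$beam == "fan2d") {
    s_iso <- detector_coords(geom$detector) * geom$sid / geom$sdd
    w <- geom$sid / sqrt(geom$sid^2 + s_iso^2)
    matrix(rep(w, each = geom$n_views), geom$n_views)
  } else {
    u <- detector_coords(geom$detector, 1)
    v <- detector_coords(geom$detector, 2)
    w <- geom$sdd / sqrt(geom$sdd^2 + outer(u^2, v^2, `+`))
    array(rep(w, each = geom$n_views),
          c(geom$n_views, geom$detector$shape))
  }
}

#' Continuous Parker weight function
#'
#' The smooth short-scan redundancy weight as a function of rotation `b`
#' since the first view and per-pixel fan angle `gamma` (see
#' [parker_weights()] for the convention and formulas).  Exposed so that
#' the pair-sum identity `w(b, gamma) + w(b + pi - 2*gamma, -gamma) = 1`
#' can be evaluated at arbitrary (off-grid) conjugate coordinates.
#'
#' @param beta rotation since the first view, radians (vectorized).
#' @param gamma per-pixel fan angle, radians (vectorized).
#' @param gamma_max half fan angle, radians.
#' @return weights in `[0, 1]`, recycled to the common length.
#' @export
parker_weight <- function(beta, gamma, gamma_max) {
  n <- max(length(beta), length(gamma))
  beta <- rep_len(beta, n); gamma <- rep_len(gamma, n)
  w <- rep(1, n)
  win <- gamma_max + gamma              # entering wedge width / 2
  wout <- gamma_max - gamma             # exiting wedge width / 2
  ent <- beta <= 2 * win
  w[ent] <- ifelse(win[ent] > 1e-12,
                   sin(pi / 4 * beta[ent] / win[ent])^2, 0)
  ext <- beta >= pi + 2 * gamma
  w[ext] <- ifelse(wout[ext] > 1e-12,
                   sin(pi / 4 * (pi + 2 * gamma_max - beta[ext]) / wout[ext])^2,
                   0)
  pmin(pmax(w, 0), 1)
}

#' Parker short-scan redundancy weights
#'
#' Smooth `sin^2` weights that make a short scan over `pi + 2*gamma_max`
#' equivalent to a full scan by giving every doubly-measured ray pair unit
#' total weight.  With this package's frame (detector coordinate `s`
#' increasing along `u = (cos b, sin b)`, per-pixel fan angle
#' `gamma = atan(s / SDD)`), the ray `(b, gamma)` is re-measured at
#' `(b + pi - 2*gamma, -gamma)`, and the weights are
#' \deqn{w = \sin^2\left(\frac{\pi}{4}\frac{b}{\gamma_m + \gamma}\right)}
#' on the entering wedge `0 <= b <= 2(gamma_m + gamma)`,
#' \deqn{w = \sin^2\left(\frac{\pi}{4}\frac{\pi + 2\gamma_m - b}{\gamma_m - \gamma}\right)}
#' on the exiting wedge `pi + 2*gamma <= b <= pi + 2*gamma_m`, and 1 in
#' between, where `b` is the rotation since the first view and `gamma_m`
#' the half fan angle.  Weights are clamped to `[0, 1]`.
#'
#' @param geom a fan/cone [scan_geometry()] whose `angular_range` equals
#'   `pi + 2*gamma_max` to within `1e-6` (only the short scan is
#'   supported).
#' @return weight array shaped like the projection stack values (constant
#'   along the cone `v` axis).
#' @export
parker_weights <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (geom$beam == "parallel2d")
    stop("Parker weights undefined for the parallel beam")
  gm <- half_fan_angle(geom)
  if (abs(geom$angular_range - (pi + 2 * gm)) > 1e-6)
    stop("Parker weights require a short scan: angular_range = pi + 2*gamma_max")
  b <- geom$angles - geom$start_angle
  gamma <- atan(detector_coords(geom$detector, 1) / geom$sdd)
  w <- outer(b, gamma, parker_weight, gamma_max = gm)
  if (geom$beam == "cone3d") {
    array(rep(w, times = geom$detector$shape[2]),
          c(geom$n_views, geom$detector$shape))
  } else w
}
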