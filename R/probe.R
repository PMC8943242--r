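#' Reflectance probe geometry
#'
#' The handheld dual-mode probe layout: eight sources in two rows of four at
#' y = +/-17.5 mm with 12 mm in-row spacing, eight detectors in two rows of
#' four at y = +/-10.8 mm, all optodes on the z = 0 surface, the pattern
#' centered on the origin, and the ultrasound imaging plane at y = 0.
#'
#' @param source_width Gaussian source profile width (sigma), mm
#' @param detector_width Gaussian detector profile width (sigma), mm
#' @return a `probe_geometry`: list with `sources` and `detectors` (8 x 3
#'   matrices, mm), profile widths, and `us_plane = 0`
#' @export
probe_geometry <- function(source_width = 0.5, detector_width = 1) {
  xs <- c(-18, -6, 6, 18)
  sources <- cbind(x = rep(xs, 2), y = rep(c(-17.5, 17.5), each = 4), z = 0)
  detectors <- cbind(x = rep(xs, 2), y = rep(c(-10.8, 10.8), each = 4), z = 0)
  structure(list(sources = sources, detectors = detectors,
                 source_width = source_width, detector_width = detector_width,
                 us_plane = 0),
            class = "probe_geometry")
}

#' Source-detector distance matrix
#' @param geometry a [probe_geometry()]
#' @return 8 x 8 matrix of Euclidean optode separations, mm
#' @export
sd_distances <- function(geometry) {
  s <- geometry$sources; d <- geometry$detectors
  outer(seq_len(nrow(s)), seq_len(nrow(d)), Vectorize(function(i, j)
    sqrt(sum((s[i, ] - d[j, ])^2))))
}

#' Time grid for the implicit-Euler stepper
#' @param dt time step, ps (default 25)
#' @param n_steps number of steps (default 400)
#' @param t0 origin, ps
#' @return a `time_grid` list; `$times` holds the sample times
#'   `t0 + dt * (1:n_steps)`
#' @export
time_grid <- function(dt = 25, n_steps = 400L, t0 = 0) {
  stopifnot(dt > 0, n_steps >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps), t0 = t0,
                 times = t0 + dt * seq_len(n_steps)),
            class = "time_grid")
}

#' Instrument response functions
#'
#' `gaussian_irf` builds the bundled synthetic IRF: a unit-area Gaussian of
#' given full width at half maximum centered at `t_center`, sampled on the
#' measurement time grid. `read_irf` reads a measured IRF from two-column
#' ASCII (time ps, amplitude) and resamples/normalizes it to the grid.
#'
#' @param timegrid a [time_grid()]
#' @param fwhm full width at half maximum, ps (default 400)
#' @param t_center center of the pulse, ps
#' @return an `irf`: list with `times` (ps) and `amplitude` (unit area with
#'   respect to the trapezoidal rule on its grid)
#' @export
gaussian_irf <- function(timegrid, fwhm = 400, t_center = 500) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tt <- c(0, timegrid$times)
  amp <- exp(-(tt - t_center)^2 / (2 * sigma^2))
  normalize_irf(tt, amp)
}

#' @rdname gaussian_irf
#' @param path two-column ASCII file (time ps, amplitude)
#' @export
read_irf <- function(path, timegrid) {
  tab <- utils::read.table(path, col.names = c("t", "amp"))
  tt <- c(0, timegrid$times)
  amp <- approx(tab$t, tab$amp, xout = tt, yleft = 0, yright = 0)$y
  normalize_irf(tt, amp)
}

normalize_irf <- function(times, amplitude) {
  if (all(amplitude == 0)) stop("empty IRF")
  amplitude <- pmax(amplitude, 0)
  area <- trapz_between(times, amplitude, times[1], times[length(times)])
  structure(list(times = times, amplitude = amplitude / area), class = "irf")
}
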