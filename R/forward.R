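#' Build a bare optical-maps object from coefficient arrays
#'
#' Convenience constructor used by the solver tests and the two-region
#' predictor: wraps per-wavelength absorption/scattering arrays with grid
#' metadata without going through the tissue model.
#'
#' @param mua,musp lists of 3D arrays (or single arrays), mm^-1
#' @param spacing voxel edge, mm
#' @param wavelengths nm labels (defaults to seq_along)
#' @param n refractive index
#' @param origin grid origin, mm (defaults to x/y-centered, z = 0 at top)
#' @return an `optical_maps` object
#' @export
optical_maps <- function(mua, musp, spacing, wavelengths = NULL, n = 1.4,
                         origin = NULL) {
  if (is.array(mua)) mua <- list(mua)
  if (is.array(musp)) musp <- list(musp)
  stopifnot(length(mua) == length(musp))
  d <- dim(mua[[1]])
  if (is.null(origin)) origin <- c(-d[1] * spacing / 2, -d[2] * spacing / 2, 0)
  if (is.null(wavelengths)) wavelengths <- seq_along(mua)
  for (k in seq_along(mua)) {
    if (any(mua[[k]] <= 0) || any(musp[[k]] <= 0))
      stop("optical coefficients must be positive")
  }
  structure(list(wavelengths = wavelengths, mua = mua, musp = musp, n = n,
                 spacing = spacing, origin = origin),
            class = "optical_maps")
}

grid_axes <- function(optics) {
  d <- dim(optics$mua[[1]])
  lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * optics$spacing +
           optics$origin[ax])
}

# Gaussian initial-condition field for one source: unit integral, deposited
# one transport mean free path below the optode.
source_field <- function(optics, wl_index, pos, width) {
  d <- dim(optics$mua[[1]])
  ax <- grid_axes(optics)
  h <- optics$spacing
  ix <- which.min(abs(ax[[1]] - pos[1]))
  iy <- which.min(abs(ax[[2]] - pos[2]))
  z0 <- 1 / optics$musp[[wl_index]][ix, iy, 1]
  dx2 <- outer(outer((ax[[1]] - pos[1])^2, (ax[[2]] - pos[2])^2, `+`),
               (ax[[3]] - z0)^2, `+`)
  w <- exp(-dx2 / (2 * width^2))
  w / (sum(w) * h^3)
}

# Gaussian surface readout weights for one detector, scaled by the exitance
# factor 1/(2A).
detector_field <- function(optics, pos, width, arobin) {
  d <- dim(optics$mua[[1]])
  ax <- grid_axes(optics)
  wxy <- exp(-(outer((ax[[1]] - pos[1])^2, (ax[[2]] - pos[2])^2, `+`)) /
               (2 * width^2))
  w <- array(0, d)
  w[, , 1] <- wxy / sum(wxy)
  w / (2 * arobin)
}

#' Solve the time-domain diffusion equation for one source
#'
#' Implicit-Euler stepping of \eqn{(1/c)\,\partial\Phi/\partial t =
#' \nabla\cdot\kappa\nabla\Phi - \mu_a\Phi} with \eqn{\kappa = 1/(3\mu_s')}
#' and the Robin boundary condition \eqn{\Phi + 2A\kappa\,\partial\Phi/
#' \partial n = 0}, on the voxel grid of `optics`. The source is a
#' unit-integral Gaussian of width `geometry$source_width` deposited one
#' transport mean free path below the optode at t = 0 (an
#' initial-condition realization of the pulsed Neumann source).
#'
#' @param optics an `optical_maps` object
#' @param geometry a [probe_geometry()] (or a list with a `sources` matrix)
#' @param source_id row index into `geometry$sources`
#' @param timegrid a [time_grid()]
#' @param wl_index wavelength index into the maps (default 1)
#' @param robin FALSE switches to a reflective (zero-flux) boundary, used by
#'   the photon-conservation sanity checks
#' @return a `fluence_movie`: list with `phi` (n_voxel x n_steps matrix),
#'   `times`, grid metadata
#' @export
solve_td_diffusion <- function(optics, geometry, source_id, timegrid,
                               wl_index = 1, robin = TRUE) {
  check_diffusive(optics, wl_index)
  d <- dim(optics$mua[[wl_index]])
  arobin <- robin_coefficient(optics$n)
  src <- matrix(source_field(optics, wl_index, geometry$sources[source_id, ],
                             geometry$source_width), ncol = 1)
  out <- .td_diffusion_cpp(
    kappa = as.vector(1 / (3 * optics$musp[[wl_index]])),
    mua = as.vector(optics$mua[[wl_index]]),
    dims = d, h = optics$spacing, dt = timegrid$dt,
    nsteps = timegrid$n_steps, cspeed = light_speed(optics$n),
    arobin = arobin, robin = robin, src = src,
    detw = matrix(numeric(0), nrow = prod(d), ncol = 0), movie = TRUE)
  structure(list(phi = out$movie, times = timegrid$times, dims = d,
                 spacing = optics$spacing, origin = optics$origin,
                 n = optics$n, arobin = arobin),
            class = "fluence_movie")
}

check_diffusive <- function(optics, wl_index) {
  ratio <- min(optics$musp[[wl_index]] / pmax(optics$mua[[wl_index]], 1e-12))
  if (ratio < 10)
    warning("musp'/mua ratio below 10 somewhere: diffusion approximation is marginal")
  invisible(ratio)
}

#' Detector readout from a fluence movie
#'
#' Gaussian-weighted (width `geometry$detector_width`) surface readout of
#' the exitance \eqn{\Gamma = \Phi/(2A)} at the detector site.
#'
#' @param movie a `fluence_movie` from [solve_td_diffusion()]
#' @param detector_id row index into `geometry$detectors`
#' @param geometry a [probe_geometry()]
#' @return a `tpsf`: list with `times` (ps) and `counts` (rate per ps)
#' @export
detect <- function(movie, detector_id, geometry) {
  pos <- geometry$detectors[detector_id, ]
  ax <- lapply(1:3, function(a) (seq_len(movie$dims[a]) - 0.5) * movie$spacing +
                 movie$origin[a])
  if (pos[1] < ax[[1]][1] - movie$spacing || pos[1] > max(ax[[1]]) + movie$spacing ||
      pos[2] < ax[[2]][1] - movie$spacing || pos[2] > max(ax[[2]]) + movie$spacing)
    stop("detector outside grid")
  fake_optics <- list(mua = list(array(0, movie$dims)), spacing = movie$spacing,
                      origin = movie$origin)
  w <- detector_field(fake_optics, pos, geometry$detector_width, movie$arobin)
  tpsf(times = movie$times, counts = as.vector(crossprod(as.vector(w), movie$phi)))
}

tpsf <- function(times, counts, source = NA, detector = NA, wavelength = NA,
                 noise = FALSE) {
  structure(list(times = times, counts = counts, source = source,
                 detector = detector, wavelength = wavelength, noise = noise),
            class = "tpsf")
}

#' Convolve a TPSF with an instrument response function
#'
#' Discrete causal convolution on the shared time grid, truncated to the
#' grid length; with a unit-area IRF the total counts are conserved up to
#' edge truncation.
#'
#' @param x a `tpsf` (or plain numeric curve on the IRF grid)
#' @param irf an `irf` object sampled at the same time step
#' @return the convolved `tpsf`
#' @export
convolve_irf <- function(x, irf) {
  counts <- if (inherits(x, "tpsf")) x$counts else x
  times <- if (inherits(x, "tpsf")) x$times else irf$times[-1]
  dt <- times[2] - times[1]
  out <- convolve_causal(counts, irf$amplitude, dt)
  if (inherits(x, "tpsf")) { x$counts <- out; x } else out
}

# y sampled at t = dt..n*dt; irf amplitude sampled at t = 0, dt, ..., n*dt.
convolve_causal <- function(y, irf_amp, dt) {
  n <- length(y)
  full <- convolve(c(0, y), rev(irf_amp), type = "open") * dt
  # full[k] = sum_j y0[j] * irf[k - j + 1]; y0 index 1 is t = 0
  full[2:(n + 1)]
}

#' Simulate a full measurement set
#'
#' Runs the forward solver for every source (batched per wavelength),
#' reads out all detectors, and convolves with the IRF. The result is a
#' noiseless `measurement_set`; add photon noise with [apply_noise()].
#'
#' @param optics an `optical_maps` object (all wavelengths)
#' @param geometry a [probe_geometry()]
#' @param timegrid a [time_grid()]
#' @param irf an `irf` object or NULL to skip convolution
#' @return a `measurement_set`: `curves` array (source x detector x
#'   wavelength x time, rate per ps), `times`, `geometry`, `wavelengths`,
#'   `irf`, `noise = FALSE`
#' @export
simulate_measurements <- function(optics, geometry, timegrid, irf = NULL) {
  d <- dim(optics$mua[[1]])
  n <- prod(d)
  arobin <- robin_coefficient(optics$n)
  ndet <- nrow(geometry$detectors)
  nsrc <- nrow(geometry$sources)
  nwl <- length(optics$wavelengths)
  detw <- vapply(seq_len(ndet), function(j)
    as.vector(detector_field(optics, geometry$detectors[j, ],
                             geometry$detector_width, arobin)),
    numeric(n))
  curves <- array(0, c(nsrc, ndet, nwl, timegrid$n_steps))
  for (k in seq_len(nwl)) {
    src <- vapply(seq_len(nsrc), function(i)
      source_field(optics, k, geometry$sources[i, ], geometry$source_width),
      numeric(n))
    out <- .td_diffusion_cpp(
      kappa = as.vector(1 / (3 * optics$musp[[k]])),
      mua = as.vector(optics$mua[[k]]), dims = d, h = optics$spacing,
      dt = timegrid$dt, nsteps = timegrid$n_steps,
      cspeed = light_speed(optics$n), arobin = arobin, robin = TRUE,
      src = src, detw = detw)
    # out$tpsf dims: (ndet, nsteps, nsrc)
    for (i in seq_len(nsrc)) {
      block <- out$tpsf[, , i]
      if (!is.null(irf))
        block <- t(apply(block, 1, convolve_causal, irf_amp = irf$amplitude,
                         dt = timegrid$dt))
      curves[i, , k, ] <- block
    }
  }
  structure(list(curves = curves, times = timegrid$times, dt = timegrid$dt,
                 geometry = geometry, wavelengths = optics$wavelengths,
                 irf = irf, noise = FALSE, Nexpect = NA_real_),
            class = "measurement_set")
}

# Poisson draw robust to very large means (normal approximation above 1e8).
rpois_safe <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e8
  if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  pmax(out, 0)
}

#' Apply the photon-budget Poisson noise model
#'
#' Per wavelength, the curve of the pair at the largest source-detector
#' separation is rescaled so that its time integral equals `Nexpect`
#' photons; every other pair is rescaled by the same factor, preserving the
#' pairwise integral ratios. Each native time bin is then replaced by a
#' Poisson draw with the rescaled expected counts.
#'
#' @param ms a noiseless `measurement_set`
#' @param Nexpect expected total counts at the largest separation (> 0)
#' @param rng_seed integer seed
#' @return the noisy `measurement_set` (counts stored as rates per ps)
#' @export
apply_noise <- function(ms, Nexpect = 1e6, rng_seed = 1L) {
  stopifnot(Nexpect > 0)
  if (isTRUE(ms$noise)) stop("measurement set already carries noise")
  dists <- sd_distances(ms$geometry)
  far <- which(dists == max(dists), arr.ind = TRUE)[1, ]
  dt <- ms$dt
  with_seed(rng_seed, {
    for (k in seq_along(ms$wavelengths)) {
      ref <- sum(ms$curves[far[1], far[2], k, ]) * dt
      scale <- Nexpect / ref
      expected <- ms$curves[, , k, , drop = FALSE] * scale * dt
      drawn <- array(rpois_safe(as.vector(pmax(expected, 0))), dim(expected))
      ms$curves[, , k, ] <- drawn / dt
    }
    ms$noise <- TRUE
    ms$Nexpect <- Nexpect
    ms
  })
}

#' Extract one TPSF from a measurement set
#' @param ms a `measurement_set`
#' @param source,detector,wavelength indices (wavelength index, not nm)
#' @return a `tpsf`
#' @export
ms_tpsf <- function(ms, source, detector, wavelength = 1) {
  tpsf(times = ms$times, counts = ms$curves[source, detector, wavelength, ],
       source = source, detector = detector,
       wavelength = ms$wavelengths[wavelength], noise = ms$noise)
}
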