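cc_14 <- usdot:::light_speed(1.4)

test_that("absorption scaling law and zero-source behaviour hold", {
  # raising mua by delta multiplies deep-interior fluence by exp(-delta c t)
  # (exact in the continuum; a small time step keeps the discrete deviation
  # well inside the tolerance)
  d <- c(21, 21, 21); h <- 2
  tg <- time_grid(dt = 5, n_steps = 200)
  src <- array(0, d); src[11, 11, 11] <- 1 / h^3
  run <- function(mua) {
    usdot:::.td_diffusion_cpp(as.vector(array(1 / 3, d)),
                              as.vector(array(mua, d)), d, h, tg$dt,
                              tg$n_steps, cc_14, robin_coefficient(1.4), TRUE,
                              matrix(as.vector(src), ncol = 1),
                              matrix(numeric(0), nrow = prod(d), ncol = 0),
                              movie = TRUE)$movie
  }
  m1 <- run(0.005); m2 <- run(0.01)
  lin <- 13 + 21 * (10 + 21 * 10)   # a nearby interior voxel
  ratio <- m2[lin, ] / m1[lin, ]
  expected <- exp(-(0.01 - 0.005) * cc_14 * tg$times)
  expect_lt(max(abs(ratio - expected) / expected), 0.02)
  # zero source -> identically zero field
  z <- usdot:::.td_diffusion_cpp(as.vector(array(1 / 3, d)),
                                 as.vector(array(0.01, d)), d, h, 25, 10,
                                 cc_14, 3.25, TRUE,
                                 matrix(0, prod(d), 1),
                                 matrix(numeric(0), nrow = prod(d), ncol = 0),
                                 movie = TRUE)
  expect_true(all(z$movie == 0))
})

test_that("photon count is conserved in a lossless reflective medium", {
  d <- c(15, 15, 9); h <- 2
  om <- optical_maps(array(1e-12, d) + 1e-12, array(1, d), spacing = h)
  om$mua[[1]][] <- 1e-12  # lossless
  geom <- probe_geometry()
  tg <- time_grid(dt = 25, n_steps = 80)
  mov <- solve_td_diffusion(om, geom, source_id = 1, timegrid = tg,
                            robin = FALSE)
  totals <- colSums(mov$phi) * h^3
  expect_lt(diff(range(totals)) / totals[1], 0.01)
})

test_that("detector readout is symmetric and ordered by separation", {
  d <- c(24, 21, 10); h <- 2
  om <- slab_optics(d = d, h = h)
  tg <- time_grid(dt = 25, n_steps = 150)
  geom <- probe_geometry()
  geom$sources <- rbind(c(0, 0, 0))
  geom$detectors <- rbind(c(-15, 0, 0), c(15, 0, 0), c(20, 0, 0))
  mov <- solve_td_diffusion(om, geom, 1, tg)
  t1 <- detect(mov, 1, geom)
  t2 <- detect(mov, 2, geom)
  t3 <- detect(mov, 3, geom)
  # symmetry about the source
  expect_lt(max(abs(t1$counts - t2$counts)) / max(t2$counts), 1e-6)
  # later peak for the longer separation
  expect_gt(which.max(t3$counts), which.max(t2$counts))
  # detector outside the grid errors
  geom_bad <- geom; geom_bad$detectors <- rbind(c(500, 0, 0))
  expect_error(detect(mov, 1, geom_bad), "outside")
})

test_that("reciprocity holds approximately in a homogeneous medium", {
  d <- c(24, 21, 10); h <- 2
  om <- slab_optics(d = d, h = h)
  tg <- time_grid(dt = 25, n_steps = 150)
  g1 <- probe_geometry()
  g1$sources <- rbind(c(-14, 0, 0)); g1$detectors <- rbind(c(14, 2, 0))
  g2 <- probe_geometry()
  g2$sources <- rbind(c(14, 2, 0)); g2$detectors <- rbind(c(-14, 0, 0))
  a <- detect(solve_td_diffusion(om, g1, 1, tg), 1, g1)
  b <- detect(solve_td_diffusion(om, g2, 1, tg), 1, g2)
  w <- a$counts > 1e-3 * max(a$counts)
  expect_lt(sqrt(sum((a$counts[w] - b$counts[w])^2) / sum(a$counts[w]^2)), 0.03)
})

test_that("halving the time step changes detector curves by under 2%", {
  # first-order stepping: the dt-halving change contracts by ~2x per level
  # (4.4% at 50->25 ps, 2.4% at 25->12.5, 1.3% at 12.5->6.25 on this far
  # pair); asserted in the asymptotic regime
  d <- c(16, 15, 8); h <- 4
  om <- slab_optics(d = d, h = h)
  geom <- probe_geometry()
  ms1 <- simulate_measurements(om, geom, time_grid(dt = 12.5, n_steps = 400))
  ms2 <- simulate_measurements(om, geom, time_grid(dt = 6.25, n_steps = 800))
  y1 <- ms1$curves[1, 8, 1, ]
  y2 <- ms2$curves[1, 8, 1, seq(2, 800, by = 2)]
  w <- y2 > 1e-3 * max(y2)
  expect_lt(sqrt(sum((y1[w] - y2[w])^2) / sum(y2[w]^2)), 0.02)
})

test_that("IRF convolution preserves area and broadens curves", {
  tg <- time_grid(dt = 25, n_steps = 240)
  y <- dnorm(tg$times, 1200, 200)
  x <- fake_tpsf(y)
  # delta IRF (unit mass at t = 0 under the discrete convolution) is identity
  delta <- structure(list(times = c(0, tg$times),
                          amplitude = c(1 / tg$dt, rep(0, tg$n_steps))),
                     class = "irf")
  expect_equal(convolve_irf(x, delta)$counts, y, tolerance = 1e-10)
  # unit-area Gaussian IRF conserves counts within 1%
  irf <- gaussian_irf(tg, fwhm = 400, t_center = 500)
  conv <- convolve_irf(x, irf)
  expect_lt(abs(sum(conv$counts) - sum(y)) / sum(y), 0.01)
  # broader IRF gives a non-decreasing full width at half maximum
  fwhm_of <- function(v) {
    above <- which(v >= max(v) / 2)
    (tail(above, 1) - above[1]) * tg$dt
  }
  irf2 <- gaussian_irf(tg, fwhm = 800, t_center = 500)
  expect_gte(fwhm_of(convolve_irf(x, irf2)$counts), fwhm_of(conv$counts))
  expect_error(usdot:::normalize_irf(c(0, 1), c(0, 0)), "empty")
})

test_that("measured IRFs load from two-column text and normalize", {
  tg <- time_grid(dt = 25, n_steps = 200)
  tt <- seq(0, 3000, by = 10)   # finer grid than the measurement axis
  amp <- exp(-(tt - 600)^2 / (2 * 150^2))
  path <- tempfile(fileext = ".txt")
  write.table(cbind(tt, amp), path, row.names = FALSE, col.names = FALSE)
  irf <- read_irf(path, tg)
  expect_equal(usdot:::trapz_between(irf$times, irf$amplitude, 0,
                                     max(irf$times)), 1, tolerance = 1e-9)
  expect_equal(irf$times[which.max(irf$amplitude)], 600)
})

test_that("discrete causal convolution matches the brute-force sum", {
  set.seed(2)
  dt <- 25; n <- 60
  y <- runif(n); irf_amp <- runif(n + 1)   # irf sampled from t = 0
  direct <- sapply(seq_len(n), function(k) {
    s <- 0
    for (j in seq_len(k)) s <- s + y[j] * irf_amp[k - j + 1]
    s * dt
  })
  expect_equal(usdot:::convolve_causal(y, irf_amp, dt), direct,
               tolerance = 1e-12)
})

test_that("Poisson noise anchors the photon budget at the far pair", {
  d <- c(16, 15, 8); h <- 4
  om <- slab_optics(d = d, h = h)
  geom <- probe_geometry()
  tg <- time_grid(dt = 50, n_steps = 100)
  ms <- simulate_measurements(om, geom, tg, gaussian_irf(tg))
  dists <- sd_distances(geom)
  far <- which(dists == max(dists), arr.ind = TRUE)[1, ]
  Nexp <- 1e6
  noisy <- apply_noise(ms, Nexp, rng_seed = 5)
  tot <- sum(noisy$curves[far[1], far[2], 1, ]) * tg$dt
  expect_lt(abs(tot - Nexp), 3 * sqrt(Nexp))
  # relative integral ratios are preserved in expectation: check a near pair
  ratio0 <- sum(ms$curves[1, 1, 1, ]) / sum(ms$curves[far[1], far[2], 1, ])
  ratio1 <- sum(noisy$curves[1, 1, 1, ]) / sum(noisy$curves[far[1], far[2], 1, ])
  expect_lt(abs(ratio1 - ratio0) / ratio0, 0.01)
  # determinism per seed and idempotence guard
  noisy2 <- apply_noise(ms, Nexp, rng_seed = 5)
  expect_identical(noisy$curves, noisy2$curves)
  expect_error(apply_noise(noisy, Nexp), "already")
  expect_error(apply_noise(ms, -1), "Nexpect")
  # large-budget limit approaches the noiseless shape
  big <- apply_noise(ms, 1e9, rng_seed = 2)
  y0 <- ms$curves[far[1], far[2], 1, ]; y0 <- y0 / sum(y0)
  y1 <- big$curves[far[1], far[2], 1, ]; y1 <- y1 / sum(y1)
  w <- y0 > 1e-3 * max(y0)
  expect_lt(sqrt(sum((y1[w] - y0[w])^2) / sum(y0[w]^2)), 0.01)
})
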