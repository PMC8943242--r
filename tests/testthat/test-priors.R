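test_that("Dice index identities and closed forms", {
  d <- c(10, 10, 10)
  X <- array(FALSE, d); X[5, 5, 5] <- TRUE
  Y <- array(FALSE, d); Y[5, 5, 5] <- TRUE; Y[5, 5, 6] <- TRUE
  expect_equal(sdi(X, X), 1)
  expect_equal(sdi(X, Y), 2 / 3)
  expect_equal(sdi(Y, X), 2 / 3)            # symmetry
  Z <- array(FALSE, d); Z[1, 1, 1] <- TRUE
  expect_equal(sdi(X, Z), 0)
  expect_error(sdi(array(FALSE, d), array(FALSE, d)), "undefined")
})

test_that("Dice range, symmetry and self-dominance on random masks", {
  set.seed(12)
  d <- c(12, 12, 12)
  for (i in 1:20) {
    X <- array(runif(prod(d)) < 0.3, d)
    Y <- array(runif(prod(d)) < 0.3, d)
    s <- sdi(X, Y)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, sdi(Y, X))
    expect_gte(sdi(X, X), s)
  }
})

test_that("geometry metrics report dV, dA and displacement", {
  d <- c(16, 15, 8); h <- 2
  truth_m <- array(FALSE, d); truth_m[6:10, 6:10, 3:5] <- TRUE
  origin <- c(-d[1] * h / 2, -d[2] * h / 2, 0)
  truth <- prior_mask(truth_m, h, origin, "ground_truth")
  expect_equal(geometry_metrics(truth, truth)$dV, 0)
  expect_equal(unname(geometry_metrics(truth, truth)$displacement), c(0, 0, 0))
  # half-volume erosion along z
  est_m <- truth_m; est_m[, , 5] <- FALSE; est_m[6:10, 6:10, 2] <- FALSE
  # build exact half-volume: keep 2 of 3 z-slabs minus some voxels
  est_m <- array(FALSE, d); est_m[6:10, 6:10, 3:4] <- TRUE
  est_m[6:10, 6, 4] <- FALSE
  # ensure |est| is about half of |truth|
  est <- prior_mask(est_m, h, origin, "degraded")
  gm <- geometry_metrics(est, truth)
  expect_equal(gm$dV, (sum(est_m) - sum(truth_m)) / sum(truth_m))
  # translation by one voxel in z
  shifted <- prior_mask(usdot:::shift3(truth_m, 3, 1L), h, origin, "degraded")
  gm2 <- geometry_metrics(shifted, truth)
  expect_equal(gm2$dV, 0)
  expect_equal(unname(gm2$displacement), c(0, 0, h))
  # dA is computed on the y = 0 slice
  iy <- which.min(abs((seq_len(d[2]) - 0.5) * h + origin[2]))
  a_t <- sum(truth_m[, iy, ]); a_e <- sum(est_m[, iy, ])
  expect_equal(gm$dA, (a_e - a_t) / a_t)
  expect_error(geometry_metrics(truth, prior_mask(array(FALSE, d), h, origin)),
               "empty")
})

test_that("2D disk extrapolates to a ball; degenerate and symmetric cases", {
  h <- 2; r <- 10
  n2 <- 21
  ax <- (seq_len(n2) - (n2 + 1) / 2) * h
  disk <- outer(ax^2, ax^2, `+`) <= r^2
  pm <- extrapolate_2d_to_3d(disk, h)
  d3 <- dim(pm$mask)
  # central slice equals the input mask
  mid <- (d3[2] + 1) / 2
  expect_equal(pm$mask[, mid, ], disk)
  # mirror symmetry in +/- y
  for (j in 1:((d3[2] - 1) / 2))
    expect_equal(pm$mask[, mid + j, ], pm$mask[, mid - j, ])
  # overlap with the analytic ball
  ay <- (seq_len(d3[2]) - mid) * h
  ball <- outer(outer(ax^2, ay^2, `+`), ax^2, `+`) <= r^2
  expect_gte(sdi(pm$mask, ball), 0.9)
  # y-extent bounded by the max interior distance
  ymax <- max(abs(ay[apply(pm$mask, 2, any)]))
  expect_lte(ymax, max(usdot:::edt2(disk)) * h)
  # single pixel -> single voxel
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  ps <- extrapolate_2d_to_3d(single, h)
  expect_equal(sum(ps$mask), 1L)
  expect_error(extrapolate_2d_to_3d(matrix(FALSE, 5, 5), h), "empty")
})

test_that("prior degradation hits volume targets and identity case", {
  h <- 2
  d <- c(20, 20, 16)
  ax1 <- (seq_len(d[1]) - (d[1] + 1) / 2) * h
  ax3 <- (seq_len(d[3]) - (d[3] + 1) / 2) * h
  ball <- outer(outer(ax1^2, ax1^2, `+`), ax3^2, `+`) <= 12^2
  truth <- prior_mask(ball, h, NULL, "ground_truth")
  # identity target returns the input
  same <- degrade_prior(truth, target_dv = 0, target_shift = c(0, 0, 0),
                        rng_seed = 1)
  expect_identical(same$mask, truth$mask)
  # -0.5 volume target achieved within the documented band
  for (s in 1:5) {
    deg <- degrade_prior(truth, target_dv = -0.5, target_shift = c(0, 0, 0),
                         rng_seed = s)
    expect_gte(deg$achieved_dv, -0.55)
    expect_lte(deg$achieved_dv, -0.45)
    expect_lt(sdi(deg, truth), 1)
  }
  # overlap decreases monotonically (on average) as the target shrinks
  sdis <- vapply(c(-0.2, -0.5, -0.8), function(tv)
    sdi(degrade_prior(truth, target_dv = tv, target_shift = c(0, 0, 0),
                      rng_seed = 3), truth), numeric(1))
  expect_true(all(diff(sdis) < 0))
  expect_error(degrade_prior(truth, target_dv = -0.96, rng_seed = 1),
               "unreachable")
})
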