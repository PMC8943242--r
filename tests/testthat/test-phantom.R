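test_that("generated phantoms honour the fat fraction and are deterministic", {
  for (ff in c(0.3, 0.6)) {
    cfg <- tiny_phantom_config()
    cfg$fat_fraction <- ff
    vol <- generate_phantom(cfg, rng_seed = 11)
    tis <- vol$tissues
    nonskin <- vol$labels[vol$labels != tis[["skin"]] & vol$labels != tis[["air"]]]
    frac <- mean(nonskin == tis[["adipose"]])
    expect_lt(abs(frac - ff), 0.1)
  }
  cfg <- tiny_phantom_config()
  v1 <- generate_phantom(cfg, rng_seed = 5)
  v2 <- generate_phantom(cfg, rng_seed = 5)
  expect_identical(v1$labels, v2$labels)
  v3 <- generate_phantom(cfg, rng_seed = 6)
  expect_false(identical(v1$labels, v3$labels))
})

test_that("degenerate composition: fat_fraction near 1 with no tubes is all adipose inside", {
  cfg <- tiny_phantom_config(n_vessels = 0L, n_ducts = 0L)
  cfg$fat_fraction <- 0.999
  vol <- generate_phantom(cfg, rng_seed = 2)
  tis <- vol$tissues
  interior <- vol$labels[vol$labels != tis[["skin"]]]
  expect_gt(mean(interior == tis[["adipose"]]), 0.99)
})

test_that("lesion shapes digitize spheres and scale with irregularity", {
  # irregularity 0: volume within 5% of the continuum ball
  m0 <- generate_lesion_shape(lesion_spec(mean_radius = 6, irregularity = 0,
                                          rng_seed = 1), spacing = 0.5)
  vol <- sum(m0) * 0.5^3
  expect_rel(vol, 4 / 3 * pi * 6^3, 0.05)
  # equivalent radius within the documented band
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  expect_gt(r_eq, 5.1); expect_lt(r_eq, 6.9)
  # reproducible irregular mask with larger surface-to-volume than a sphere
  m1 <- generate_lesion_shape(lesion_spec(mean_radius = 6, irregularity = 0.5,
                                          rng_seed = 3), spacing = 0.5)
  m2 <- generate_lesion_shape(lesion_spec(mean_radius = 6, irregularity = 0.5,
                                          rng_seed = 3), spacing = 0.5)
  expect_identical(m1, m2)
  surf_vox <- function(m) sum(m & !usdot:::erode6(m))
  expect_gte(surf_vox(m1) / sum(m1), surf_vox(m0) / sum(m0))
  # single connected component
  expect_equal(usdot:::n_components6(m1), 1L)
  # unresolvable radius errors out
  expect_error(generate_lesion_shape(lesion_spec(mean_radius = 3), spacing = 2),
               "resolvable")
})

test_that("lesion insertion respects the imaging-plane constraint and locality", {
  cfg <- tiny_phantom_config()
  vol <- generate_phantom(cfg, rng_seed = 4)
  mask <- generate_lesion_shape(lesion_spec(mean_radius = 5, irregularity = 0.2,
                                            rng_seed = 9), spacing = 1)
  out <- insert_lesion(vol, mask, rng_seed = 21)
  tis <- vol$tissues
  les <- which(out$labels == tis[["lesion"]], arr.ind = TRUE)
  expect_gt(nrow(les), 0)
  ys <- voxel_centers(out, 2)[les[, 2]]
  l_mm <- (diff(range(les[, 2])) + 1) * out$spacing
  expect_lte(abs(mean(ys)), 0.3 * l_mm + 1e-9)
  # voxels outside the lesion are untouched
  changed <- which(out$labels != vol$labels)
  expect_true(all(out$labels[changed] == tis[["lesion"]]))
  # lesion never lands on air or skin
  expect_false(any(vol$labels[changed] %in% c(tis[["air"]], tis[["skin"]])))
  # all-skin volume has no admissible placement
  skin_vol <- label_volume(array(tis[["skin"]], c(10, 10, 10)), spacing = 1)
  expect_error(insert_lesion(skin_vol, mask, rng_seed = 1), "placement|interior")
})

test_that("placement constraint holds across many seeds", {
  cfg <- tiny_phantom_config()
  vol <- generate_phantom(cfg, rng_seed = 8)
  mask <- generate_lesion_shape(lesion_spec(mean_radius = 4, irregularity = 0.3,
                                            rng_seed = 2), spacing = 1)
  for (s in 1:25) {
    out <- insert_lesion(vol, mask, rng_seed = s)
    les <- which(out$labels == out$tissues[["lesion"]], arr.ind = TRUE)
    ys <- voxel_centers(out, 2)[les[, 2]]
    l_mm <- (diff(range(les[, 2])) + 1) * out$spacing
    expect_lte(abs(mean(ys)), 0.3 * l_mm + 1e-9)
  }
})

test_that("compression hits the target thickness and conserves volume", {
  cfg <- tiny_phantom_config()
  vol <- generate_phantom(cfg, rng_seed = 3)
  out <- compress_phantom(vol, 24)
  nz <- apply(usdot:::breast_mask(out), 3, any)
  expect_lte(abs(sum(nz) * out$spacing - 24), out$spacing)
  v_in <- sum(usdot:::breast_mask(vol)) * vol$spacing^3
  v_out <- sum(usdot:::breast_mask(out)) * out$spacing^3
  expect_lt(abs(v_out - v_in) / v_in, 0.1)
  expect_true(all(unique(as.vector(out$labels)) %in% unname(vol$tissues)))
  # already at target -> no-op with warning
  expect_warning(same <- compress_phantom(out, 24 + 2), "no-op")
  expect_identical(same$labels, out$labels)
})

test_that("majority downsampling reassigns air and matches the optical grid", {
  tis <- tissue_registry()
  # uniform block stays itself
  u <- label_volume(array(tis[["glandular"]], c(8, 8, 8)), spacing = 0.5)
  expect_true(all(downsample_labels(u, 4)$labels == tis[["glandular"]]))
  # air-majority voxel in an adipose-dominated breast becomes adipose
  lab <- array(tis[["adipose"]], c(8, 8, 8))
  lab[, , 7:8] <- tis[["air"]]
  lab[1, 1, 1] <- tis[["glandular"]]
  v <- label_volume(lab, spacing = 0.5)
  dd <- downsample_labels(v, 4)
  expect_equal(dim(dd$labels), c(2L, 2L, 2L))
  expect_true(all(dd$labels[, , 2] == tis[["adipose"]]))
  expect_equal(dd$spacing, 2)
  # 0.5 mm grid with factor 4 gives the 2 mm optical grid
  cfg <- tiny_phantom_config()
  vol <- generate_phantom(cfg, rng_seed = 13)
  coarse <- downsample_labels(vol, 4)
  expect_equal(coarse$spacing, vol$spacing * 4)
  # down-then-up agreement on smooth phantoms
  up <- coarse$labels[rep(seq_len(dim(coarse$labels)[1]), each = 4),
                      rep(seq_len(dim(coarse$labels)[2]), each = 4),
                      rep(seq_len(dim(coarse$labels)[3]), each = 4)]
  d <- dim(vol$labels)
  agree <- mean(up[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] == vol$labels)
  expect_gt(agree, 0.7)
})

test_that("label volumes round-trip through NIfTI + YAML", {
  cfg <- tiny_phantom_config()
  vol <- generate_phantom(cfg, rng_seed = 17)
  path <- file.path(tempdir(), "phantom_rt")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
})
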