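# Small shared fixtures built in code.

tiny_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(fat_fraction = 0.6, target_thickness = 24,
         domain_size = c(32, 32, 32), fine_spacing = 1,
         coarse_spacing = 4, n_vessels = 2L, n_ducts = 2L),
    list(...))
  do.call(phantom_config, args)
}

# Homogeneous optical maps on a small study-style grid.
slab_optics <- function(mua = 0.008, musp = 1.0, d = c(16, 15, 8), h = 4,
                        mask = NULL, mua_in = mua, musp_in = musp) {
  mua_arr <- array(mua, d); musp_arr <- array(musp, d)
  if (!is.null(mask)) { mua_arr[mask] <- mua_in; musp_arr[mask] <- musp_in }
  optical_maps(mua_arr, musp_arr, spacing = h)
}

# Centered ball mask on the grid of `optics`.
ball_mask <- function(optics, radius, center = c(0, 0, 15)) {
  ax <- usdot:::grid_axes(optics)
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`),
              (ax[[3]] - center[3])^2, `+`)
  d2 <= radius^2
}

# A synthetic TPSF-like curve object.
fake_tpsf <- function(counts, dt = 25) {
  usdot:::tpsf(times = dt * seq_along(counts), counts = counts)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
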