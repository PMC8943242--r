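#' Morphological prior mask
#'
#' Binary 3D region on the optical lattice defining the two-region split.
#'
#' @param mask logical 3D array
#' @param spacing voxel edge, mm
#' @param origin grid origin, mm
#' @param provenance one of "ground_truth", "extrapolated_2d", "degraded"
#' @return a `prior_mask` object
#' @export
prior_mask <- function(mask, spacing, origin = NULL,
                       provenance = c("ground_truth", "extrapolated_2d",
                                      "degraded")) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(mask), length(dim(mask)) == 3, spacing > 0)
  d <- dim(mask)
  if (is.null(origin)) origin <- c(-d[1] * spacing / 2, -d[2] * spacing / 2, 0)
  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 provenance = provenance),
            class = "prior_mask")
}

#' Ground-truth prior from a labeled phantom
#' @param volume a [label_volume()] on the optical grid
#' @return a `prior_mask` with provenance "ground_truth"
#' @export
lesion_prior <- function(volume) {
  m <- volume$labels == volume$tissues[["lesion"]]
  dim(m) <- dim(volume$labels)
  prior_mask(m, volume$spacing, volume$origin, "ground_truth")
}

#' Sorensen-Dice index of two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)`; symmetric, in `[0, 1]`.
#'
#' @param X,Y logical arrays on the same grid
#' @return dimensionless overlap score
#' @export
sdi <- function(X, Y) {
  if (inherits(X, "prior_mask")) X <- X$mask
  if (inherits(Y, "prior_mask")) Y <- Y$mask
  stopifnot(identical(dim(X), dim(Y)))
  nx <- sum(X); ny <- sum(Y)
  if (nx + ny == 0) stop("SDI undefined for two empty masks")
  2 * sum(X & Y) / (nx + ny)
}

#' Geometry metrics of an estimated prior against the ground truth
#'
#' Relative volume mismatch `dV = (V_est - V_truth)/V_truth`, the analogous
#' area mismatch `dA` computed on the ultrasound imaging-plane slice
#' (y = 0), the Sorensen-Dice index, and the per-axis center-of-mass
#' displacement in mm (estimate minus truth).
#'
#' @param est,truth `prior_mask` objects on the same grid
#' @return list with `sdi`, `dA`, `dV`, `displacement` (mm, named x/y/z)
#' @export
geometry_metrics <- function(est, truth) {
  stopifnot(identical(dim(est$mask), dim(truth$mask)))
  if (!any(truth$mask)) stop("empty truth mask")
  vt <- sum(truth$mask); ve <- sum(est$mask)
  dv <- (ve - vt) / vt
  ypos <- (seq_len(dim(est$mask)[2]) - 0.5) * est$spacing + est$origin[2]
  iy <- which.min(abs(ypos))
  at <- sum(truth$mask[, iy, ]); ae <- sum(est$mask[, iy, ])
  da <- if (at > 0) (ae - at) / at else NA_real_
  com <- function(m, sp, orig) {
    idx <- which(m, arr.ind = TRUE)
    (colMeans(idx) - 0.5) * sp + orig
  }
  disp <- if (any(est$mask))
    com(est$mask, est$spacing, est$origin) - com(truth$mask, truth$spacing,
                                                 truth$origin)
  else c(NA_real_, NA_real_, NA_real_)
  names(disp) <- c("x", "y", "z")
  list(sdi = sdi(est$mask, truth$mask), dA = da, dV = dv, displacement = disp)
}

#' Extrapolate a 2D imaging-plane mask to a 3D solid
#'
#' Stand-in for an interactive distance-transform extrapolation: the 2D
#' mask's interior Euclidean distance field `d(x, z)` is converted to a
#' local half-thickness with a spherical profile,
#' `t(x, z) = sqrt(dmax^2 - (dmax - d)^2)` with `dmax = max d`, and the 3D
#' solid contains the voxel at out-of-plane offset y when `|y| < t`. A 2D
#' disk therefore extrapolates to the corresponding ball, the output's
#' y = 0 slice equals the input mask, and the y-extent is bounded by the
#' mask's maximum interior distance.
#'
#' @param mask2d logical matrix (x by z) on the imaging plane
#' @param spacing voxel edge, mm
#' @param ny number of output slices along y (odd; default wide enough for
#'   the profile)
#' @return a `prior_mask` with provenance "extrapolated_2d"; the central
#'   slice is the y = 0 plane
#' @export
extrapolate_2d_to_3d <- function(mask2d, spacing, ny = NULL) {
  if (!any(mask2d)) stop("empty input mask")
  # pixel-center to boundary distance: the transform measures to the nearest
  # background pixel center, half a pixel beyond the contour
  dmap <- pmax(edt2(mask2d) - 0.5, 0) * spacing
  dmax <- max(dmap)
  thick <- sqrt(pmax(dmax^2 - (dmax - dmap)^2, 0))
  if (is.null(ny)) ny <- 2L * ceiling(dmax / spacing) + 1L
  if (ny %% 2 == 0) ny <- ny + 1L
  half <- (ny - 1L) / 2L
  d2 <- dim(mask2d)
  out <- array(FALSE, c(d2[1], ny, d2[2]))
  for (j in (-half):half) {
    yoff <- abs(j) * spacing
    out[, j + half + 1L, ] <- mask2d & (yoff < thick)
  }
  origin <- c(-d2[1] * spacing / 2, -ny * spacing / 2, 0)
  prior_mask(out, spacing, origin, "extrapolated_2d")
}

# Exact 2D Euclidean distance transform (distance of foreground pixels to
# the nearest background pixel, in pixels), via EBImage when available.
edt2 <- function(mask) {
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(img, metric = "euclidean"))
}

# Integer chamfer-style interior/exterior distances via repeated 6-connected
# erosion/dilation (in voxels); sufficient resolution for the emulator.
signed_chamfer3 <- function(mask, max_iter = 64L) {
  d <- array(0, dim(mask))
  cur <- mask
  for (i in seq_len(max_iter)) {
    if (!any(cur)) break
    d[cur] <- d[cur] + 1
    cur <- erode6(cur)
  }
  cur <- !mask
  dout <- array(0, dim(mask))
  for (i in seq_len(max_iter)) {
    if (!any(cur)) break
    dout[cur] <- dout[cur] + 1
    cur <- erode6(cur)
  }
  d - dout
}

#' Degrade a ground-truth prior to emulate ultrasound-derived quality
#'
#' Emulator of the geometric quality of priors segmented and extrapolated
#' from B-mode images: the truth mask's signed (chamfer) distance field is
#' perturbed by a smooth random field and re-thresholded so that the
#' relative volume mismatch hits `target_dv` (level set chosen by
#' bisection), then the mask is shifted by the rounded `target_shift`.
#' Defaults draw `target_dv ~ N(-0.5, 0.17)` (truncated to (-0.9, 0.2))
#' and per-axis shifts from the displacement statistics of the
#' extrapolation procedure (x: N(0.04, 0.13), y: N(0.08, 0.05),
#' z: N(0.14, 0.08) mm). The shape noise amplitude is calibrated so that
#' the emulated population's mean Dice overlap against truth sits near
#' 0.55 at the default 50% volume underestimation.
#'
#' @param truth a `prior_mask` (non-empty)
#' @param target_dv relative volume mismatch to achieve (within +/- 0.05);
#'   NULL draws the default
#' @param target_shift mm, length 3; NULL draws the default
#' @param rng_seed integer seed
#' @param noise_amp shape-noise amplitude in voxel (distance) units
#' @return a `prior_mask` with provenance "degraded"
#' @export
degrade_prior <- function(truth, target_dv = NULL, target_shift = NULL,
                          rng_seed = 1L, noise_amp = 1.3) {
  if (!any(truth$mask)) stop("empty truth mask")
  with_seed(rng_seed, {
    if (is.null(target_dv)) {
      target_dv <- rnorm(1, -0.5, 0.17)
      target_dv <- min(max(target_dv, -0.9), 0.2)
    }
    if (is.null(target_shift))
      target_shift <- c(rnorm(1, 0.04, 0.13), rnorm(1, 0.08, 0.05),
                        rnorm(1, 0.14, 0.08))
    if (target_dv <= -0.95)
      stop("unreachable volume target (dV <= -0.95)")
    if (target_dv == 0 && all(target_shift == 0)) return_mask <- truth$mask
    else {
      vt <- sum(truth$mask)
      v_target <- max(round((1 + target_dv) * vt), 1)
      field <- signed_chamfer3(truth$mask)
      noise <- smooth3_gauss(array(rnorm(length(field)), dim(field)), 1.5)
      noise <- noise / max(sd(noise), 1e-12)
      field <- field + noise_amp * noise
      threshold_to <- function(v_want) {
        lo <- min(field) - 1; hi <- max(field) + 1
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          if (sum(field > mid) > v_want) lo <- mid else hi <- mid
        }
        mm <- field > (lo + hi) / 2
        if (any(mm)) mm <- largest_component6(mm)
        mm
      }
      v_want <- v_target
      m <- threshold_to(v_want)
      # component pruning can undershoot the volume; correct up to twice
      for (rep in 1:2) {
        if (any(m) && abs(sum(m) - v_target) / vt <= 0.04) break
        v_want <- v_want + (v_target - sum(m))
        if (v_want < 1) break
        m <- threshold_to(v_want)
      }
      if (!any(m)) {  # fall back to the deepest voxel
        m <- array(FALSE, dim(field))
        m[which.max(field)] <- TRUE
      }
      shift_vox <- round(target_shift / truth$spacing)
      for (ax in 1:3) if (shift_vox[ax] != 0) m <- shift3(m, ax, shift_vox[ax])
      if (!any(m)) stop("shift moved the mask out of the grid")
      return_mask <- m
    }
    achieved <- (sum(return_mask) - sum(truth$mask)) / sum(truth$mask)
    out <- prior_mask(return_mask, truth$spacing, truth$origin, "degraded")
    out$target_dv <- target_dv
    out$achieved_dv <- achieved
    out$target_shift <- target_shift
    out
  })
}
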