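#' Phantom generation configuration
#'
#' @param fat_fraction target adipose fraction of the non-skin breast
#'   interior, in (0, 1)
#' @param target_thickness slab thickness after compression, mm (default
#'   45 mm, the mild flat-paddle compression of a handheld probe)
#' @param domain_size length-3 numeric, mm extent of the generated domain
#' @param fine_spacing fine (anatomical) voxel edge, mm
#' @param coarse_spacing coarse (optical) voxel edge, mm; must be an integer
#'   multiple of `fine_spacing`
#' @param skin_thickness skin layer thickness at the top and bottom of the
#'   slab, mm
#' @param texture_scale correlation length of the adipose/glandular mixture
#'   texture, mm; the default (15 mm) produces the centimetre-scale
#'   compartmental fibroglandular structure of real breasts rather than
#'   voxel-scale binary noise
#' @param center_bias strength (in field standard deviations) of the
#'   central concentration of glandular tissue
#' @param n_vessels,n_ducts number of vessel (artery + vein) and duct tubes
#' @return a `phantom_config` list
#' @export
phantom_config <- function(fat_fraction = 0.5, target_thickness = 45,
                           domain_size = c(64, 58, 60), fine_spacing = 0.5,
                           coarse_spacing = 2, skin_thickness = 1.5,
                           texture_scale = 15, center_bias = 1,
                           n_vessels = 4L, n_ducts = 4L) {
  stopifnot(fat_fraction > 0, fat_fraction < 1,
            target_thickness > 0, all(domain_size > 0),
            fine_spacing > 0, coarse_spacing > 0)
  ratio <- coarse_spacing / fine_spacing
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("coarse_spacing must be an integer multiple of fine_spacing")
  structure(list(fat_fraction = fat_fraction,
                 target_thickness = target_thickness,
                 domain_size = domain_size, fine_spacing = fine_spacing,
                 coarse_spacing = coarse_spacing,
                 skin_thickness = skin_thickness,
                 texture_scale = texture_scale,
                 center_bias = center_bias,
                 n_vessels = as.integer(n_vessels),
                 n_ducts = as.integer(n_ducts)),
            class = "phantom_config")
}

#' Generate a voxelized breast digital phantom
#'
#' Simplified layered-morphology generator: a tissue slab filling the domain
#' in z, skin layers at the top and bottom surfaces, an adipose/glandular
#' interior obtained by thresholding a smoothed Gaussian random field at the
#' configured fat fraction, and sparse vessel and duct tubes. The adipose
#' fraction of the non-skin interior matches `config$fat_fraction` exactly
#' at threshold time (tube insertion perturbs it by well under 0.1).
#'
#' @param config a [phantom_config()]
#' @param rng_seed integer seed; identical seed and config give bit-identical
#'   label grids
#' @return a [label_volume()] at `config$fine_spacing`
#' @export
generate_phantom <- function(config, rng_seed = 1L) {
  h <- config$fine_spacing
  dims <- pmax(round(config$domain_size / h), 1L)
  skin_vox <- round(config$skin_thickness / h)
  if (2 * skin_vox >= dims[3])
    stop("domain too small to contain the skin layers at this spacing")
  tis <- tissue_registry()
  with_seed(rng_seed, {
    labels <- array(tis[["adipose"]], dims)
    zi <- seq_len(dims[3])
    skin <- zi <= skin_vox | zi > dims[3] - skin_vox
    # adipose/glandular mixture: smoothed Gaussian field plus a central
    # bias (glandular tissue concentrates in a central fibroglandular
    # compartment), thresholded at the fat-fraction quantile. The field is
    # built on a decimated lattice and upsampled: its correlation length is
    # far above the voxel size, so nothing is lost and smoothing stays fast.
    dec <- max(1L, floor(config$texture_scale / (4 * h)))
    ddims <- pmax(dims %/% dec, 2L)
    gd <- array(rnorm(prod(ddims)), ddims)
    gd <- smooth3_gauss(gd, config$texture_scale / (h * dec))
    gd <- (gd - mean(gd)) / max(sd(gd), 1e-12)
    if (config$center_bias != 0) {
      nc <- lapply(1:3, function(ax) {
        v <- (seq_len(ddims[ax]) - (ddims[ax] + 1) / 2) / (ddims[ax] / 2)
        v
      })
      r2 <- outer(outer(nc[[1]]^2, nc[[2]]^2, `+`), nc[[3]]^2, `+`)
      gd <- gd + config$center_bias * (1 - r2)
    }
    g <- gd[pmin(ceiling(seq_len(dims[1]) / dec), ddims[1]),
            pmin(ceiling(seq_len(dims[2]) / dec), ddims[2]),
            pmin(ceiling(seq_len(dims[3]) / dec), ddims[3]), drop = FALSE]
    gi <- g[, , !skin, drop = FALSE]
    thr <- quantile(gi, probs = config$fat_fraction, names = FALSE)
    mix <- ifelse(gi >= thr, tis[["glandular"]], tis[["adipose"]])
    labels[, , !skin] <- mix
    labels[, , skin] <- tis[["skin"]]
    # sparse tubes: arteries/veins and ducts drawn as jittered line segments
    add_tube <- function(labels, value, radius_mm) {
      p0 <- c(runif(1, 0.1, 0.9) * dims[1], runif(1, 0.1, 0.9) * dims[2],
              runif(1, 0.2, 0.8) * dims[3])
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- runif(1, 0.3, 0.8) * min(dims)
      tpts <- seq(0, len, by = 0.5)
      smooth1 <- function(v) {
        if (length(v) < 9) return(rep(0, length(v)))
        as.vector(stats::filter(c(rev(v[1:4]), v, rev(tail(v, 4))),
                                rep(1 / 9, 9)))[5:(length(v) + 4)]
      }
      jitter <- 2 * cbind(smooth1(rnorm(length(tpts))), smooth1(rnorm(length(tpts))),
                          smooth1(rnorm(length(tpts))))
      pts <- t(p0 + outer(dir, tpts)) + jitter
      r_vox <- radius_mm / h
      for (row in seq_len(nrow(pts))) {
        ctr <- pts[row, ]
        lo <- pmax(floor(ctr - r_vox), 1)
        hi <- pmin(ceiling(ctr + r_vox), dims)
        if (any(lo > hi)) next
        ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
        dd <- outer(outer((ix - ctr[1])^2, (iy - ctr[2])^2, `+`),
                    (iz - ctr[3])^2, `+`)
        sub <- labels[ix, iy, iz, drop = FALSE]
        inside <- dd <= r_vox^2 & sub != tis[["skin"]]
        sub[inside] <- value
        labels[ix, iy, iz] <- sub
      }
      labels
    }
    if (config$n_vessels > 0) {
      for (v in seq_len(config$n_vessels)) {
        value <- if (v %% 2 == 1) tis[["artery"]] else tis[["vein"]]
        labels <- add_tube(labels, value, radius_mm = runif(1, 0.4, 0.9))
      }
    }
    if (config$n_ducts > 0) {
      for (d in seq_len(config$n_ducts))
        labels <- add_tube(labels, tis[["duct"]], radius_mm = runif(1, 0.3, 0.6))
    }
    label_volume(labels, spacing = h)
  })
}

#' Lesion specification
#'
#' @param mean_radius target equivalent-sphere radius, mm (the study draws
#'   from 6 to 13.5 mm)
#' @param irregularity dimensionless >= 0 amplitude of the low-order
#'   spherical-harmonic radial perturbation (0 = sphere)
#' @param malignancy_class one of "benign", "malignant", "cyst" (cysts are a
#'   benign sub-class for classification labels)
#' @param rng_seed integer seed for the shape draw
#' @return a `lesion_spec` list
#' @export
lesion_spec <- function(mean_radius = 8, irregularity = 0.3,
                        malignancy_class = c("benign", "malignant", "cyst"),
                        rng_seed = 1L) {
  malignancy_class <- match.arg(malignancy_class)
  stopifnot(mean_radius > 0, irregularity >= 0)
  structure(list(mean_radius = mean_radius, irregularity = irregularity,
                 malignancy_class = malignancy_class,
                 rng_seed = as.integer(rng_seed)),
            class = "lesion_spec")
}

# Real low-order spherical-harmonic-like basis evaluated on unit directions.
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x, y, z,
        x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1,
        x * (5 * z^2 - 1), y * (5 * z^2 - 1), z * (5 * z^2 - 3),
        x * y * z, (x^2 - y^2) * z)
}

#' Generate a tumor-like binary lesion mask
#'
#' A digitized sphere whose radius is modulated along each direction by a
#' random combination of low-order spherical harmonics scaled by
#' `spec$irregularity`. The shape is rescaled once so that the
#' equivalent-sphere radius (from the voxel volume) matches
#' `spec$mean_radius`.
#'
#' @param spec a [lesion_spec()]
#' @param spacing voxel edge, mm; must satisfy `mean_radius >= 2 * spacing`
#' @return a logical 3D array (single 6-connected component) with attribute
#'   `spacing`
#' @export
generate_lesion_shape <- function(spec, spacing) {
  if (spec$mean_radius < 2 * spacing)
    stop("lesion radius below resolvable size at this spacing")
  with_seed(spec$rng_seed, {
    coefs <- rnorm(13)
    make_mask <- function(R0) {
      rmax <- R0 * (1 + 3 * spec$irregularity)
      n <- 2 * ceiling(rmax / spacing) + 3
      ax <- (seq_len(n) - (n + 1) / 2) * spacing
      gx <- array(rep(ax, times = n * n), c(n, n, n))
      gy <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
      gz <- array(rep(ax, each = n * n), c(n, n, n))
      rr <- sqrt(gx^2 + gy^2 + gz^2)
      rr_safe <- pmax(rr, 1e-9)
      u <- cbind(as.vector(gx / rr_safe), as.vector(gy / rr_safe),
                 as.vector(gz / rr_safe))
      if (spec$irregularity > 0) {
        f <- as.vector(sh_basis(u) %*% coefs)
        f <- f / max(sd(f), 1e-12)
        radius <- R0 * pmax(1 + spec$irregularity * array(f, dim(rr)), 0.2)
      } else radius <- array(R0, dim(rr))
      mask <- rr <= radius
      mask
    }
    mask <- make_mask(spec$mean_radius)
    r_eq <- (3 * sum(mask) * spacing^3 / (4 * pi))^(1 / 3)
    mask <- make_mask(spec$mean_radius * spec$mean_radius / r_eq)
    mask <- largest_component6(mask)
    # trim to the tight bounding box
    idx <- which(mask, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    attr(mask, "spacing") <- spacing
    mask
  })
}

#' Insert a lesion mask into a phantom
#'
#' Places the lesion so that its center of mass lies within `0.3 * l` of the
#' ultrasound imaging plane y = 0, where `l` is the mask's maximum y-extent,
#' and so that the lesion overwrites only breast interior tissue (never air
#' or skin). Voxels outside the mask are unchanged.
#'
#' @param volume a [label_volume()]
#' @param mask logical 3D array from [generate_lesion_shape()] on the same
#'   spacing
#' @param rng_seed integer seed for the placement draw
#' @param max_tries bounded number of placement attempts
#' @param center_bounds optional list with `x` and/or `z` ranges (mm, probe
#'   frame) constraining the lesion center of mass; models the operator
#'   centering the probe over the lesion before acquisition
#' @return the volume with lesion voxels labeled
#' @export
insert_lesion <- function(volume, mask, rng_seed = 1L, max_tries = 200L,
                          center_bounds = NULL) {
  h <- volume$spacing
  msp <- attr(mask, "spacing")
  if (!is.null(msp) && abs(msp - h) > 1e-9)
    stop("mask spacing does not match volume spacing")
  tis <- volume$tissues
  interior_ok <- !(volume$labels %in% c(tis[["air"]], tis[["skin"]]))
  dim(interior_ok) <- dim(volume$labels)
  if (!any(interior_ok)) stop("no breast interior available for placement")
  md <- dim(mask)
  vd <- dim(volume$labels)
  if (any(md > vd)) stop("lesion mask larger than the phantom domain")
  idx <- which(mask, arr.ind = TRUE)
  com_vox <- colMeans(idx)                       # mask-local center of mass
  l_mm <- (diff(range(idx[, 2])) + 1) * h        # max y elongation, mm
  # admissible integer offsets per axis: the mask must fit in the grid and
  # the center of mass must satisfy the imaging-plane (and optional probe)
  # constraints; sample uniformly from the feasible set, rejecting only on
  # tissue overlap
  feasible <- function(axis, lim = NULL) {
    offs <- 0:(vd[axis] - md[axis])
    ci <- pmin(pmax(round(offs + com_vox[axis]), 1), vd[axis])
    centers <- voxel_centers(volume, axis)[ci]
    keep <- rep(TRUE, length(offs))
    if (axis == 2) keep <- abs(centers) <= 0.3 * l_mm
    if (!is.null(lim)) keep <- keep & centers >= lim[1] & centers <= lim[2]
    offs[keep]
  }
  ox <- feasible(1, center_bounds$x)
  oy <- feasible(2)
  oz <- feasible(3, center_bounds$z)
  if (length(ox) == 0 || length(oy) == 0 || length(oz) == 0)
    stop("no admissible lesion placement: constraints leave an empty feasible set")
  with_seed(rng_seed, {
    for (try in seq_len(max_tries)) {
      off <- c(sample(ox, 1), sample(oy, 1), sample(oz, 1))
      target <- idx
      target[, 1] <- target[, 1] + off[1]
      target[, 2] <- target[, 2] + off[2]
      target[, 3] <- target[, 3] + off[3]
      lin <- target[, 1] + vd[1] * (target[, 2] - 1 + vd[2] * (target[, 3] - 1))
      if (all(interior_ok[lin])) {
        labels <- volume$labels
        labels[lin] <- tis[["lesion"]]
        out <- volume
        out$labels <- labels
        return(out)
      }
    }
    stop("no admissible lesion placement found after ", max_tries, " tries")
  })
}

#' Compress a phantom to a target slab thickness
#'
#' Volume-preserving anisotropic affine rescale standing in for mechanical
#' compression: the breast extent along z is scaled to `target_thickness`
#' and both lateral axes are dilated by `1/sqrt(scale)` so that the total
#' tissue volume is conserved (up to digitization). Labels are resampled by
#' nearest neighbor, so the tissue label set is preserved.
#'
#' @param volume a [label_volume()]
#' @param target_thickness mm
#' @return the compressed [label_volume()] (same spacing, resized grid)
#' @export
compress_phantom <- function(volume, target_thickness) {
  h <- volume$spacing
  nz_any <- apply(breast_mask(volume), 3, any)
  thick <- sum(nz_any) * h
  if (thick <= target_thickness + h / 2) {
    warning("breast already at or below target thickness; no-op")
    return(volume)
  }
  s <- target_thickness / thick
  lat <- 1 / sqrt(s)
  d <- dim(volume$labels)
  nd <- c(round(d[1] * lat), round(d[2] * lat), round(target_thickness / h))
  # output voxel centers mapped back into input voxel indices
  ix <- pmin(pmax(round((seq_len(nd[1]) - 0.5) / lat + 0.5), 1L), d[1])
  iy <- pmin(pmax(round((seq_len(nd[2]) - 0.5) / lat + 0.5), 1L), d[2])
  iz <- pmin(pmax(round((seq_len(nd[3]) - 0.5) / s + 0.5), 1L), d[3])
  labels <- volume$labels[ix, iy, iz, drop = FALSE]
  out <- label_volume(labels, spacing = h, tissues = volume$tissues)
  out
}

#' Downsample a label volume by majority vote
#'
#' Each coarse voxel takes the majority fine label. Coarse voxels whose
#' majority is air are reassigned to adipose or glandular tissue, whichever
#' is prevalent in the remainder of the breast (matching the optical-domain
#' convention that the computational cuboid is fully tissue-filled).
#'
#' @param volume a [label_volume()]
#' @param factor integer downsampling factor; the grid is padded with air to
#'   a multiple of `factor`
#' @return a [label_volume()] at `factor * spacing`
#' @export
downsample_labels <- function(volume, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(volume)
  tis <- volume$tissues
  d <- dim(volume$labels)
  pad <- (factor - d %% factor) %% factor
  labels <- volume$labels
  if (any(pad > 0)) {
    nd <- d + pad
    padded <- array(tis[["air"]], nd)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- labels
    labels <- padded
    d <- nd
  }
  cd <- d %/% factor
  vals <- sort(unique(as.vector(labels)))
  counts <- array(0L, c(cd, length(vals)))
  for (vi in seq_along(vals)) {
    m <- array(as.integer(labels == vals[vi]), d)
    # block sum via two reshapes per axis
    m <- apply_block_sum(m, factor)
    counts[, , , vi] <- m
  }
  maj <- apply(counts, 1:3, which.max)
  coarse <- array(vals[maj], cd)
  # air-majority voxels -> prevalent of adipose/glandular in the breast
  air_major <- coarse == tis[["air"]]
  if (any(air_major)) {
    n_ad <- sum(volume$labels == tis[["adipose"]])
    n_gl <- sum(volume$labels == tis[["glandular"]])
    fill <- if (n_gl > n_ad) tis[["glandular"]] else tis[["adipose"]]
    coarse[air_major] <- fill
  }
  label_volume(coarse, spacing = volume$spacing * factor,
               origin = volume$origin, tissues = volume$tissues)
}

# Sum of f x f x f blocks of a 3D integer/numeric array whose dims are
# multiples of f.
apply_block_sum <- function(x, f) {
  d <- dim(x)
  cd <- d %/% f
  dim(x) <- c(f, cd[1], f, cd[2], f, cd[3])
  x <- colSums(x)                        # (c1, f, c2, f, c3)
  x <- colSums(aperm(x, c(2, 1, 3, 4, 5)))   # (c1, c2, f, c3)
  x <- colSums(aperm(x, c(3, 1, 2, 4)))      # (c1, c2, c3)
  x
}
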