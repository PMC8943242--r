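#' Registered tissue indices
#'
#' The canonical index -> tissue map used by the phantom generator. Index 0
#' is reserved for air; the lesion always carries the highest index.
#'
#' @return named integer vector mapping tissue name to label index
#' @export
tissue_registry <- function() {
  c(air = 0L, adipose = 1L, glandular = 2L, skin = 3L, muscle = 4L,
    duct = 5L, TDLU = 6L, ligament = 7L, artery = 8L, vein = 9L,
    nipple = 10L, lesion = 11L)
}

#' Voxelized tissue-label volume
#'
#' Container for a breast digital phantom: a 3D integer grid of tissue
#' indices with isotropic voxel spacing and an origin in the probe frame.
#' The probe frame has z = 0 at the top (probe) surface with z increasing
#' into the tissue, and y = 0 the ultrasound imaging plane. Voxel centers
#' sit at `(index - 1 + 0.5) * spacing + origin` per axis (1-based R
#' indices).
#'
#' @param labels 3D integer array of tissue indices
#' @param spacing voxel edge length, mm (isotropic, > 0)
#' @param origin length-3 numeric, mm offset of the grid corner
#' @param tissues named integer vector registering the tissue indices
#' @return an object of class `label_volume`
#' @export
label_volume <- function(labels, spacing, origin = NULL,
                         tissues = tissue_registry()) {
  stopifnot(length(dim(labels)) == 3, spacing > 0)
  storage.mode(labels) <- "integer"
  if (is.null(origin)) {
    d <- dim(labels)
    origin <- c(-d[1] * spacing / 2, -d[2] * spacing / 2, 0)
  }
  stopifnot(length(origin) == 3)
  bad <- setdiff(unique(as.vector(labels)), unname(tissues))
  if (length(bad) > 0)
    stop("unregistered tissue indices present: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = spacing, origin = as.numeric(origin),
                 tissues = tissues),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("<label_volume> ", paste(d, collapse = " x "), " voxels @ ",
      x$spacing, " mm (", paste(round(d * x$spacing, 1), collapse = " x "),
      " mm)\n", sep = "")
  tab <- table(factor(as.vector(x$labels), levels = unname(x$tissues),
                      labels = names(x$tissues)))
  present <- tab[tab > 0]
  cat("  tissues: ", paste(names(present), present, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Physical voxel-center coordinates along one axis
#' @param volume a `label_volume` (or any list with labels/spacing/origin)
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-center coordinates, mm
#' @export
voxel_centers <- function(volume, axis) {
  n <- dim(volume$labels)[axis]
  (seq_len(n) - 0.5) * volume$spacing + volume$origin[axis]
}

#' Write / read a label volume as NIfTI with a YAML sidecar
#'
#' The labels are stored as an int16 NIfTI image (`<path>.nii.gz`) and the
#' spacing, origin and tissue table in `<path>.yaml`.
#'
#' @param volume a `label_volume`
#' @param path file path stem (extensions appended)
#' @return `write_volume` returns `path` invisibly; `read_volume` the volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels,
                         pixdim = rep(volume$spacing, 3), datatype = "int16")
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  yaml::write_yaml(list(spacing_mm = volume$spacing,
                        origin_mm = as.list(volume$origin),
                        tissues = as.list(volume$tissues)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  labels <- array(as.integer(img), dim = dim(img))
  label_volume(labels, spacing = meta$spacing_mm,
               origin = unlist(meta$origin_mm),
               tissues = unlist(meta$tissues))
}

# Breast (non-air) voxel mask
breast_mask <- function(volume) volume$labels != volume$tissues[["air"]]

# ---- small 3D morphology helpers used across modules -----------------------

# Shift a logical/numeric 3D array by one voxel along an axis, zero-filled.
shift3 <- function(x, axis, by) {
  d <- dim(x)
  out <- array(if (is.logical(x)) FALSE else 0, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n
  }
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(x), idx_src)))))
}

# 6-neighbour dilation / erosion of a logical 3D mask.
dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) out <- out | shift3(m, ax, 1L) | shift3(m, ax, -1L)
  out
}
erode6 <- function(m) !dilate6(!m)

# Largest 6-connected component of a logical 3D mask.
largest_component6 <- function(m) {
  if (!any(m)) return(m)
  remaining <- m
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(m))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate6(seed) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) { best <- seed; best_n <- n }
    remaining <- remaining & !seed
    if (best_n >= sum(remaining)) break  # no remaining component can be larger
  }
  best
}

# Number of 6-connected components (used by invariants/tests).
n_components6 <- function(m) {
  k <- 0L
  remaining <- m
  while (any(remaining)) {
    seed <- array(FALSE, dim(m))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate6(seed) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    remaining <- remaining & !seed
    k <- k + 1L
  }
  k
}

# Separable Gaussian smoothing of a 3D array (reflected edges).
smooth3_gauss <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2)); k <- k / sum(k)
  for (ax in 1:3) {
    acc <- x * k[r + 1]
    for (s in seq_len(r)) {
      acc <- acc + k[r + 1 + s] * shift3_reflect(x, ax, s) +
        k[r + 1 - s] * shift3_reflect(x, ax, -s)
    }
    x <- acc
  }
  x
}

shift3_reflect <- function(x, axis, by) {
  d <- dim(x); n <- d[axis]
  if (n == 1) return(x)
  i0 <- (seq_len(n) - 1) - by
  period <- 2 * n - 2
  m <- ((i0 %% period) + period) %% period
  src <- ifelse(m < n, m, period - m) + 1
  idx <- lapply(d, seq_len)
  idx[[axis]] <- src
  do.call(`[`, c(list(x), idx))
}
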