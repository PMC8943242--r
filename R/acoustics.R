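#' Default per-tissue acoustic parameters
#'
#' Mean speed of sound (m/s), between-phantom spread (`sigma_macro`, m/s)
#' and within-tissue texture level (`sigma_micro`). Adipose, glandular and
#' lesion speeds follow the common soft-tissue convention (adipose around
#' 1470 m/s, glandular around 1515 m/s, lesions around 1550 m/s); the
#' remaining tissues share the glandular distribution. `sigma_micro = "auto"`
#' draws the texture level uniformly between 1% and 5% of the tissue's mean
#' speed; the lesion texture is fixed at 0.5% so that it is strictly below
#' every surrounding tissue's, reproducing the lower echogenicity of masses
#' in B-mode images.
#'
#' @return data frame with columns tissue, mu, sigma_macro, sigma_micro
#' @export
acoustic_params <- function() {
  tis <- names(tissue_registry())
  mu <- c(air = 343, adipose = 1470, glandular = 1515, skin = 1615,
          muscle = 1580, duct = 1515, TDLU = 1515, ligament = 1515,
          artery = 1570, vein = 1570, nipple = 1615, lesion = 1550)
  sig_mac <- c(air = 0, adipose = 30, glandular = 25, skin = 25, muscle = 25,
               duct = 25, TDLU = 25, ligament = 25, artery = 25, vein = 25,
               nipple = 25, lesion = 25)
  data.frame(tissue = tis, mu = unname(mu[tis]),
             sigma_macro = unname(sig_mac[tis]),
             sigma_micro = "auto", stringsAsFactors = FALSE)
}

#' Assign a dual-scale stochastic speed-of-sound field
#'
#' For each tissue i one mean speed `vbar_i ~ N(mu_i, sigma_macro_i)` is
#' drawn (the macroscopic, between-phantom scale), and every voxel of that
#' tissue receives `vbar_i` plus zero-mean Gaussian texture of standard
#' deviation `sigma_micro_i` (the microscopic, within-tissue scale). The
#' texture is a white (voxelwise independent) Gaussian field by default; a
#' correlated option smooths the texture with a Gaussian kernel and rescales
#' it back to the requested standard deviation.
#'
#' @param volume a [label_volume()]
#' @param params data frame as from [acoustic_params()]
#' @param rng_seed integer seed
#' @param correlation_length mm; 0 (default) keeps the white field
#' @return an `acoustic_map`: list with `vbar` (per-tissue means, m/s),
#'   `vs_field` and `sigma_micro_field` (3D grids, m/s), `spacing`
#' @export
assign_acoustic_properties <- function(volume, params = acoustic_params(),
                                       rng_seed = 1L, correlation_length = 0) {
  labs <- volume$labels
  present <- sort(unique(as.vector(labs)))
  tis <- volume$tissues
  pnames <- names(tis)[match(present, tis)]
  missing <- pnames[!pnames %in% params$tissue]
  if (length(missing) > 0)
    stop("missing acoustic params for tissue(s): ", paste(missing, collapse = ", "))
  with_seed(rng_seed, {
    row <- params[match(pnames, params$tissue), ]
    vbar <- rnorm(nrow(row), row$mu, row$sigma_macro)
    names(vbar) <- pnames
    smicro <- vapply(seq_len(nrow(row)), function(i) {
      sm <- row$sigma_micro[i]
      if (identical(sm, "auto")) {
        if (pnames[i] == "lesion") 0.005 * row$mu[i]
        else if (pnames[i] == "air") 0
        else runif(1, 0.01, 0.05) * row$mu[i]
      } else as.numeric(sm)
    }, numeric(1))
    names(smicro) <- pnames
    code <- match(as.vector(labs), present)
    sig_field <- array(smicro[code], dim(labs))
    noise <- array(rnorm(length(labs)), dim(labs))
    if (correlation_length > 0) {
      noise <- smooth3_gauss(noise, correlation_length / volume$spacing)
      noise <- noise / sd(noise)
    }
    vs <- array(vbar[code], dim(labs)) + noise * sig_field
    structure(list(vbar = vbar, vs_field = vs, sigma_micro_field = sig_field,
                   spacing = volume$spacing, density = 1000),
              class = "acoustic_map")
  })
}

#' Transducer parameters of the emulated linear probe
#'
#' The companion configuration shipped alongside an exported wave-simulation
#' medium: a 7 MHz, 256-element linear array with 0.2 mm pitch and a
#' 1465 m/s beamforming reference speed. The mismatch between this reference
#' and the true lesion speed is the documented mechanism behind the
#' systematic size underestimation of ultrasound-derived priors.
#'
#' @return named list of transducer parameters
#' @export
transducer_config <- function() {
  list(fc_hz = 7e6, focus_mm = 15, elevation_focus_mm = 16,
       fractional_bandwidth = 0.8, n_elements = 256L, height_mm = 4,
       pitch_mm = 0.2, kerf_mm = 0.001, width_mm = 0.198,
       scan_lines = 200L, vs0_m_per_s = 1465)
}

#' Export / import a medium for an external wave simulator
#'
#' Writes the sound-speed and (constant) density grids as NIfTI images and a
#' YAML companion holding the transducer parameters and the grid spacing in
#' meters (with an explicit unit attribute). The round trip is lossless to
#' float precision.
#'
#' @param map an `acoustic_map` from [assign_acoustic_properties()]
#' @param path file path stem
#' @return `export_wave_medium` returns `path` invisibly;
#'   `read_wave_medium` the re-imported map
#' @export
export_wave_medium <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$vs_field,
                                     pixdim = rep(map$spacing, 3)),
                     paste0(path, "_sound_speed.nii.gz"))
  dens <- array(map$density, dim(map$vs_field))
  RNifti::writeNifti(RNifti::asNifti(dens, pixdim = rep(map$spacing, 3)),
                     paste0(path, "_density.nii.gz"))
  yaml::write_yaml(list(transducer = transducer_config(),
                        grid = list(spacing = map$spacing * 1e-3, unit = "m"),
                        density_kg_m3 = map$density,
                        vbar_m_per_s = as.list(map$vbar)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname export_wave_medium
#' @export
read_wave_medium <- function(path) {
  vs <- RNifti::readNifti(paste0(path, "_sound_speed.nii.gz"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  structure(list(vbar = unlist(meta$vbar_m_per_s),
                 vs_field = array(as.numeric(vs), dim(vs)),
                 sigma_micro_field = NULL,
                 spacing = meta$grid$spacing * 1e3,
                 density = meta$density_kg_m3,
                 transducer = meta$transducer),
            class = "acoustic_map")
}
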