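#' Study configuration
#'
#' Bundles every knob of an end-to-end study: phantom generation,
#' simulation, reconstruction and classification. Physical defaults follow
#' the full-scale study conditions (0.5 mm anatomical / 2 mm optical grid,
#' 45 mm compressed slab, 64 x 58 x 30 mm optical cuboid, 25 ps x 400
#' steps, lesion radii 6-13.5 mm, photon budget 1e6 at the largest
#' separation, eight wavelengths); `n_phantoms` and the grid/time
#' resolution can be scaled down for desk-scale experiments.
#'
#' @param n_phantoms number of phantoms
#' @param class_mix named fractions for benign/malignant/cyst lesions; must
#'   sum to 1. With `cyst = 0` (default) cysts still arise as the benign
#'   cyst branch (25% of benign draws)
#' @param prior_modes subset of c("ground_truth", "degraded")
#' @param wavelengths nm (default the canonical eight)
#' @param Nexpect photon budget at the largest source-detector separation
#' @param seed base seed; all per-phantom seeds derive from it
#' @param fine_spacing,coarse_spacing mm
#' @param domain_size mm, generated (pre-compression) domain
#' @param target_thickness mm compressed slab
#' @param optical_depth mm, z-extent of the optical cuboid
#' @param dt,n_steps time grid, ps
#' @param radius_range mm, lesion mean-radius range
#' @param ntw,min_distance preprocessing settings
#' @param fit_control control list for the two-region optimizer
#' @param out_dir optional directory for stage persistence/resumption
#' @return a `study_config` list
#' @export
study_config <- function(n_phantoms = 20L,
                         class_mix = c(benign = 0.479, malignant = 0.521,
                                       cyst = 0),
                         prior_modes = c("ground_truth", "degraded"),
                         wavelengths = c(635, 670, 685, 785, 905, 930, 975, 1060),
                         Nexpect = 1e6, seed = 1L,
                         fine_spacing = 0.5, coarse_spacing = 2,
                         domain_size = c(64, 58, 60), target_thickness = 45,
                         optical_depth = 30, dt = 25, n_steps = 400L,
                         radius_range = c(6, 13.5), ntw = 80L,
                         min_distance = 27,
                         fit_control = list(maxiter = 100, ftol = 1e-6,
                                            ptol = 1e-4),
                         out_dir = NULL) {
  if (is.null(names(class_mix))) names(class_mix) <- c("benign", "malignant", "cyst")
  class_mix <- class_mix[c("benign", "malignant", "cyst")]
  class_mix[is.na(class_mix)] <- 0
  names(class_mix) <- c("benign", "malignant", "cyst")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix fractions must sum to 1")
  prior_modes <- match.arg(prior_modes, several.ok = TRUE)
  structure(as.list(environment()), class = "study_config")
}

# Deterministic class allocation honouring the mix at small n.
allocate_classes <- function(n, mix, seed) {
  counts <- floor(n * mix)
  while (sum(counts) < n) {
    frac <- n * mix - counts
    counts[which.max(frac)] <- counts[which.max(frac)] + 1
  }
  classes <- rep(names(mix), counts)
  with_seed(seed, sample(classes))
}

#' Sample a ground-truth lesion population
#'
#' Draws `n` lesions from the class-conditional optical distributions
#' (chromophore concentrations -> absorption; power-law amplitude/slope
#' plus fractional spectral noise -> reduced scattering) without any
#' phantom or reconstruction step. This is the population whose 16-feature
#' table the ground-truth classification operates on.
#'
#' @param n number of lesions
#' @param class_mix as in [study_config()]
#' @param seed base seed
#' @param compositions,panel model tables
#' @param cyst_prob cyst branch probability among benign draws when the
#'   mix does not allocate cysts explicitly
#' @return list with `mua` and `musp` (n x 8 matrices), `class`
#'   (benign/malignant/cyst), `label` (benign/malignant)
#' @export
generate_lesion_population <- function(n, class_mix = c(benign = 0.479,
                                                        malignant = 0.521,
                                                        cyst = 0),
                                       seed = 1L,
                                       compositions = tissue_compositions(),
                                       panel = chromophore_panel(),
                                       cyst_prob = 0.25) {
  classes <- allocate_classes(n, class_mix, derive_seed(seed, 0L, 11L))
  wl <- panel$wavelengths
  mua <- matrix(0, n, length(wl))
  musp <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    with_seed(derive_seed(seed, i, 13L), {
      if (classes[i] == "benign" && runif(1) < cyst_prob)
        classes[i] <- "cyst"
      rowc <- compositions[compositions$tissue == paste0("lesion_", classes[i]), ]
      cc <- draw_composition(rowc)
      mua[i, ] <- mua_from_chromophores(cc$C, panel)
      musp[i, ] <- musp_power_law(cc$a, cc$b, wl, noise_sd_frac = 0.1)
    })
  }
  list(mua = mua, musp = musp, class = classes,
       label = ifelse(classes == "malignant", "malignant", "benign"))
}

# Crop a volume to a centered x/y window and the top `depth_mm` of z.
crop_volume <- function(volume, size_xy_mm, depth_mm) {
  h <- volume$spacing
  d <- dim(volume$labels)
  nx <- min(round(size_xy_mm[1] / h), d[1])
  ny <- min(round(size_xy_mm[2] / h), d[2])
  nz <- min(round(depth_mm / h), d[3])
  x0 <- floor((d[1] - nx) / 2); y0 <- floor((d[2] - ny) / 2)
  labels <- volume$labels[x0 + seq_len(nx), y0 + seq_len(ny), seq_len(nz),
                          drop = FALSE]
  label_volume(labels, spacing = h, tissues = volume$tissues)
}

simulate_one_phantom <- function(cfg, i, class_i) {
  seed_i <- derive_seed(cfg$seed, i, 23L)
  pcfg <- phantom_config(fat_fraction = with_seed(derive_seed(seed_i, 1L, 2L),
                                                  runif(1, 0.4, 0.9)),
                         target_thickness = cfg$target_thickness,
                         domain_size = cfg$domain_size,
                         fine_spacing = cfg$fine_spacing,
                         coarse_spacing = cfg$coarse_spacing)
  vol <- generate_phantom(pcfg, derive_seed(seed_i, 2L, 2L))
  vol <- suppressWarnings(compress_phantom(vol, cfg$target_thickness))
  radius <- with_seed(derive_seed(seed_i, 3L, 2L),
                      runif(1, cfg$radius_range[1], cfg$radius_range[2]))
  shape <- generate_lesion_shape(
    lesion_spec(mean_radius = radius, irregularity = 0.3,
                malignancy_class = if (class_i == "malignant") "malignant"
                                   else "benign",
                rng_seed = derive_seed(seed_i, 4L, 2L)),
    spacing = cfg$fine_spacing)
  # lesion inserted in the compressed slab (it may extend below the optical
  # cuboid, which only sees its upper part), centered under the probe
  vol <- insert_lesion(vol, shape, rng_seed = derive_seed(seed_i, 5L, 2L),
                       max_tries = 500L,
                       center_bounds = list(x = c(-10, 10), z = c(8, 22)))
  vol <- crop_volume(vol, cfg$domain_size[1:2], cfg$optical_depth)
  factor <- as.integer(round(cfg$coarse_spacing / cfg$fine_spacing))
  coarse <- downsample_labels(vol, factor)
  if (!any(coarse$labels == coarse$tissues[["lesion"]]))
    stop("lesion vanished on the optical grid")
  optics <- assign_optical_properties(coarse, lesion_class = class_i,
                                      panel = chromophore_panel(cfg$wavelengths),
                                      rng_seed = derive_seed(seed_i, 6L, 2L))
  tg <- time_grid(dt = cfg$dt, n_steps = cfg$n_steps)
  irf <- gaussian_irf(tg)
  geom <- probe_geometry()
  ms <- simulate_measurements(optics, geom, tg, irf)
  ms <- apply_noise(ms, cfg$Nexpect, derive_seed(seed_i, 7L, 2L))
  gt_prior <- lesion_prior(coarse)
  priors <- list(ground_truth = gt_prior)
  if ("degraded" %in% cfg$prior_modes)
    priors$degraded <- degrade_prior(gt_prior,
                                     rng_seed = derive_seed(seed_i, 8L, 2L))
  list(seed = seed_i, class = optics$lesion_class, volume_coarse = coarse,
       optics = optics, ms = ms, priors = priors)
}

fit_one_phantom <- function(cfg, sim) {
  nwl <- length(cfg$wavelengths)
  fits <- list()
  for (mode in cfg$prior_modes)
    fits[[mode]] <- list(mua = numeric(nwl), musp = numeric(nwl),
                         converged = logical(nwl), iterations = integer(nwl))
  prev <- list()
  for (k in seq_len(nwl)) {
    hom <- fit_homogeneous(sim$ms, k, ntw = cfg$ntw,
                           min_distance = cfg$min_distance)
    for (mode in cfg$prior_modes) {
      init <- c(mua_in = hom$mua, mua_bulk = hom$mua, musp_in = hom$musp,
                musp_bulk = hom$musp, tshift = 0)
      # chain the inclusion/bulk contrast from the previous wavelength's
      # solution: adjacent wavelengths have similar contrasts, which saves
      # optimizer iterations
      if (!is.null(prev[[mode]])) {
        p <- prev[[mode]]
        init[["mua_in"]] <- max(hom$mua * p[["mua_in"]] / max(p[["mua_bulk"]], 1e-6),
                                1e-4)
        init[["musp_in"]] <- max(hom$musp * p[["musp_in"]] / max(p[["musp_bulk"]], 0.05),
                                 0.05)
        init[["tshift"]] <- p[["tshift"]]
      }
      fit <- fit_two_region(sim$ms, sim$priors[[mode]], k, init = init,
                            ntw = cfg$ntw, min_distance = cfg$min_distance,
                            control = cfg$fit_control)
      prev[[mode]] <- unclass(fit$params)
      fits[[mode]]$mua[k] <- fit$params[["mua_in"]]
      fits[[mode]]$musp[k] <- fit$params[["musp_in"]]
      fits[[mode]]$converged[k] <- fit$converged
      fits[[mode]]$iterations[k] <- fit$iterations
    }
  }
  fits
}

#' Run an end-to-end study
#'
#' For each phantom: generate the anatomy, compress, embed a lesion,
#' assign acoustic-free optical ground truth, simulate noisy time-resolved
#' data at all wavelengths, build the ground-truth and degraded priors,
#' fit the two-region model per wavelength for each prior mode, and
#' collect ground-truth and reconstructed feature tables. Classification
#' reports (logistic regression, SVM, network) are produced for every
#' provenance. Per-phantom failures are recorded and the study continues.
#' With `out_dir` set, per-phantom stage outputs are content-addressed by
#' the configuration hash and reloaded on rerun.
#'
#' @param config a [study_config()]
#' @param classify logical: run the classifiers (default TRUE)
#' @return a `usdot_study`: list with `features` (per provenance),
#'   `reports`, `errors` (relative per-wavelength coefficient errors per
#'   prior mode), `manifest`
#' @export
run_study <- function(config, classify = TRUE) {
  cfg <- config
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  classes <- allocate_classes(cfg$n_phantoms,
                              cfg$class_mix / sum(cfg$class_mix),
                              derive_seed(cfg$seed, 0L, 29L))
  n <- cfg$n_phantoms
  nwl <- length(cfg$wavelengths)
  gt_mua <- matrix(NA_real_, n, nwl); gt_musp <- matrix(NA_real_, n, nwl)
  rec <- lapply(cfg$prior_modes, function(m)
    list(mua = matrix(NA_real_, n, nwl), musp = matrix(NA_real_, n, nwl),
         converged = matrix(NA, n, nwl)))
  names(rec) <- cfg$prior_modes
  manifest <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    rec_file <- if (!is.null(cfg$out_dir))
      file.path(cfg$out_dir, sprintf("phantom_%s_%03d.rds", cfg_hash, i))
    else NULL
    result <- NULL
    if (!is.null(rec_file) && file.exists(rec_file))
      result <- readRDS(rec_file)
    if (is.null(result)) {
      result <- tryCatch({
        sim <- simulate_one_phantom(cfg, i, classes[i])
        fits <- fit_one_phantom(cfg, sim)
        list(ok = TRUE, class = sim$class,
             gt_mua = sim$optics$spectra$mua["lesion", ],
             gt_musp = sim$optics$spectra$musp["lesion", ],
             fits = fits,
             prior_metrics = if ("degraded" %in% names(sim$priors))
               geometry_metrics(sim$priors$degraded, sim$priors$ground_truth)
             else NULL,
             seed = sim$seed)
      }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
      if (!is.null(rec_file)) {
        dir.create(dirname(rec_file), showWarnings = FALSE, recursive = TRUE)
        saveRDS(result, rec_file)
      }
    }
    manifest[[i]] <- list(index = i, ok = result$ok,
                          class = if (result$ok) result$class else NA,
                          seed = if (result$ok) result$seed else NA,
                          error = if (!result$ok) result$error else NULL,
                          checksum = rlang::hash(result))
    if (result$ok) {
      labels[i] <- if (result$class == "malignant") "malignant" else "benign"
      gt_mua[i, ] <- result$gt_mua
      gt_musp[i, ] <- result$gt_musp
      for (mode in cfg$prior_modes) {
        rec[[mode]]$mua[i, ] <- result$fits[[mode]]$mua
        rec[[mode]]$musp[i, ] <- result$fits[[mode]]$musp
        rec[[mode]]$converged[i, ] <- result$fits[[mode]]$converged
      }
    }
  }
  ok <- vapply(manifest, function(m) isTRUE(m$ok), logical(1))
  features <- list(
    ground_truth = build_features(gt_mua[ok, , drop = FALSE],
                                  gt_musp[ok, , drop = FALSE], labels[ok],
                                  "ground_truth",
                                  wavelengths = cfg$wavelengths))
  errors <- list()
  prov_of_mode <- c(ground_truth = "recon_gt_prior", degraded = "recon_us_prior")
  for (mode in cfg$prior_modes) {
    features[[prov_of_mode[[mode]]]] <-
      build_features(rec[[mode]]$mua[ok, , drop = FALSE],
                     rec[[mode]]$musp[ok, , drop = FALSE], labels[ok],
                     prov_of_mode[[mode]], wavelengths = cfg$wavelengths)
    errors[[mode]] <- list(
      mua = (rec[[mode]]$mua[ok, , drop = FALSE] - gt_mua[ok, , drop = FALSE]) /
        gt_mua[ok, , drop = FALSE],
      musp = (rec[[mode]]$musp[ok, , drop = FALSE] - gt_musp[ok, , drop = FALSE]) /
        gt_musp[ok, , drop = FALSE])
  }
  reports <- NULL
  if (classify) {
    reports <- lapply(features, function(tab) {
      if (nlevels(droplevels(tab$label)) < 2) return(NULL)
      lapply(c(logreg = "logreg", svm = "svm", fcn = "fcn"), function(m)
        train_eval(tab, m, rng_seed = derive_seed(cfg$seed, 99L, 31L)))
    })
  }
  structure(list(features = features, reports = reports, errors = errors,
                 manifest = manifest, config_hash = cfg_hash, config = cfg),
            class = "usdot_study")
}
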