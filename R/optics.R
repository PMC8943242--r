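#' Bundled chromophore specific-absorption panel
#'
#' Specific absorption spectra \eqn{\epsilon_i(\lambda)} of the five
#' chromophores resolved by the eight probing wavelengths (635, 670, 685,
#' 785, 905, 930, 975, 1060 nm): deoxy- and oxy-hemoglobin in
#' mm^-1 per micromolar (natural-log convention folded in), and lipid,
#' water and collagen in mm^-1 per unit volume fraction. The table is a
#' fixture compiled to track the standard literature compilations at these
#' wavelengths (hemoglobin Q-band tail and near-infrared crossover, the
#' 930 nm lipid peak, the 975 nm water peak, the slow collagen rise toward
#' 1060 nm); users may override it with their own panel of the same shape.
#'
#' @param wavelengths optional subset of the eight canonical wavelengths, nm
#' @return a `chromophore_panel`: list with `wavelengths` (nm, increasing)
#'   and `epsilon` (5 x n matrix, rows Hb, HbO2, lipid, water, collagen)
#' @export
chromophore_panel <- function(wavelengths = NULL) {
  wl <- c(635, 670, 685, 785, 905, 930, 975, 1060)
  # molar extinction of hemoglobins (cm^-1 / M, base-10) converted to
  # mm^-1 / uM: eps_mm_uM = 2.303e-7 * eps_cm_M
  hb_cm   <- c(4300, 2800, 2300, 850, 750, 720, 650, 450)
  hbo2_cm <- c(320, 320, 350, 740, 1200, 1250, 1350, 1050)
  eps <- rbind(
    Hb       = 2.303e-7 * hb_cm,
    HbO2     = 2.303e-7 * hbo2_cm,
    lipid    = c(8e-5, 6e-5, 1e-4, 6e-4, 5.0e-3, 1.2e-2, 4e-3, 5e-3),
    water    = c(3.0e-4, 4.2e-4, 4.7e-4, 2.6e-3, 6.7e-3, 1.2e-2, 4.5e-2, 1.3e-2),
    collagen = c(2.0e-3, 2.0e-3, 2.0e-3, 3.0e-3, 5.0e-3, 6.0e-3, 6.0e-3, 1.0e-2))
  colnames(eps) <- wl
  if (!is.null(wavelengths)) {
    keep <- match(wavelengths, wl)
    if (anyNA(keep)) stop("panel is tabulated only at the canonical wavelengths")
    eps <- eps[, keep, drop = FALSE]
    wl <- wavelengths
  }
  if (is.unsorted(wl, strictly = TRUE)) stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wl, epsilon = eps), class = "chromophore_panel")
}

#' Absorption from chromophore concentrations
#'
#' Linear spectral model \eqn{\mu_a(\lambda) = \sum_i \epsilon_i(\lambda)
#' C_i}: homogeneous of degree one in the concentration vector.
#'
#' @param C named concentration vector aligned with the panel rows (Hb and
#'   HbO2 in micromolar, lipid/water/collagen as volume fractions)
#' @param panel a [chromophore_panel()]
#' @return numeric vector of mu_a per wavelength, mm^-1
#' @export
mua_from_chromophores <- function(C, panel = chromophore_panel()) {
  rows <- rownames(panel$epsilon)
  if (!all(rows %in% names(C)))
    stop("C must provide a concentration for every panel chromophore")
  C <- C[rows]
  if (any(C < 0)) stop("negative chromophore concentration")
  as.vector(C %*% panel$epsilon)
}

#' Reduced scattering from the power-law spectral model
#'
#' \eqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b} + \eta} with optional
#' multiplicative-scale Gaussian noise \eqn{\eta \sim N(0,
#' noise\_sd\_frac \cdot \mu_s'(\lambda))}; the result is clipped to a
#' 0.05 mm^-1 floor to keep the diffusion approximation valid.
#'
#' @param a scattering amplitude at `lambda0`, mm^-1 (> 0)
#' @param b scattering power, dimensionless
#' @param lambda wavelength(s), nm
#' @param lambda0 reference wavelength, nm (default 600)
#' @param noise_sd_frac fractional noise level (typical value 0.1); 0
#'   disables noise
#' @param rng_seed optional seed for the noise draw
#' @return mu_s' per wavelength, mm^-1
#' @export
musp_power_law <- function(a, b, lambda, lambda0 = 600, noise_sd_frac = 0,
                           rng_seed = NULL) {
  stopifnot(a > 0, all(lambda > 0), lambda0 > 0)
  base <- a * (lambda / lambda0)^(-b)
  if (noise_sd_frac > 0) {
    draw <- function() rnorm(length(base), 0, noise_sd_frac * base)
    eta <- if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
    base <- base + eta
  }
  pmax(base, 0.05)
}

#' Default per-tissue composition distributions
#'
#' Means and standard deviations of the chromophore concentrations (Hb,
#' HbO2 in micromolar; lipid, water, collagen as volume fractions) and of
#' the scattering parameters (a, b) for every registered tissue and the
#' three lesion classes. The lesion classes encode the malignancy contrast
#' the classifier must exploit: malignant lesions carry higher total
#' hemoglobin, water and collagen and lower lipid than benign ones; cysts
#' (a benign sub-class) are water-dominated with very low scattering
#' amplitude (`a ~ N(0.3, 0.01) mm^-1`). Benign lesions draw
#' `a ~ N(1.5, 0.25) mm^-1` and malignant `a ~ N(1.4, 0.25) mm^-1`. All
#' values are modeling choices of this package, kept in one table so they
#' can be overridden wholesale.
#'
#' @return data frame, one row per tissue/class, with `*_mean` / `*_sd`
#'   columns for hb, hbo2, lipid, water, collagen, a, b
#' @export
tissue_compositions <- function() {
  row <- function(tissue, hb, hbo2, lipid, water, collagen, a, b,
                  hb_sd = 0.1 * hb, hbo2_sd = 0.1 * hbo2,
                  lipid_sd = 0.1 * lipid, water_sd = 0.1 * water,
                  collagen_sd = 0.1 * collagen, a_sd = 0.1 * a, b_sd = 0.1 * b) {
    data.frame(tissue = tissue, hb_mean = hb, hb_sd = hb_sd,
               hbo2_mean = hbo2, hbo2_sd = hbo2_sd,
               lipid_mean = lipid, lipid_sd = lipid_sd,
               water_mean = water, water_sd = water_sd,
               collagen_mean = collagen, collagen_sd = collagen_sd,
               a_mean = a, a_sd = a_sd, b_mean = b, b_sd = b_sd,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("adipose",   2.4,  5.6, 0.60, 0.10, 0.02, 1.00, 0.60),
    row("glandular", 3.8, 11.2, 0.25, 0.30, 0.12, 1.20, 1.00),
    row("skin",      6.0, 14.0, 0.10, 0.35, 0.20, 1.80, 1.20),
    row("muscle",    8.0, 16.0, 0.05, 0.70, 0.10, 0.90, 0.80),
    row("duct",      3.8, 11.2, 0.20, 0.35, 0.12, 1.20, 1.00),
    row("TDLU",      3.8, 11.2, 0.20, 0.35, 0.12, 1.20, 1.00),
    row("ligament",  3.0,  8.0, 0.20, 0.30, 0.25, 1.40, 1.10),
    row("artery",   12.0, 588., 0.00, 0.80, 0.05, 1.20, 1.00,
        lipid_sd = 0, a_sd = 0.12, b_sd = 0.1),
    row("vein",    240.0, 360., 0.00, 0.80, 0.05, 1.20, 1.00,
        lipid_sd = 0, a_sd = 0.12, b_sd = 0.1),
    row("nipple",    6.0, 14.0, 0.10, 0.50, 0.25, 1.80, 1.20),
    row("lesion_benign",    5.0, 13.0, 0.40, 0.35, 0.12, 1.50, 1.00,
        hb_sd = 0.9, hbo2_sd = 2.3, lipid_sd = 0.07, water_sd = 0.05,
        collagen_sd = 0.02, a_sd = 0.25, b_sd = 0.15),
    row("lesion_malignant", 10.2, 21.8, 0.18, 0.55, 0.22, 1.40, 1.20,
        hb_sd = 1.4, hbo2_sd = 2.8, lipid_sd = 0.05, water_sd = 0.06,
        collagen_sd = 0.03, a_sd = 0.25, b_sd = 0.15),
    row("lesion_cyst",      1.5,  3.5, 0.02, 0.85, 0.02, 0.30, 0.80,
        hb_sd = 0.3, hbo2_sd = 0.7, lipid_sd = 0.01, water_sd = 0.05,
        collagen_sd = 0.01, a_sd = 0.01, b_sd = 0.10))
}

# Draw one composition (concentrations + scattering params) for a tissue row.
draw_composition <- function(row) {
  draw <- function(m, s) max(rnorm(1, m, s), 0)
  list(C = c(Hb = draw(row$hb_mean, row$hb_sd),
             HbO2 = draw(row$hbo2_mean, row$hbo2_sd),
             lipid = draw(row$lipid_mean, row$lipid_sd),
             water = draw(row$water_mean, row$water_sd),
             collagen = draw(row$collagen_mean, row$collagen_sd)),
       a = max(rnorm(1, row$a_mean, row$a_sd), 0.05),
       b = rnorm(1, row$b_mean, row$b_sd))
}

#' Assign per-wavelength optical property maps to a phantom
#'
#' Draws one chromophore composition and one scattering parameter pair per
#' tissue (no spatial variation of the optical coefficients inside a
#' tissue), applies the spectral model to obtain \eqn{\mu_a(\lambda)} and
#' \eqn{\mu_s'(\lambda)}, and paints the voxel maps. The lesion scattering
#' amplitude is drawn from its class-conditional normal; when
#' `lesion_class = "benign"` the draw is replaced by the cyst branch with
#' probability `cyst_prob`. Scattering receives the fractional spectral
#' noise term per wavelength.
#'
#' @param volume a [label_volume()] (typically the coarse optical grid)
#' @param compositions data frame as [tissue_compositions()]
#' @param panel a [chromophore_panel()]
#' @param lesion_class "benign", "malignant" or "cyst"
#' @param rng_seed integer seed
#' @param cyst_prob probability that a benign lesion is a cyst (default 0.25)
#' @param lambda0 scattering reference wavelength, nm
#' @param musp_noise_frac fractional scattering noise (default 0.1)
#' @param n_refr refractive index (default 1.4)
#' @return an `optical_maps` object: list with `wavelengths`, `mua` and
#'   `musp` (lists of 3D arrays, mm^-1), `n`, `spacing`, plus the per-tissue
#'   ground-truth spectra in `$spectra` and the realized lesion class in
#'   `$lesion_class`
#' @export
assign_optical_properties <- function(volume, compositions = tissue_compositions(),
                                      panel = chromophore_panel(),
                                      lesion_class = "benign", rng_seed = 1L,
                                      cyst_prob = 0.25, lambda0 = 600,
                                      musp_noise_frac = 0.1, n_refr = 1.4) {
  labs <- volume$labels
  tis <- volume$tissues
  present <- sort(unique(as.vector(labs)))
  pnames <- names(tis)[match(present, tis)]
  wl <- panel$wavelengths
  with_seed(rng_seed, {
    realized_class <- lesion_class
    if (lesion_class == "benign" && runif(1) < cyst_prob)
      realized_class <- "cyst"
    mua_tab <- matrix(0, length(present), length(wl),
                      dimnames = list(pnames, wl))
    musp_tab <- mua_tab
    for (i in seq_along(pnames)) {
      nm <- pnames[i]
      comp_name <- if (nm == "lesion") paste0("lesion_", realized_class) else nm
      if (nm == "air") comp_name <- "adipose"  # optical cuboid is tissue-filled
      rowc <- compositions[compositions$tissue == comp_name, ]
      if (nrow(rowc) != 1) stop("missing composition for tissue: ", comp_name)
      cc <- draw_composition(rowc)
      mua_tab[i, ] <- mua_from_chromophores(cc$C, panel)
      musp_tab[i, ] <- musp_power_law(cc$a, cc$b, wl, lambda0,
                                      noise_sd_frac = musp_noise_frac)
    }
    code <- match(as.vector(labs), present)
    mua <- lapply(seq_along(wl), function(k) array(mua_tab[code, k], dim(labs)))
    musp <- lapply(seq_along(wl), function(k) array(musp_tab[code, k], dim(labs)))
    names(mua) <- names(musp) <- wl
    structure(list(wavelengths = wl, mua = mua, musp = musp, n = n_refr,
                   spacing = volume$spacing, origin = volume$origin,
                   spectra = list(mua = mua_tab, musp = musp_tab),
                   lesion_class = realized_class),
              class = "optical_maps")
  })
}
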