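#' Select the temporal region of interest of a TPSF
#'
#' The ROI runs from the first sample at or above `high_frac` of the peak
#' to the last sample at or above `low_frac` of the peak. Thresholds are
#' peak-relative, so the ROI is invariant to positive rescaling of the
#' curve. Crossings are resolved at sample level (no sub-sample
#' interpolation).
#'
#' @param x a `tpsf` (or list with `times`, `counts`)
#' @param high_frac leading threshold (default 0.1 of peak)
#' @param low_frac trailing threshold (default 0.01 of peak)
#' @return numeric `c(T1, TN)`, ps
#' @export
select_roi <- function(x, high_frac = 0.1, low_frac = 0.01) {
  y <- x$counts
  pk <- max(y)
  if (!(pk > 0)) stop("degenerate curve: no positive peak")
  i1 <- which(y >= high_frac * pk)[1]
  iN <- tail(which(y >= low_frac * pk), 1)
  t1 <- x$times[i1]; tN <- x$times[iN]
  if (!(t1 < tN)) stop("degenerate curve: ROI collapses to a point")
  c(t1, tN)
}

#' Bin and self-normalize a TPSF over its ROI
#'
#' Implements the preprocessing operator P_k: `ntw` equal-width bins span
#' the ROI, each bin value is the trapezoidal integral of the curve over
#' the bin divided by the sum of all bin integrals, so the binned curve has
#' unit mass and is invariant to positive rescaling of the input.
#'
#' @param x a `tpsf`
#' @param roi `c(T1, TN)` from [select_roi()] (computed if NULL)
#' @param ntw number of time windows (default 80)
#' @return a `binned_curve`: list with `edges` (ntw + 1 times), `p`
#'   (normalized bin values), `raw` (bin integrals, counts),
#'   `total_counts` (ROI mass), `sigma2` (Poisson weights)
#' @export
bin_normalize <- function(x, roi = NULL, ntw = 80L) {
  if (is.null(roi)) roi <- select_roi(x)
  edges <- seq(roi[1], roi[2], length.out = ntw + 1)
  raw <- diff(cumtrapz_at(x$times, x$counts, edges))
  total <- sum(raw)
  if (!(total > 0)) stop("all-zero ROI mass")
  out <- structure(list(edges = edges, p = raw / total, raw = raw,
                        total_counts = total, source = x$source,
                        detector = x$detector, wavelength = x$wavelength),
                   class = "binned_curve")
  out$sigma2 <- poisson_weights(out)
  out
}

#' Poisson-motivated weights for the binned misfit
#'
#' Under Poisson counting noise the variance of a normalized bin value is
#' `sigma2_k = p_k / N` with `N` the total ROI counts. Zero-count bins
#' receive a `1 / N^2` floor so the weighted misfit stays finite.
#'
#' @param binned a `binned_curve`
#' @return numeric vector of per-bin variances
#' @export
poisson_weights <- function(binned) {
  total <- binned$total_counts
  if (!(total > 0)) stop("zero total counts")
  s2 <- binned$p / total
  s2[s2 <= 0] <- 1 / total^2
  s2
}

# Bin a model curve with a data curve's precomputed edges (shared ROI).
bin_with_edges <- function(times, counts, edges) {
  raw <- diff(cumtrapz_at(times, counts, edges))
  total <- sum(raw)
  if (total <= 0) return(rep(0, length(edges) - 1))
  raw / total
}

#' Preprocess every curve of a measurement set
#'
#' Applies [select_roi()] and [bin_normalize()] to each source-detector
#' pair at one wavelength, keeping only pairs beyond a minimum separation.
#'
#' @param ms a `measurement_set`
#' @param wl_index wavelength index
#' @param ntw number of bins
#' @param min_distance mm; only pairs with larger separation are kept
#'   (default 27 mm, the convergence-motivated cut)
#' @return list of `binned_curve` objects with attached pair indices
#' @export
preprocess_measurements <- function(ms, wl_index = 1, ntw = 80L,
                                    min_distance = 27) {
  dists <- sd_distances(ms$geometry)
  keep <- which(dists > min_distance, arr.ind = TRUE)
  if (nrow(keep) == 0) stop("all pairs filtered out by the distance cut")
  lapply(seq_len(nrow(keep)), function(r) {
    i <- keep[r, 1]; j <- keep[r, 2]
    b <- bin_normalize(ms_tpsf(ms, i, j, wl_index), ntw = ntw)
    b$source <- i; b$detector <- j; b$distance <- dists[i, j]
    b
  })
}
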