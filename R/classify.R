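#' Assemble the 16-feature lesion table
#'
#' One row per lesion: the log of the eight reconstructed (or ground-truth)
#' inclusion absorption coefficients and the eight reduced-scattering
#' coefficients. Lesions with any non-positive coefficient or non-converged
#' fit are flagged and excluded (their ids are attached as the `excluded`
#' attribute). Standardization is deliberately deferred to [train_eval()],
#' which computes z-score statistics on the training split only.
#'
#' @param mua_in n x 8 matrix of inclusion absorption per wavelength, mm^-1
#' @param musp_in n x 8 matrix of inclusion reduced scattering, mm^-1
#' @param labels character/factor of "benign"/"malignant" per lesion (cysts
#'   enter as benign)
#' @param provenance one of "ground_truth", "recon_gt_prior",
#'   "recon_us_prior"
#' @param converged optional logical per lesion (fits that converged)
#' @param wavelengths nm labels for the feature columns
#' @return a data.frame with 16 log-feature columns, `label`, `provenance`
#' @export
build_features <- function(mua_in, musp_in, labels,
                           provenance = c("ground_truth", "recon_gt_prior",
                                          "recon_us_prior"),
                           converged = NULL, wavelengths = NULL) {
  provenance <- match.arg(provenance)
  mua_in <- as.matrix(mua_in); musp_in <- as.matrix(musp_in)
  stopifnot(nrow(mua_in) == nrow(musp_in), nrow(mua_in) == length(labels),
            ncol(mua_in) == ncol(musp_in))
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(mua_in))
  ok <- apply(mua_in > 0, 1, all) & apply(musp_in > 0, 1, all)
  if (!is.null(converged)) ok <- ok & converged
  excluded <- which(!ok)
  f <- cbind(log(mua_in[ok, , drop = FALSE]), log(musp_in[ok, , drop = FALSE]))
  colnames(f) <- c(paste0("log_mua_", wavelengths),
                   paste0("log_musp_", wavelengths))
  out <- data.frame(f, check.names = FALSE)
  out$label <- factor(as.character(labels)[ok], levels = c("benign", "malignant"))
  out$provenance <- provenance
  attr(out, "excluded") <- excluded
  out
}

feature_matrix <- function(table) {
  as.matrix(table[, grep("^log_", names(table)), drop = FALSE])
}

# z-score using training-split statistics only
standardize_features <- function(train, apply_to = NULL) {
  mu <- colMeans(train); s <- apply(train, 2, sd)
  s[s == 0] <- 1
  f <- function(x) sweep(sweep(x, 2, mu, `-`), 2, s, `/`)
  if (is.null(apply_to)) f(train) else list(train = f(train), test = f(apply_to))
}

#' Principal-component embedding of a feature table
#'
#' Centered PCA of the log features; components are orthogonal and ordered
#' by explained variance. Used to visualize class separability.
#'
#' @param table a feature table from [build_features()] (or a numeric
#'   matrix)
#' @param n_components number of scores to return (default 3)
#' @return list with `scores` (n x n_components), `rotation`,
#'   `explained_variance`
#' @export
pca_embed <- function(table, n_components = 3L) {
  X <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  if (ncol(X) < n_components) stop("fewer features than requested components")
  if (nrow(X) < n_components) stop("fewer samples than requested components")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = p$sdev^2)
}

#' Classification metrics from confusion counts
#'
#' Malignant is the positive class: TM/TB are correctly identified
#' malignant/benign lesions, FM/FB incorrectly identified ones.
#' `accuracy = (TM + TB)/total`, `precision = TM/(TM + FM)`,
#' `recall = TM/(TM + FB)`, `F1 = 2 pr / (p + r)`. Zero-denominator
#' metrics are reported as NA (undefined), never as 0.
#'
#' @param TM,TB,FM,FB non-negative integer confusion counts
#' @return list with `accuracy`, `precision`, `recall`, `f1` and the counts
#' @export
classification_metrics <- function(TM, TB, FM, FB) {
  stopifnot(TM >= 0, TB >= 0, FM >= 0, FB >= 0, TM + TB + FM + FB > 0)
  total <- TM + TB + FM + FB
  prec <- if (TM + FM > 0) TM / (TM + FM) else NA_real_
  rec <- if (TM + FB > 0) TM / (TM + FB) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(accuracy = (TM + TB) / total, precision = prec, recall = rec, f1 = f1,
       counts = c(TM = TM, TB = TB, FM = FM, FB = FB))
}

stratified_split <- function(labels, fractions, seed) {
  with_seed(seed, {
    groups <- vector("list", length(fractions))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      cuts <- round(cumsum(fractions) * n)
      starts <- c(1, head(cuts, -1) + 1)
      for (g in seq_along(fractions))
        if (starts[g] <= cuts[g])
          groups[[g]] <- c(groups[[g]], idx[starts[g]:cuts[g]])
    }
    groups
  })
}

svm_grid_select <- function(X, y, seed, folds = 5L) {
  kernels <- list(list(kernel = "radial"),
                  list(kernel = "polynomial", degree = 3),
                  list(kernel = "sigmoid"))
  Cs <- c(0.5, 1, 2, 3, 4, 5)
  folds <- max(2L, min(folds, nrow(X) %/% 2))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  best <- list(kernel = "radial", cost = 1); best_acc <- -1
  for (kk in kernels) for (C in Cs) {
    acc <- mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      tryCatch({
        m <- do.call(e1071::svm, c(list(x = X[tr, , drop = FALSE], y = y[tr],
                                        cost = C, scale = FALSE), kk))
        mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
      }, error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
    if (!is.nan(acc) && acc > best_acc) {
      best_acc <- acc; best <- c(kk, list(cost = C))
    }
  }
  best
}

#' Train and evaluate a classifier on a feature table
#'
#' Stratified split per the method's convention (60:40 train:test for
#' logistic regression and the SVM; 60:20:20 train:validation:test for the
#' network). Features are z-scored with training-split statistics. The SVM
#' is model-selected by 5-fold cross-validated training accuracy over
#' kernels {Gaussian, polynomial degree 3, sigmoid} and cost C in
#' {0.5, 1, 2, 3, 4, 5}. The network is the fixed 16/32/16/1 dense
#' architecture trained on the hinge loss with early stopping on the
#' validation split. Deterministic given `rng_seed`.
#'
#' @param table a feature table from [build_features()] with both classes
#' @param method "logreg", "svm" or "fcn"
#' @param split_spec split fractions; defaults to the method's convention
#' @param rng_seed integer seed (drives the split and any training
#'   stochasticity)
#' @return a `class_report`: the [classification_metrics()] list plus
#'   `method`, `split`, `n_test`
#' @export
train_eval <- function(table, method = c("logreg", "svm", "fcn"),
                       split_spec = NULL, rng_seed = 1L) {
  method <- match.arg(method)
  y <- table$label
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  X <- feature_matrix(table)
  if (is.null(split_spec))
    split_spec <- if (method == "fcn") c(0.6, 0.2, 0.2) else c(0.6, 0.4)
  groups <- stratified_split(y, split_spec, derive_seed(rng_seed, 1L, 3L))
  tr <- groups[[1]]
  te <- groups[[length(groups)]]
  Xz <- standardize_features(X[tr, , drop = FALSE], X)
  Xtr <- Xz$test[tr, , drop = FALSE]
  Xte <- Xz$test[te, , drop = FALSE]
  pred <- switch(method,
    logreg = {
      df_tr <- data.frame(Xtr, y = as.integer(y[tr] == "malignant"))
      fit <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial()))
      suppressWarnings(
        as.vector(predict(fit, data.frame(Xte), type = "response")) > 0.5)
    },
    svm = {
      cfg <- svm_grid_select(Xtr, droplevels(y[tr]), derive_seed(rng_seed, 2L, 5L))
      m <- do.call(e1071::svm, c(list(x = Xtr, y = droplevels(y[tr]),
                                      scale = FALSE), cfg))
      predict(m, Xte) == "malignant"
    },
    fcn = {
      va <- groups[[2]]
      Xva <- Xz$test[va, , drop = FALSE]
      enc <- function(lab) ifelse(lab == "malignant", 1, -1)
      m <- mlp_train(Xtr, enc(y[tr]), Xva, enc(y[va]),
                     seed = derive_seed(rng_seed, 3L, 7L))
      mlp_predict(m, Xte)
    })
  truth <- y[te] == "malignant"
  rep <- classification_metrics(TM = sum(pred & truth),
                                TB = sum(!pred & !truth),
                                FM = sum(pred & !truth),
                                FB = sum(!pred & truth))
  rep$method <- method
  rep$split <- split_spec
  rep$n_test <- length(te)
  class(rep) <- "class_report"
  rep
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> %s: acc %.3f prec %.3f rec %.3f F1 %.3f (n_test = %d)\n",
              x$method, x$accuracy, x$precision, x$recall, x$f1, x$n_test))
  invisible(x)
}
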