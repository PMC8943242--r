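test_that("feature tables log-transform, flag bad lesions, defer scaling", {
  set.seed(3)
  mua <- matrix(exp(rnorm(40)), 5, 8)
  musp <- matrix(exp(rnorm(40)), 5, 8)
  lab <- c("benign", "malignant", "benign", "malignant", "benign")
  tab <- build_features(mua, musp, lab, "ground_truth")
  expect_equal(dim(tab), c(5L, 18L))
  expect_equal(unname(as.matrix(tab[, 1:8])), log(mua))
  # non-positive coefficient flags the lesion out
  mua2 <- mua; mua2[2, 4] <- -1
  tab2 <- build_features(mua2, musp, lab, "recon_gt_prior")
  expect_equal(nrow(tab2), 4L)
  expect_equal(attr(tab2, "excluded"), 2L)
  # standardization statistics come from the training split only
  X <- usdot:::feature_matrix(tab)
  z <- usdot:::standardize_features(X[1:3, ], X)
  expect_equal(colMeans(z$test[1:3, ]), setNames(rep(0, 16), colnames(X)),
               tolerance = 1e-12)
})

test_that("PCA embedding is orthogonal with non-increasing variance", {
  set.seed(8)
  X <- matrix(rnorm(300 * 16), 300, 16) %*% diag(seq(4, 0.5, length.out = 16))
  colnames(X) <- paste0("log_f", 1:16)
  emb <- pca_embed(X, 3)
  G <- crossprod(emb$rotation)
  expect_equal(G, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(emb$explained_variance) <= 1e-10))
  # isotropic 3-d data: explained variances comparable
  W <- matrix(rnorm(4000 * 3), ncol = 3)
  colnames(W) <- paste0("log_w", 1:3)
  ev <- pca_embed(W, 3)$explained_variance
  expect_lt(max(ev) / min(ev), 1.15)
  expect_error(pca_embed(X[1:2, ], 3), "fewer samples")
})

test_that("classification metrics match the confusion-count definitions", {
  m <- classification_metrics(TM = 85, TB = 80, FM = 15, FB = 20)
  expect_equal(m$accuracy, 0.825)
  expect_equal(m$precision, 0.85)
  expect_equal(m$recall, 85 / 105, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.85 * (85 / 105) / (0.85 + 85 / 105))
  perfect <- classification_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all-benign predictor: recall 0, precision undefined (never 0)
  degen <- classification_metrics(TM = 0, TB = 50, FM = 0, FB = 50)
  expect_equal(degen$recall, 0)
  expect_true(is.na(degen$precision))
})

test_that("all three classifiers separate linearly separable blobs", {
  set.seed(21)
  n <- 120
  X <- rbind(matrix(rnorm(n / 2 * 16, -2, 0.3), ncol = 16),
             matrix(rnorm(n / 2 * 16, 2, 0.3), ncol = 16))
  tab <- build_features(exp(X[, 1:8]), exp(X[, 9:16]),
                        rep(c("benign", "malignant"), each = n / 2),
                        "ground_truth")
  for (m in c("logreg", "svm", "fcn")) {
    rep_ <- train_eval(tab, m, rng_seed = 7)
    expect_equal(rep_$accuracy, 1.0)
    # metrics recomputable from the returned confusion counts
    cm <- rep_$counts
    expect_equal(rep_$accuracy,
                 (cm[["TM"]] + cm[["TB"]]) / sum(cm))
  }
})

test_that("label permutation drives accuracy to chance", {
  pop <- generate_lesion_population(300, seed = 31)
  tab <- build_features(pop$mua, pop$musp, pop$label, "ground_truth")
  perm <- tab
  perm$label <- tab$label[usdot:::with_seed(5, sample(nrow(tab)))]
  accs <- vapply(1:3, function(s)
    train_eval(perm, "logreg", rng_seed = s)$accuracy, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("classifier reports are deterministic per seed", {
  pop <- generate_lesion_population(200, seed = 13)
  tab <- build_features(pop$mua, pop$musp, pop$label, "ground_truth")
  for (m in c("logreg", "svm", "fcn")) {
    a <- train_eval(tab, m, rng_seed = 11)
    b <- train_eval(tab, m, rng_seed = 11)
    expect_identical(a$counts, b$counts)
  }
})
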