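test_that("SMOTE equalizes a 296/531 table to exactly 531/531", {
  d <- make_feature_dataset(dataset_spec(n_minority = 296, n_majority = 531,
                                         n_features = 6, seed = 2))
  b <- smote_balance(d, k_neighbors = 5, seed = 3)
  expect_equal(sum(b$label == 1), 531)
  expect_equal(sum(b$label == 0), 531)
  expect_equal(sum(b$synthetic), 235)
  # all original rows preserved, majority untouched
  orig <- b[!b$synthetic, names(d)]
  rownames(orig) <- NULL
  expect_equal(orig, d)
  # determinism
  b2 <- smote_balance(d, k_neighbors = 5, seed = 3)
  expect_equal(b, b2)
})

test_that("balanced input with target equal to current count is a no-op", {
  d <- make_feature_dataset(dataset_spec(n_minority = 50, n_majority = 50,
                                         n_features = 3))
  b <- smote_balance(d, target = 50)
  expect_equal(nrow(b), 100)
  expect_false(any(b$synthetic))
})

test_that("synthetic points interpolate a seed point and one of its 5 brute-force neighbors", {
  d <- make_feature_dataset(dataset_spec(n_minority = 40, n_majority = 90,
                                         n_features = 4, seed = 9))
  b <- smote_balance(d, k_neighbors = 5, seed = 4)
  prov <- attr(b, "smote_provenance")
  cols <- paste0("feat_", 1:4)
  xm <- as.matrix(d[d$label == 1, cols])
  syn <- as.matrix(b[b$synthetic, cols])
  # brute-force 5-NN on the same min-max-scaled metric
  mins <- apply(xm, 2, min); rng <- apply(xm, 2, max) - mins
  xs <- sweep(sweep(xm, 2, mins), 2, rng, "/")
  for (j in seq_len(nrow(syn))) {
    i <- prov$seed_idx[j]
    d2 <- colSums((t(xs) - xs[i, ])^2); d2[i] <- Inf
    expect_true(prov$nn_idx[j] %in% order(d2)[1:5])
    # exact convex combination with the recorded weight
    expected <- xm[i, ] + prov$u[j] * (xm[prov$nn_idx[j], ] - xm[i, ])
    expect_equal(unname(syn[j, ]), unname(expected), tolerance = 1e-12)
    expect_true(prov$u[j] >= 0 && prov$u[j] <= 1)
  }
})

test_that("SMOTE rejects an undersized minority class", {
  d <- make_feature_dataset(dataset_spec(n_minority = 4, n_majority = 20,
                                         n_features = 3))
  expect_error(smote_balance(d, k_neighbors = 5), "smaller k")
})

test_that("scaler maps training range to [-1, 1] with documented edge cases", {
  tr <- data.frame(x = c(2, 6, 10), y = c(7, 7, 7), label = c(0, 1, 0))
  sc <- fit_scaler(tr)
  out <- apply_scaler(sc, tr)
  expect_equal(out$x, c(-1, 0, 1))
  expect_equal(out$y, c(0, 0, 0))        # constant feature
  te <- data.frame(x = 12, y = 3, label = 1)
  expect_equal(apply_scaler(sc, te)$x, 1.5)  # extrapolation, no clipping
})

test_that("PCA keeps the smallest component count reaching the retained variance", {
  # rank-1 data
  set.seed(1)
  t1 <- runif(50)
  d1 <- data.frame(a = 2 * t1, b = -t1, c = 0.5 * t1, label = rbinom(50, 1, 0.5))
  m1 <- fit_pca(d1, retain = 0.95)
  expect_equal(m1$k, 1)

  # isotropic 20-dim Gaussian: equal population eigenvalues force k = 19
  set.seed(2)
  x <- matrix(rnorm(400 * 20), ncol = 20)
  d2 <- as.data.frame(x); d2$label <- rbinom(400, 1, 0.5)
  m2 <- fit_pca(d2, retain = 0.95)
  expect_equal(m2$k, 19)
  # against an independent eigensolver
  ev <- sort(eigen(cov(x), symmetric = TRUE)$values, decreasing = TRUE)
  k_ref <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(m2$k, k_ref)
  expect_equal(m2$var_ratio, ev / sum(ev), tolerance = 1e-8)
})

test_that("PCA components are orthonormal and projections decorrelated", {
  set.seed(3)
  x <- matrix(rnorm(120 * 8), ncol = 8) %*% diag(c(4, 3, 2, 1.5, 1, .5, .3, .1))
  d <- as.data.frame(x); d$label <- rbinom(120, 1, 0.5)
  m <- fit_pca(d, retain = 0.95)
  gram <- t(m$rotation) %*% m$rotation
  expect_lt(max(abs(gram - diag(m$k))), 1e-8)
  z <- as.matrix(apply_pca(m, d)[, seq_len(m$k)])
  cv <- cov(z)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # reconstruction error bounded by the discarded variance
  xc <- scale(as.matrix(d[, m$cols]), center = m$center, scale = FALSE)
  recon_err <- mean(rowSums((xc - z %*% t(m$rotation))^2))
  total_var <- sum(apply(xc, 2, function(v) mean(v^2)))
  expect_lte(recon_err, (1 - 0.95) * total_var + 1e-9)
})

test_that("a fitted scaler+PCA pipeline is leakage-free by construction", {
  d <- make_feature_dataset(dataset_spec(n_minority = 40, n_majority = 60,
                                         n_features = 6, seed = 4))
  sc <- fit_scaler(d)
  pc <- fit_pca(apply_scaler(sc, d))
  held_out_copy <- d[1:10, ]
  a <- apply_pca(pc, apply_scaler(sc, d[1:10, ]))
  b <- apply_pca(pc, apply_scaler(sc, held_out_copy))
  expect_identical(a, b)
  # training features lie inside [-1, 1] exactly
  s <- apply_scaler(sc, d)
  feats <- as.matrix(s[, paste0("feat_", 1:6)])
  expect_gte(min(feats), -1); expect_lte(max(feats), 1)
})

test_that("missing coating features are imputed with training means", {
  tr <- data.frame(a = c(1, 2, 3, NA), b = c(4, NA, 6, 8), label = c(0, 1, 0, 1))
  out <- impute_missing(tr)
  expect_equal(out$a[4], 2)
  expect_equal(out$b[2], 6)
  te <- data.frame(a = NA_real_, b = NA_real_, label = 0)
  out2 <- impute_missing(tr, te)
  expect_equal(unlist(out2[, c("a", "b")], use.names = FALSE), c(2, 6))
})
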