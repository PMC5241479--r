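feature_cols <- function(data, label_col = "label", drop = c("synthetic")) {
  setdiff(names(data)[vapply(data, is.numeric, TRUE)], c(label_col, drop))
}

#' Balance classes with SMOTE
#'
#' Oversamples the minority class by interpolating between each minority
#' point and one of its k nearest minority neighbors:
#' `x_new = x + u (x_nn - x)` with `u ~ Uniform(0, 1)`. Neighbors are found
#' by Euclidean distance on a min-max-scaled copy of the features (so no
#' feature dominates by its magnitude); the synthetic points themselves are
#' generated in the raw feature space. When the oversampling rate is not an
#' integer, every minority point contributes `floor(rate)` synthetic points
#' and a seeded random subset contributes one more, so the minority count
#' hits `target` exactly (e.g. 296 minority rows against a 531-row majority
#' are equalized to exactly 531/531). Majority rows are untouched; every
#' original row is preserved.
#'
#' @param data Data.frame with numeric features and a 0/1 `label` column.
#' @param k_neighbors Number of minority nearest neighbors (default 5).
#' @param target Desired minority count; default = majority count.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @param integer_cols Columns rounded to the nearest integer on synthetic
#'   rows (binary covariates such as gender stay binary); default: any of
#'   `gender` present in the data.
#' @return The input rows (flagged `synthetic = FALSE`) plus synthetic
#'   minority rows (`synthetic = TRUE`), minority count exactly `target`.
#' @export
smote_balance <- function(data, k_neighbors = 5, target = NULL, seed = 1,
                          label_col = "label",
                          integer_cols = intersect("gender", names(data))) {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- data[[label_col]]
  stopifnot_binary_labels(y)
  counts <- table(factor(y, levels = c(0, 1)))
  minority_label <- if (counts["1"] <= counts["0"]) 1 else 0
  n_min <- sum(y == minority_label)
  target <- target %||% sum(y != minority_label)
  if (target < n_min) stop("target must be >= the minority count")
  out <- data
  out$synthetic <- FALSE
  if (target == n_min) return(out)
  if (n_min <= k_neighbors) {
    stop(sprintf("minority class has %d samples; needs > k_neighbors = %d (try a smaller k)",
                 n_min, k_neighbors))
  }
  cols <- feature_cols(data, label_col)
  xm <- as.matrix(data[y == minority_label, cols, drop = FALSE])

  # min-max pre-scaling for the neighbor metric only
  mins <- apply(xm, 2, min); maxs <- apply(xm, 2, max)
  rng <- ifelse(maxs > mins, maxs - mins, 1)
  xs <- sweep(sweep(xm, 2, mins), 2, rng, "/")
  d2 <- as.matrix(stats::dist(xs))^2
  diag(d2) <- Inf
  nn_idx <- t(apply(d2, 1, function(r) order(r)[seq_len(k_neighbors)]))

  n_syn <- target - n_min
  base <- n_syn %/% n_min
  extra <- n_syn %% n_min
  prov <- with_seed(seed, {
    extra_idx <- if (extra > 0) sample(n_min, extra) else integer(0)
    reps <- rep(base, n_min)
    reps[extra_idx] <- reps[extra_idx] + 1L
    seeds_i <- rep(seq_len(n_min), reps)
    nn_pick <- vapply(seeds_i, function(i) nn_idx[i, sample.int(k_neighbors, 1)], 1L)
    data.frame(seed_idx = seeds_i, nn_idx = nn_pick,
               u = stats::runif(length(seeds_i)))
  })
  syn <- xm[prov$seed_idx, , drop = FALSE] +
    prov$u * (xm[prov$nn_idx, , drop = FALSE] - xm[prov$seed_idx, , drop = FALSE])
  syn_df <- as.data.frame(syn)
  for (cc in intersect(integer_cols, cols)) syn_df[[cc]] <- round(syn_df[[cc]])
  # carry non-feature columns from the template, then overwrite features
  tmpl <- out[rep(which(y == minority_label)[1], nrow(syn_df)), , drop = FALSE]
  tmpl[cols] <- syn_df[cols]
  tmpl[[label_col]] <- minority_label
  tmpl$synthetic <- TRUE
  rownames(tmpl) <- NULL
  res <- rbind(out, tmpl)
  rownames(res) <- NULL
  # provenance (minority-relative indices of seed point and chosen neighbor,
  # interpolation weight) for audit: synthetic row j derives from row
  # prov$seed_idx[j] of the minority subset
  attr(res, "smote_provenance") <- prov
  res
}

#' Fit / apply a [-1, 1] min-max scaler
#'
#' `fit_scaler` records per-feature training minima and maxima;
#' `apply_scaler` maps `x` to `2 (x - min) / (max - min) - 1`. Features that
#' are constant on the training data map to 0. Values outside the training
#' range extrapolate beyond [-1, 1] (no clipping).
#'
#' @param train Training data.frame.
#' @param cols Feature columns (default: numeric columns except the label
#'   and the `synthetic` flag).
#' @param label_col Label column name.
#' @return `fit_scaler`: object of class `scaler_model`.
#' @export
fit_scaler <- function(train, cols = feature_cols(train, label_col), label_col = "label") {
  x <- as.matrix(train[, cols, drop = FALSE])
  structure(list(cols = cols,
                 min = apply(x, 2, min),
                 max = apply(x, 2, max)),
            class = "scaler_model")
}

#' @rdname fit_scaler
#' @param model A `scaler_model`.
#' @param data Data to scale; non-feature columns pass through unchanged.
#' @export
apply_scaler <- function(model, data) {
  stopifnot(inherits(model, "scaler_model"))
  rng <- model$max - model$min
  for (j in seq_along(model$cols)) {
    cc <- model$cols[j]
    data[[cc]] <- if (rng[j] > 0) {
      2 * (data[[cc]] - model$min[j]) / rng[j] - 1
    } else rep(0, nrow(data))
  }
  data
}

#' Fit / apply PCA at a retained-variance level
#'
#' `fit_pca` centers the training features and keeps the smallest number of
#' principal components whose cumulative explained-variance ratio reaches
#' `retain` (default 0.95, i.e. 95% of the information in the features).
#' With fewer samples than features the component count is capped at the
#' data rank, with a warning.
#'
#' @param train Training data.frame (fit on training rows only).
#' @param retain Fraction of variance to retain, in (0, 1].
#' @param cols,label_col Feature columns / label column.
#' @return `fit_pca`: object of class `pca_model` with the mean vector, the
#'   orthonormal component matrix (columns), per-component explained
#'   variance ratios and the retained count `k`.
#' @export
fit_pca <- function(train, retain = 0.95,
                    cols = feature_cols(train, label_col), label_col = "label") {
  if (retain <= 0 || retain > 1) stop("retain must lie in (0, 1]")
  x <- as.matrix(train[, cols, drop = FALSE])
  if (nrow(x) < length(cols) + 1) {
    warning("fewer samples than features; component count capped at the data rank")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(var_ratio) >= retain - 1e-12)[1]
  if (is.na(k)) k <- length(var_ratio)
  structure(list(cols = cols, center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 var_ratio = var_ratio, k = k, retain = retain),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model A `pca_model`.
#' @param data Data to project; returns `PC1..PCk` plus any label /
#'   `synthetic` columns present.
#' @export
apply_pca <- function(model, data) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(data[, model$cols, drop = FALSE])
  z <- sweep(x, 2, model$center) %*% model$rotation
  out <- as.data.frame(z)
  names(out) <- paste0("PC", seq_len(model$k))
  for (cc in intersect(c("label", "synthetic"), names(data))) out[[cc]] <- data[[cc]]
  out
}

#' Impute missing feature values with training-set means
#'
#' Coating features can be absent when an image carries no coating; they are
#' imputed with the per-column training mean so the feature dimensionality
#' stays fixed.
#'
#' @param train Training data (defines the means).
#' @param data Data to impute (default: the training data itself).
#' @param cols,label_col Feature columns / label column.
#' @return `data` with NAs in feature columns replaced by training means.
#' @export
impute_missing <- function(train, data = train,
                           cols = feature_cols(train, label_col),
                           label_col = "label") {
  mu <- vapply(train[cols], function(v) mean(v, na.rm = TRUE), 1)
  mu[is.nan(mu)] <- 0
  for (j in seq_along(cols)) {
    v <- data[[cols[j]]]
    v[is.na(v)] <- mu[j]
    data[[cols[j]]] <- v
  }
  data
}
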