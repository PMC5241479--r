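#' Segmentation configuration
#'
#' @param min_block_size Minimum block pixel count in the quadtree division
#'   phase; blocks at or below this size are not split further (default 4,
#'   i.e. 2 x 2 blocks).
#' @param homogeneity_tol Maximum within-block chrominance standard deviation
#'   for a block to count as homogeneous, in chrominance units (default 6).
#' @param chroma_channel Chrominance transform used for splitting and
#'   thresholding: `"a"` (CIELAB a*, the red-green opponent axis; default),
#'   `"hue"` (HSI hue in degrees), or `"rg"` (R - G).
#' @param threshold_mode `"automatic"` (Otsu's criterion on the region-mean
#'   histogram) or `"fixed"`.
#' @param fixed_threshold Threshold value when `threshold_mode = "fixed"`.
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(min_block_size = 4, homogeneity_tol = 6,
                                chroma_channel = c("a", "hue", "rg"),
                                threshold_mode = c("automatic", "fixed"),
                                fixed_threshold = NULL) {
  if (min_block_size < 2) stop("min_block_size must be >= 2")
  if (homogeneity_tol <= 0) stop("homogeneity_tol must be > 0")
  chroma_channel <- match.arg(chroma_channel)
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold required when threshold_mode = 'fixed'")
  }
  structure(list(min_block_size = min_block_size,
                 homogeneity_tol = homogeneity_tol,
                 chroma_channel = chroma_channel,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold),
            class = "segmentation_config")
}

#' Chrominance map of a tongue image
#'
#' @param image A [tongue_image()].
#' @param channel `"a"` (CIELAB a*), `"hue"` (HSI hue, degrees) or `"rg"`
#'   (R - G difference).
#' @return Numeric matrix with finite values on tongue pixels and NA outside.
#' @export
chrominance_map <- function(image, channel = "a") {
  stopifnot(inherits(image, "tongue_image"))
  if (!channel %in% c("a", "hue", "rg")) {
    stop(sprintf("unknown chrominance channel '%s'", channel))
  }
  mask <- image$tongue_mask
  px <- cbind(image$pixels[, , 1][mask],
              image$pixels[, , 2][mask],
              image$pixels[, , 3][mask])
  v <- switch(channel,
    a = rgb_to_lab(px)[, "a"],
    hue = rgb_to_hsi(px / 255)[, "H"],
    rg = px[, 1] - px[, 2])
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[mask] <- v
  out
}

# Summed-area tables for O(1) block statistics over the masked chroma map.
.block_stats_fun <- function(chroma, mask) {
  z <- ifelse(mask, chroma, 0)
  sat <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  S1 <- sat(z); S2 <- sat(z^2); N <- sat(mask * 1)
  lookup <- function(S, r0, r1, c0, c1) {
    S[r1, c1] -
      (if (r0 > 1) S[r0 - 1, c1] else 0) -
      (if (c0 > 1) S[r1, c0 - 1] else 0) +
      (if (r0 > 1 && c0 > 1) S[r0 - 1, c0 - 1] else 0)
  }
  function(r0, r1, c0, c1) {
    n <- lookup(N, r0, r1, c0, c1)
    if (n == 0) return(c(n = 0, mean = NA, sd = NA))
    s1 <- lookup(S1, r0, r1, c0, c1)
    s2 <- lookup(S2, r0, r1, c0, c1)
    mu <- s1 / n
    c(n = n, mean = mu, sd = sqrt(max(s2 / n - mu^2, 0)))
  }
}

#' Division-merging segmentation of the tongue region
#'
#' Division phase: the tongue bounding box is split quadtree-style while a
#' block's within-mask chrominance standard deviation exceeds
#' `homogeneity_tol` and the block holds more than `min_block_size` pixels.
#' Terminal blocks that remain inhomogeneous (generically, blocks straddling
#' a region boundary) are dissolved into single-pixel regions. Merge phase:
#' in region-index order, each region is greedily merged with the adjacent
#' region of closest mean chrominance whenever the merged standard deviation
#' stays within `homogeneity_tol` and the two region means differ by at most
#' `homogeneity_tol` (the second condition keeps a large region from
#' swallowing opposite-colored single pixels whose effect on its standard
#' deviation is diluted away); ties are broken by lower region index and
#' passes repeat until no merge applies.
#'
#' @param image A [tongue_image()].
#' @param cfg A [segmentation_config()].
#' @return List with `labels` (integer matrix, NA outside the tongue; region
#'   ids are consecutive from 1 in column-major order of first pixel),
#'   `regions` (data.frame: id, n, mean, sd of chrominance), `chroma` (the
#'   chrominance map used), `channel`, and `trace` (block/merge counts). The
#'   regions tile the tongue mask.
#' @export
division_merge <- function(image, cfg = segmentation_config()) {
  stopifnot(inherits(image, "tongue_image"))
  mask <- image$tongue_mask
  chroma <- chrominance_map(image, cfg$chroma_channel)
  h <- nrow(mask); w <- ncol(mask)
  bs <- .block_stats_fun(chroma, mask)
  tol <- cfg$homogeneity_tol

  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  stack <- list(c(rr[1], rr[2], cc[1], cc[2]))
  leaves <- list()
  while (length(stack) > 0) {
    b <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    st <- bs(b[1], b[2], b[3], b[4])
    if (st["n"] == 0) next
    splittable <- (b[2] > b[1] || b[4] > b[3]) && st["n"] > cfg$min_block_size
    if (st["sd"] <= tol || !splittable) {
      leaves[[length(leaves) + 1]] <- c(b, st)
    } else {
      rmid <- if (b[2] > b[1]) (b[1] + b[2]) %/% 2 else b[1]
      cmid <- if (b[4] > b[3]) (b[3] + b[4]) %/% 2 else b[3]
      rs <- if (b[2] > b[1]) list(c(b[1], rmid), c(rmid + 1, b[2])) else list(c(b[1], b[2]))
      cs <- if (b[4] > b[3]) list(c(b[3], cmid), c(cmid + 1, b[4])) else list(c(b[3], b[4]))
      for (ri in rs) for (ci in cs) {
        stack[[length(stack) + 1]] <- c(ri[1], ri[2], ci[1], ci[2])
      }
    }
  }
  n_leaves <- length(leaves)

  # paint leaf ids; dissolve inhomogeneous terminal leaves into pixels
  labels <- matrix(NA_integer_, h, w)
  nid <- 0L
  n_dissolved <- 0L
  for (lf in leaves) {
    sub <- matrix(FALSE, h, w)
    sub[lf[1]:lf[2], lf[3]:lf[4]] <- TRUE
    sub <- sub & mask
    if (lf["sd"] > tol && lf["n"] > 1) {
      idx <- which(sub)
      labels[idx] <- nid + seq_along(idx)
      nid <- nid + length(idx)
      n_dissolved <- n_dissolved + 1L
    } else {
      nid <- nid + 1L
      labels[sub] <- nid
    }
  }
  # renumber by first (column-major) pixel
  ord <- order(match(seq_len(nid), as.vector(labels)))
  relab <- integer(nid); relab[ord] <- seq_len(nid)
  labels[mask] <- relab[labels[mask]]

  # region stats
  v <- chroma[mask]; l <- labels[mask]
  n_r <- tabulate(l, nid)
  s1 <- as.numeric(rowsum(v, l))
  s2 <- as.numeric(rowsum(v^2, l))

  # greedy merge passes on the region adjacency graph
  parent <- seq_len(nid)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  repeat {
    lb <- labels
    lb[mask] <- vapply(lb[mask], find, 1L)
    pairs <- rbind(
      cbind(as.vector(lb[-h, ]), as.vector(lb[-1, ])),
      cbind(as.vector(lb[, -w]), as.vector(lb[, -1])))
    pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) == 0) break
    pairs <- unique(rbind(pairs, pairs[, 2:1]))
    mu <- s1 / n_r
    o <- order(pairs[, 1], abs(mu[pairs[, 1]] - mu[pairs[, 2]]), pairs[, 2])
    pairs <- pairs[o, , drop = FALSE]
    merged_any <- FALSE
    seen <- rep(FALSE, nid)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a == b) next
      if (seen[pairs[k, 1]]) next  # one merge attempt per region per pass
      seen[pairs[k, 1]] <- TRUE
      n2 <- n_r[a] + n_r[b]; t1 <- s1[a] + s1[b]; t2 <- s2[a] + s2[b]
      sd2 <- sqrt(max(t2 / n2 - (t1 / n2)^2, 0))
      # similar-neighbor condition: a large region could otherwise absorb
      # opposite-colored single pixels with negligible impact on its std
      dmu <- abs(s1[a] / n_r[a] - s1[b] / n_r[b])
      if (sd2 <= tol && dmu <= tol) {
        keep <- min(a, b); drop <- max(a, b)
        parent[drop] <- keep
        n_r[keep] <- n2; s1[keep] <- t1; s2[keep] <- t2
        n_r[drop] <- 0; s1[drop] <- 0; s2[drop] <- 0
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  labels[mask] <- vapply(labels[mask], find, 1L)
  ids <- sort(unique(labels[mask]))
  relab <- integer(nid); relab[ids] <- seq_along(ids)
  labels[mask] <- relab[labels[mask]]
  regions <- data.frame(id = seq_along(ids),
                        n = n_r[ids],
                        mean = s1[ids] / n_r[ids],
                        sd = sqrt(pmax(s2[ids] / n_r[ids] - (s1[ids] / n_r[ids])^2, 0)))
  list(labels = labels, regions = regions, chroma = chroma,
       channel = cfg$chroma_channel,
       trace = list(n_leaves = n_leaves, n_dissolved_blocks = n_dissolved,
                    n_regions = nrow(regions)))
}

#' Otsu threshold of a weighted sample
#'
#' Maximizes the between-class variance of a 256-bin histogram built over the
#' sample range; returns the threshold value (upper edge of the optimal bin).
#'
#' @param values Numeric vector.
#' @param weights Nonnegative weights (default 1).
#' @return Threshold; values strictly above it fall in the upper class.
#' @export
otsu_threshold <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  bin <- pmin(pmax(ceiling((values - rng[1]) / diff(rng) * nb), 1L), nb)
  hist <- numeric(nb)
  acc <- rowsum(weights, bin)
  hist[as.integer(rownames(acc))] <- acc
  p <- hist / sum(hist)
  mids <- rng[1] + (seq_len(nb) - 0.5) * diff(rng) / nb
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nb]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, nb)
  bcv[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  # plateau of equal criterion values (empty valley): take its midpoint
  top <- which(bcv >= max(bcv) - abs(max(bcv)) * 1e-9)
  k <- floor(mean(range(top)))
  rng[1] + k * diff(rng) / nb
}

#' Separate tongue body and coating
#'
#' Combines the division-merging segmentation with a chrominance threshold:
#' regions from [division_merge()] are labeled body or coating by comparing
#' their mean chrominance to a threshold (Otsu's criterion on the
#' pixel-weighted region-mean histogram by default). The side with the higher
#' mean CIELAB a* (the redder side) is the body. Two per-pixel fallbacks
#' handle thin or overlapping coating, where region means alone are
#' ambiguous: (i) pixels of regions whose mean lies within
#' `homogeneity_tol` of the threshold are relabeled individually by the
#' pixel's own chrominance; (ii) a pixel whose chrominance lies beyond the
#' threshold by more than `homogeneity_tol` on the side opposite its
#' region's label is flipped to the side its own color supports.
#'
#' @param image A [tongue_image()].
#' @param cfg A [segmentation_config()].
#' @return Object of class `segmentation_result`: `body_mask`,
#'   `coating_mask` (logical matrices partitioning the tongue mask) and
#'   `method_trace` (region counts, threshold, channel, fallback counts).
#'   When the region-mean histogram is single-mode the whole tongue is
#'   labeled body and a warning is emitted.
#' @export
segment_body_coating <- function(image, cfg = segmentation_config()) {
  dm <- division_merge(image, cfg)
  mask <- image$tongue_mask
  tol <- cfg$homogeneity_tol
  all_body <- function(reason) {
    warning(sprintf("single-mode chrominance histogram (%s); entire tongue labeled body",
                    reason), call. = FALSE)
    structure(list(body_mask = mask, coating_mask = mask & FALSE,
                   method_trace = c(dm$trace,
                                    list(threshold = NA_real_,
                                         channel = dm$channel,
                                         degenerate = TRUE))),
              class = "segmentation_result")
  }
  if (nrow(dm$regions) < 2) return(all_body("single region"))

  thr <- if (cfg$threshold_mode == "fixed") cfg$fixed_threshold else
    otsu_threshold(dm$regions$mean, dm$regions$n)
  hi <- dm$regions$mean > thr
  if (all(hi) || !any(hi)) return(all_body("threshold separates nothing"))
  mu_hi <- sum(dm$regions$mean[hi] * dm$regions$n[hi]) / sum(dm$regions$n[hi])
  mu_lo <- sum(dm$regions$mean[!hi] * dm$regions$n[!hi]) / sum(dm$regions$n[!hi])
  if (abs(mu_hi - mu_lo) <= tol && cfg$threshold_mode != "fixed") {
    return(all_body("modes closer than homogeneity_tol"))
  }

  # body = the redder side, judged on the a* axis
  amap <- if (dm$channel == "a") dm$chroma else chrominance_map(image, "a")
  region_of_px <- dm$labels[mask]
  hi_px <- hi[region_of_px]
  body_is_hi <- mean(amap[mask][hi_px]) >= mean(amap[mask][!hi_px])

  # region labels, then the two per-pixel chrominance-threshold fallbacks
  near <- abs(dm$regions$mean - thr) <= tol
  px_side_hi <- hi[region_of_px]
  chroma_px <- dm$chroma[mask]
  relabeled <- near[region_of_px]
  px_side_hi[relabeled] <- chroma_px[relabeled] > thr
  confident_hi <- chroma_px > thr + tol
  confident_lo <- chroma_px < thr - tol
  flipped <- (confident_hi & !px_side_hi) | (confident_lo & px_side_hi)
  px_side_hi[confident_hi] <- TRUE
  px_side_hi[confident_lo] <- FALSE

  body_px <- if (body_is_hi) px_side_hi else !px_side_hi
  body <- coating <- matrix(FALSE, nrow(mask), ncol(mask))
  body[mask] <- body_px
  coating[mask] <- !body_px
  structure(list(body_mask = body, coating_mask = coating,
                 method_trace = c(dm$trace,
                                  list(threshold = thr, channel = dm$channel,
                                       body_is_high_chroma = body_is_hi,
                                       n_regions_relabeled = sum(near),
                                       n_pixels_flipped = sum(flipped),
                                       degenerate = FALSE))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> body %d px, coating %d px (threshold %.2f on %s)\n",
              sum(x$body_mask), sum(x$coating_mask),
              x$method_trace$threshold %||% NA, x$method_trace$channel))
  invisible(x)
}
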