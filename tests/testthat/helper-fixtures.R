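# Shared fixture builders; everything is generated in code at test time.

default_fixture <- function(seed = 1, ...) {
  make_tongue_image(synthetic_spec(seed = seed, ...))
}

flat_fixture <- function(seed = 1, ...) {
  make_tongue_image(synthetic_spec(texture_amplitude = 0, noise_sigma = 0,
                                   seed = seed, ...))
}

# Flat-color image with every pixel in the tongue mask.
flat_image <- function(h, w, col) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- col[ch]
  tongue_image(px, matrix(TRUE, h, w))
}

random_image <- function(h, w, seed, mask_frac = 1) {
  set.seed(seed)
  px <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  mask <- matrix(runif(h * w) < mask_frac, h, w)
  if (!any(mask)) mask[1, 1] <- TRUE
  tongue_image(px, mask)
}

# Brute-force gray-difference histogram: explicit double loop over pixels.
brute_gray_diff_hist <- function(image, mask, displacement) {
  g <- round(0.299 * image$pixels[, , 1] + 0.587 * image$pixels[, , 2] +
             0.114 * image$pixels[, , 3])
  mask <- (mask > 0) & image$tongue_mask
  dy <- displacement[1]; dx <- displacement[2]
  counts <- numeric(256)
  for (r in seq_len(nrow(g))) {
    for (c in seq_len(ncol(g))) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 >= 1 && r2 <= nrow(g) && c2 >= 1 && c2 <= ncol(g) &&
          mask[r, c] && mask[r2, c2]) {
        d <- abs(g[r, c] - g[r2, c2])
        counts[d + 1] <- counts[d + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Mann-Whitney pair statistic with ties counted one half.
mann_whitney_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
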