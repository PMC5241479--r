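#' Gray level of an RGB image (BT.601 luminance)
#'
#' @param image A [tongue_image()].
#' @return Integer matrix of rounded luminance values 0..255.
#' @keywords internal
gray_level <- function(image) {
  d <- dim(image$pixels)
  matrix(round(0.299 * image$pixels[, , 1] +
               0.587 * image$pixels[, , 2] +
               0.114 * image$pixels[, , 3]), d[1], d[2])
}

#' Gray-level difference histogram
#'
#' Histogram of absolute gray-level differences `|g(x) - g(x + d)|` over all
#' pixel pairs whose two endpoints both lie inside the mask, normalized to
#' sum 1. Gray level is the rounded BT.601 luminance.
#'
#' @param image A [tongue_image()].
#' @param mask Logical region mask (intersected with the tongue mask).
#' @param displacement Integer offset `c(dy, dx)` in (row, column) order.
#' @return Object of class `difference_histogram`: list with `p` (probability
#'   vector over difference levels 0..255), `displacement`, and `n_pairs`.
#' @export
gray_difference_histogram <- function(image, mask, displacement = c(0, 1)) {
  stopifnot(inherits(image, "tongue_image"), length(displacement) == 2)
  dy <- as.integer(displacement[1]); dx <- as.integer(displacement[2])
  mask <- (mask > 0) & image$tongue_mask
  g <- gray_level(image)
  h <- nrow(g); w <- ncol(g)
  r0lo <- max(1, 1 - dy); r0hi <- min(h, h - dy)
  c0lo <- max(1, 1 - dx); c0hi <- min(w, w - dx)
  if (r0lo > r0hi || c0lo > c0hi || !any(mask)) {
    stop(sprintf("no valid pixel pairs for displacement (%d, %d)", dy, dx))
  }
  r0 <- r0lo:r0hi
  c0 <- c0lo:c0hi
  ok <- mask[r0, c0, drop = FALSE] & mask[r0 + dy, c0 + dx, drop = FALSE]
  if (!any(ok)) {
    stop(sprintf("no valid pixel pairs for displacement (%d, %d)", dy, dx))
  }
  d <- abs(g[r0, c0, drop = FALSE] - g[r0 + dy, c0 + dx, drop = FALSE])[ok]
  p <- tabulate(d + 1L, nbins = 256L)
  p <- p / sum(p)
  structure(list(p = p, displacement = c(dy, dx), n_pairs = sum(ok)),
            class = "difference_histogram")
}

#' Texture statistics of a gray-difference histogram
#'
#' Computes the four gray-level-difference statistics over difference levels
#' `i = 0..255` with probabilities `p(i)`:
#' contrast `CON = sum i^2 p(i)`, angular second moment `ASM = sum p(i)^2`,
#' entropy `ENT = -sum p(i) log p(i)` over positive bins (base-2 by default),
#' and `MEAN = sum i p(i)`.
#'
#' @param h A `difference_histogram` (or a bare probability vector).
#' @param ent_base Logarithm base for the entropy (default 2, i.e. bits).
#' @return Named vector `c(CON, ASM, ENT, MEAN)`.
#' @export
texture_stats <- function(h, ent_base = 2) {
  p <- if (inherits(h, "difference_histogram")) h$p else h
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("histogram must be a probability vector summing to 1")
  }
  i <- seq_along(p) - 1
  pos <- p > 0
  c(CON = sum(i^2 * p),
    ASM = sum(p^2),
    ENT = -sum(p[pos] * log(p[pos], base = ent_base)),
    MEAN = sum(i * p))
}

#' Per-region texture features, averaged over displacements
#'
#' Computes [texture_stats()] for each displacement and averages them; the
#' default displacements are the two axial unit offsets.
#'
#' @param image A [tongue_image()].
#' @param mask Region mask.
#' @param displacements List of `c(dy, dx)` offsets.
#' @inheritParams texture_stats
#' @return Named vector `tex_CON, tex_ASM, tex_ENT, tex_MEAN`; all NA with a
#'   `missing` attribute when the mask is empty or admits no pixel pairs.
#' @export
region_texture_features <- function(image, mask,
                                    displacements = list(c(0, 1), c(1, 0)),
                                    ent_base = 2) {
  nm <- c("tex_CON", "tex_ASM", "tex_ENT", "tex_MEAN")
  res <- tryCatch({
    stats_list <- lapply(displacements, function(d) {
      texture_stats(gray_difference_histogram(image, mask, d), ent_base)
    })
    colMeans(do.call(rbind, stats_list))
  }, error = function(e) NULL)
  if (is.null(res)) {
    out <- stats::setNames(rep(NA_real_, 4), nm)
    attr(out, "missing") <- TRUE
    return(out)
  }
  stats::setNames(res, nm)
}
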