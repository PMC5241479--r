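#' Specification for a synthetic tongue image
#'
#' Describes a pre-cropped tongue photograph emulated as an elliptical tongue
#' region whose "body" pixels cluster around a reddish mean color and whose
#' "coating" pixels cluster around a paler, yellower mean color. Texture is a
#' luminance-correlated gray variation shared across channels; noise is
#' i.i.d. Gaussian per channel. Defaults give clear chrominance separation
#' (body a* around +24, coating a* around -1).
#'
#' @param height,width Image size in pixels.
#' @param body_color,coating_color Mean region colors, 8-bit RGB triples.
#' @param coating_fraction Fraction of the tongue area covered by coating,
#'   in [0, 1].
#' @param texture_amplitude Standard deviation of the per-pixel gray-level
#'   variation added identically to all three channels.
#' @param noise_sigma Standard deviation of additive i.i.d. Gaussian noise
#'   per channel.
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical images.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 64, width = 64,
                           body_color = c(180, 120, 120),
                           coating_color = c(210, 200, 170),
                           coating_fraction = 0.3,
                           texture_amplitude = 5,
                           noise_sigma = 3,
                           seed = 1) {
  if (height <= 0 || width <= 0) stop("image dimensions must be positive")
  if (coating_fraction < 0 || coating_fraction > 1) {
    stop("coating_fraction must lie in [0, 1]")
  }
  check_rgb8 <- function(v, nm) {
    if (length(v) != 3 || any(v < 0) || any(v > 255)) {
      stop(sprintf("%s must be an 8-bit RGB triple", nm))
    }
  }
  check_rgb8(body_color, "body_color")
  check_rgb8(coating_color, "coating_color")
  structure(list(height = height, width = width,
                 body_color = body_color, coating_color = coating_color,
                 coating_fraction = coating_fraction,
                 texture_amplitude = texture_amplitude,
                 noise_sigma = noise_sigma, seed = seed),
            class = "synthetic_spec")
}

#' Construct a tongue image object
#'
#' @param pixels H x W x 3 array of 8-bit intensities (values in [0, 255]).
#' @param tongue_mask H x W logical matrix, TRUE on tongue pixels. Pixels
#'   outside the mask are ignored by all feature operations.
#' @return An object of class `tongue_image`.
#' @export
tongue_image <- function(pixels, tongue_mask) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  tongue_mask <- tongue_mask > 0
  stopifnot(identical(dim(tongue_mask), dim(pixels)[1:2]))
  if (!any(tongue_mask)) stop("tongue_mask must be nonempty")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, tongue_mask = tongue_mask),
            class = "tongue_image")
}

#' @export
print.tongue_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tongue_image> %d x %d, %d tongue pixels (%.1f%%)\n",
              d[1], d[2], sum(x$tongue_mask),
              100 * mean(x$tongue_mask)))
  invisible(x)
}

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

#' Generate a synthetic tongue image with ground-truth masks
#'
#' The tongue region is an ellipse inscribed in the frame; the coating is a
#' second ellipse centered in the upper half of the tongue whose size is
#' solved by bisection so the coating covers (as closely as the pixel grid
#' allows) the requested fraction of the tongue area. Per-region pixel colors
#' are the region mean plus shared-channel texture and per-channel noise,
#' clipped to [0, 255] and rounded.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `image` (a [tongue_image()]), `body_mask` and
#'   `coating_mask` (logical matrices). The two masks partition the tongue
#'   mask: their union is the tongue region and their intersection is empty.
#' @export
make_tongue_image <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  tongue <- ellipse_mask(h, w, cy, cx, max(h / 2 - 1, 0.5), max(w / 2 - 1, 0.5))
  if (!any(tongue)) tongue[round(cy), round(cx)] <- TRUE
  n_tongue <- sum(tongue)

  frac <- spec$coating_fraction
  if (frac <= 0) {
    coating <- tongue & FALSE
  } else if (frac >= 1) {
    coating <- tongue
  } else {
    # coating ellipse centered in the upper half; bisect its scale until the
    # covered tongue fraction matches the request on the pixel grid
    ccy <- cy - h / 6
    shape_ry <- h / 2; shape_rx <- w / 2
    cover <- function(s) {
      sum(ellipse_mask(h, w, ccy, cx, s * shape_ry, s * shape_rx) & tongue) /
        n_tongue
    }
    lo <- 0; hi <- 3
    for (i in 1:48) {
      mid <- (lo + hi) / 2
      if (cover(mid) < frac) lo <- mid else hi <- mid
    }
    coating <- ellipse_mask(h, w, ccy, cx, hi * shape_ry, hi * shape_rx) & tongue
  }
  body <- tongue & !coating

  px <- with_seed(spec$seed, {
    a <- array(40, dim = c(h, w, 3))
    for (region in list(list(mask = body, col = spec$body_color),
                        list(mask = coating, col = spec$coating_color))) {
      n <- sum(region$mask)
      if (n == 0) next
      tex <- stats::rnorm(n, 0, spec$texture_amplitude)
      for (ch in 1:3) {
        noise <- stats::rnorm(n, 0, spec$noise_sigma)
        plane <- a[, , ch]
        plane[region$mask] <- region$col[ch] + tex + noise
        a[, , ch] <- plane
      }
    }
    round(clip255(a))
  })

  list(image = tongue_image(px, tongue),
       body_mask = body, coating_mask = coating)
}

#' Specification for a synthetic labeled feature table
#'
#' Two Gaussian classes in `n_features` dimensions whose means are separated
#' by Euclidean distance `class_separation` (unit isotropic covariance).
#' Defaults emulate the 296/531 class imbalance of a diabetic vs. nondiabetic
#' cohort.
#'
#' @param n_minority,n_majority Class sample counts (minority is labeled 1,
#'   the diabetes-analog class).
#' @param n_features Feature dimensionality.
#' @param class_separation Distance between the class means; 0 makes the
#'   classes indistinguishable.
#' @param seed Integer seed.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_minority = 296, n_majority = 531,
                         n_features = 10, class_separation = 2, seed = 1) {
  if (n_minority < 1 || n_majority < 1) stop("class counts must be >= 1")
  if (n_features < 1) stop("n_features must be >= 1")
  if (class_separation < 0) stop("class_separation must be >= 0")
  structure(list(n_minority = n_minority, n_majority = n_majority,
                 n_features = n_features,
                 class_separation = class_separation, seed = seed),
            class = "dataset_spec")
}

#' Generate a labeled two-class Gaussian feature table
#'
#' @param spec A [dataset_spec()].
#' @return A data.frame with columns `feat_1 ... feat_k` and an integer
#'   `label` column (1 = minority/diabetes-analog class, 0 = majority).
#' @export
make_feature_dataset <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "dataset_spec"))
  p <- spec$n_features
  shift <- spec$class_separation / sqrt(p)
  with_seed(spec$seed, {
    x0 <- matrix(stats::rnorm(spec$n_majority * p), ncol = p)
    x1 <- matrix(stats::rnorm(spec$n_minority * p), ncol = p) + shift
    x <- rbind(x0, x1)
    colnames(x) <- paste0("feat_", seq_len(p))
    df <- as.data.frame(x)
    df$label <- c(rep(0L, spec$n_majority), rep(1L, spec$n_minority))
    df
  })
}

#' Write / read a binary mask as single-channel PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write / read a tongue image as PNG (plus its mask)
#'
#' @param img A [tongue_image()].
#' @param image_path,mask_path Output paths.
#' @export
write_tongue_png <- function(img, image_path, mask_path = NULL) {
  png::writePNG(img$pixels / 255, image_path)
  if (!is.null(mask_path)) write_mask_png(img$tongue_mask, mask_path)
  invisible(image_path)
}

#' @rdname write_tongue_png
#' @param full_mask If no mask file is given, treat every pixel as tongue.
#' @export
read_tongue_png <- function(image_path, mask_path = NULL, full_mask = is.null(mask_path)) {
  a <- png::readPNG(image_path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  px <- round(a * 255)
  mask <- if (is.null(mask_path)) {
    if (!full_mask) stop("mask_path required when full_mask = FALSE")
    matrix(TRUE, dim(px)[1], dim(px)[2])
  } else read_mask_png(mask_path)
  tongue_image(px, mask)
}
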