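#' RGB to HSI conversion (arccos hue formulation)
#'
#' Converts RGB triples with components in [0, 1] to hue-saturation-intensity.
#' Intensity is the channel mean, saturation is `1 - 3 min(R,G,B)/(R+G+B)`,
#' and hue comes from the arccos formulation, reflected to (180, 360) degrees
#' when B > G. Achromatic inputs (R = G = B, including black) take H = 0 by
#' convention; black additionally takes S = 0.
#'
#' @param rgb Numeric triple or N x 3 matrix, components in [0, 1].
#' @return A named vector (H, S, I) or an N x 3 matrix. H in degrees
#'   [0, 360); S and I in [0, 1].
#' @export
rgb_to_hsi <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (ncol(m) != 3) stop("rgb must have 3 components")
  if (min(m) < -1e-12 || max(m) > 1 + 1e-12) stop("rgb components must lie in [0, 1]")
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  s <- r + g + b
  i <- s / 3
  sat <- ifelse(s > 0, 1 - 3 * pmin(r, g, b) / s, 0)
  num <- ((r - g) + (r - b)) / 2
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1)) * 180 / pi
  h <- ifelse(den > 0, ifelse(b > g, 360 - theta, theta), 0)
  out <- cbind(H = h, S = sat, I = i)
  if (is.matrix(rgb)) out else out[1, ]
}

#' HSI to RGB conversion (sector formulation)
#'
#' Inverse of [rgb_to_hsi()]; exact for non-achromatic colors.
#'
#' @param hsi Numeric triple (H degrees, S, I) or N x 3 matrix.
#' @return RGB with components in [0, 1].
#' @export
hsi_to_rgb <- function(hsi) {
  m <- if (is.matrix(hsi)) hsi else matrix(hsi, ncol = 3)
  h <- m[, 1] %% 360; s <- m[, 2]; i <- m[, 3]
  sector <- floor(h / 120)
  hs <- (h - 120 * sector) * pi / 180
  x <- i * (1 - s)
  y <- i * (1 + s * cos(hs) / cos(pi / 3 - hs))
  z <- 3 * i - x - y
  r <- ifelse(sector == 0, y, ifelse(sector == 1, x, z))
  g <- ifelse(sector == 0, z, ifelse(sector == 1, y, x))
  b <- ifelse(sector == 0, x, ifelse(sector == 1, z, y))
  out <- cbind(R = r, G = g, B = b)
  if (is.matrix(hsi)) out else out[1, ]
}

# sRGB (D65) linear RGB -> XYZ (BT.709 primaries, 6-digit coefficients)
.srgb2xyz <- matrix(c(0.412453, 0.357580, 0.180423,
                      0.212671, 0.715160, 0.072169,
                      0.019334, 0.119193, 0.950227),
                    nrow = 3, byrow = TRUE)
.d65 <- c(X = 0.95047, Y = 1, Z = 1.08883)

#' RGB (8-bit sRGB) to CIELAB conversion
#'
#' Applies sRGB gamma expansion, the linear-RGB to XYZ transform under the
#' D65 white point, and the CIE 1976 L*a*b* piecewise cube-root function.
#'
#' @param rgb 8-bit triple (components in [0, 255]) or N x 3 matrix.
#' @return Named vector (L, a, b) or N x 3 matrix; L in [0, 100].
#' @export
rgb_to_lab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (ncol(m) != 3) stop("rgb must have 3 components")
  if (min(m) < 0 || max(m) > 255) stop("rgb components must lie in [0, 255]")
  s <- m / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  tnorm <- sweep(xyz, 2, .d65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(tnorm > eps, tnorm^(1 / 3), tnorm / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (is.matrix(rgb)) out else out[1, ]
}

#' Per-region mean color in RGB, HSI and CIELAB
#'
#' Averages pixel colors in RGB over the masked region first, then transforms
#' the single mean color to HSI and CIELAB (mean-then-transform). The
#' alternative (transform each pixel, then average) is available via
#' `per_pixel = TRUE`.
#'
#' @param image A [tongue_image()].
#' @param mask Logical matrix selecting the region (intersected with the
#'   tongue mask).
#' @param per_pixel If TRUE, transform each pixel first and average the
#'   transformed values instead (not the default).
#' @return Named numeric vector: `rgb_R, rgb_G, rgb_B` (8-bit scale),
#'   `hsi_H` (degrees), `hsi_S`, `hsi_I` ([0,1]), `lab_L`, `lab_a`, `lab_b`.
#'   All NA (with a `missing` attribute) when the mask is empty, since a
#'   tongue may carry no coating at all.
#' @export
region_color_means <- function(image, mask, per_pixel = FALSE) {
  stopifnot(inherits(image, "tongue_image"))
  mask <- (mask > 0) & image$tongue_mask
  nm <- c("rgb_R", "rgb_G", "rgb_B", "hsi_H", "hsi_S", "hsi_I",
          "lab_L", "lab_a", "lab_b")
  if (!any(mask)) {
    out <- stats::setNames(rep(NA_real_, 9), nm)
    attr(out, "missing") <- TRUE
    return(out)
  }
  px <- cbind(image$pixels[, , 1][mask],
              image$pixels[, , 2][mask],
              image$pixels[, , 3][mask])
  if (per_pixel) {
    hsi <- colMeans(rgb_to_hsi(px / 255))
    lab <- colMeans(rgb_to_lab(px))
    mu <- colMeans(px)
  } else {
    mu <- colMeans(px)
    hsi <- rgb_to_hsi(mu / 255)
    lab <- rgb_to_lab(mu)
  }
  stats::setNames(c(mu, hsi, lab), nm)
}
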