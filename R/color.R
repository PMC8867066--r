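#' sRGB to CIE L*a*b* conversion
#'
#' Converts sRGB values (D65 white point, 2 degree observer) to CIE L*a*b*.
#' The usual chain is applied: inverse sRGB companding, linear RGB to XYZ
#' (IEC 61966-2-1 matrix), XYZ to L*a*b* with the standard f() including the
#' linear segment below (6/29)^3.
#'
#' @param rgb numeric vector of length 3, or an n x 3 matrix, in \[0, 1\].
#' @return matrix (n x 3) with columns L, a, b; a vector input returns a
#'   length-3 named vector.
#' @export
srgb_to_lab <- function(rgb) {
  vec_in <- is.null(dim(rgb))
  m <- if (vec_in) matrix(rgb, ncol = 3) else as.matrix(rgb)
  stopifnot(ncol(m) == 3)
  # inverse companding
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  # D65 reference white
  wp <- c(0.95047, 1.00000, 1.08883)
  xyz <- sweep(xyz, 2, wp, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (vec_in) out[1, ] else out
}

#' Mean CIE L*a*b* color of an image region
#'
#' Per the set-to-0 convention for undetectable regions, an empty mask
#' returns (0, 0, 0) rather than an error.
#'
#' @param image H x W x 3 array, sRGB in \[0, 1\].
#' @param mask logical matrix matching the image plane.
#' @return named numeric vector (L, a, b).
#' @export
mean_lab <- function(image, mask) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(image)[1:2] == dim(mask)))
  if (!any(mask)) return(c(L = 0, a = 0, b = 0))
  idx <- which(mask)
  n <- prod(dim(mask))
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  lab <- srgb_to_lab(rgb)
  c(L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]))
}
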