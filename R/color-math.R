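## sRGB <-> CIE L*u*v* conversion, D65 white point, 2-degree observer.
## Rasters are numeric arrays of dim c(h, w, 3); pixel matrices are n x 3.

.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# D65 reference white taken as the matrix's own row sums (XYZ of RGB
# (1,1,1)), so grays map to exactly u* = v* = 0
.XYZ_D65 <- c(X = sum(.srgb_to_xyz_mat[1, ]), Y = sum(.srgb_to_xyz_mat[2, ]),
              Z = sum(.srgb_to_xyz_mat[3, ]))

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

.uv_prime <- function(X, Y, Z) {
  d <- X + 15 * Y + 3 * Z
  d[d == 0] <- 1 # achromatic black: u', v' conventionally at white point below
  list(u = 4 * X / d, v = 9 * Y / d)
}

.UVN <- {
  w <- .uv_prime(.XYZ_D65[1], .XYZ_D65[2], .XYZ_D65[3])
  c(u = unname(w$u), v = unname(w$v))
}

.as_pixel_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3) return(list(m = x, dim = NULL))
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3) {
    d <- dim(x)
    return(list(m = matrix(x, ncol = 3), dim = d))
  }
  if (is.numeric(x) && length(x) == 3) return(list(m = matrix(x, ncol = 3), dim = NULL))
  stop("expected an n x 3 pixel matrix, a length-3 pixel, or an h x w x 3 raster", call. = FALSE)
}

.restore_shape <- function(m, d) {
  if (is.null(d)) m else array(m, dim = d)
}

#' Convert 8-bit sRGB values to CIE L*u*v*
#'
#' Channels are interpreted as sRGB (IEC 61966-2-1) with a D65 white point.
#' Input may be a length-3 pixel, an n x 3 matrix, or an h x w x 3 raster;
#' the output has the same shape with columns/planes (L, u, v).
#'
#' @param rgb numeric values in \[0, 255\].
#' @return same-shaped numeric object holding L* in \[0, 100\] and the
#'   unbounded chromaticity coordinates u*, v*.
#' @export
srgb_to_luv <- function(rgb) {
  p <- .as_pixel_matrix(rgb)
  m <- p$m
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255)) {
    stop("RGB channels must be finite and within [0, 255]", call. = FALSE)
  }
  s <- m / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz_mat)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  yr <- Y / .XYZ_D65[["Y"]]
  eps <- (6 / 29)^3
  L <- ifelse(yr > eps, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  uv <- .uv_prime(X, Y, Z)
  u <- 13 * L * (uv$u - .UVN[["u"]])
  v <- 13 * L * (uv$v - .UVN[["v"]])
  # L = 0 pixels carry no chromatic information
  u[L == 0] <- 0
  v[L == 0] <- 0
  .restore_shape(cbind(L, u, v, deparse.level = 0), p$dim)
}

#' Convert CIE L*u*v* back to 8-bit sRGB
#'
#' Out-of-gamut pixels are clipped channel-wise and counted; the count is
#' attached as attribute `gamut_clip_count` (and the per-pixel flag as
#' `gamut_clipped` when `flag_pixels = TRUE`). Channels are quantized to
#' integers unless `quantize = FALSE`.
#'
#' @param luv numeric pixel/matrix/raster of (L, u, v) values.
#' @param quantize round channels to integers (default TRUE).
#' @param flag_pixels attach a logical vector marking clipped pixels.
#' @return RGB object of the same shape, channels in \[0, 255\].
#' @export
luv_to_srgb <- function(luv, quantize = TRUE, flag_pixels = FALSE) {
  p <- .as_pixel_matrix(luv)
  m <- p$m
  L <- m[, 1]; u <- m[, 2]; v <- m[, 3]
  yr <- ifelse(L > 8, ((L + 16) / 116)^3, L * (3 / 29)^3)
  Y <- yr * .XYZ_D65[["Y"]]
  safeL <- ifelse(L == 0, 1, L)
  up <- u / (13 * safeL) + .UVN[["u"]]
  vp <- v / (13 * safeL) + .UVN[["v"]]
  X <- Y * (9 * up) / (4 * vp)
  Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
  X[L == 0] <- 0; Z[L == 0] <- 0
  lin <- cbind(X, Y, Z, deparse.level = 0) %*% t(.xyz_to_srgb_mat)
  clipped <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  s <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- s * 255
  if (quantize) out <- round(out)
  out <- .restore_shape(out, p$dim)
  attr(out, "gamut_clip_count") <- sum(clipped)
  if (flag_pixels) attr(out, "gamut_clipped") <- clipped
  out
}

#' CIELUV chroma (saturation)
#'
#' Euclidean distance from the achromatic axis, sqrt(u^2 + v^2) — the
#' saturation measure used for calibration.
#'
#' @param u,v chromaticity coordinates, or `u` may be a (L,u,v) matrix/raster.
#' @return non-negative chroma values.
#' @export
luv_chroma <- function(u, v = NULL) {
  if (is.null(v)) {
    p <- .as_pixel_matrix(u)
    return(sqrt(p$m[, 2]^2 + p$m[, 3]^2))
  }
  sqrt(u^2 + v^2)
}

#' Shift-and-shrink values to a target mean within bounds
#'
#' Adds a constant to the masked values so their mean equals `target`; if any
#' adjusted value then falls outside `bounds`, the deviations about the mean
#' are multiplied by the largest admissible shrink factor in (0, 1\] so that
#' every masked value lies within bounds while the mean stays exactly on
#' target. Unmasked values are untouched.
#'
#' @param values numeric vector.
#' @param mask logical vector selecting the values to adjust (default all).
#' @param target desired mean of the masked values.
#' @param bounds length-2 numeric interval the adjusted values must lie in.
#' @return list with `values` (adjusted vector), `shrink` (scalar factor
#'   applied to deviations; 1 when no shrinkage was needed).
#' @export
equate_channel_mean <- function(values, mask = NULL, target, bounds) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  if (length(mask) != length(values)) {
    stop("mask length must match values length", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no values", call. = FALSE)
  if (target < bounds[1] || target > bounds[2]) {
    stop("target mean lies outside the permissible bounds", call. = FALSE)
  }
  x <- values[mask]
  dev <- x - mean(x)
  # Largest s in (0,1] with target + s*dev inside bounds for all pixels:
  # the feasible set is an interval [0, s_max], so s_max has a closed form.
  lo <- bounds[1] - target
  hi <- bounds[2] - target
  s <- 1
  pos <- dev > 0
  neg <- dev < 0
  if (any(pos)) s <- min(s, hi / max(dev[pos]))
  if (any(neg)) s <- min(s, lo / min(dev[neg]))
  s <- max(s, 0)
  out <- values
  out[mask] <- target + s * dev
  list(values = out, shrink = s)
}

#' Rotate hue in the (u, v) chromaticity plane
#'
#' Applies a 2-D rotation of angle `angle` (degrees, counterclockwise) to the
#' (u, v) coordinates of every pixel; L is untouched. Chroma is preserved.
#'
#' @param luv (L,u,v) pixel/matrix/raster.
#' @param angle rotation angle in degrees.
#' @return object of the same shape.
#' @export
rotate_hue <- function(luv, angle) {
  p <- .as_pixel_matrix(luv)
  m <- p$m
  th <- angle * pi / 180
  u <- m[, 2] * cos(th) - m[, 3] * sin(th)
  v <- m[, 2] * sin(th) + m[, 3] * cos(th)
  .restore_shape(cbind(m[, 1], u, v, deparse.level = 0), p$dim)
}

#' Desaturate: drop all chromatic content
#'
#' Sets u = v = 0 everywhere while keeping L bitwise identical.
#'
#' @param luv (L,u,v) pixel/matrix/raster.
#' @return achromatic object of the same shape.
#' @export
desaturate <- function(luv) {
  p <- .as_pixel_matrix(luv)
  m <- p$m
  .restore_shape(cbind(m[, 1], 0, 0, deparse.level = 0), p$dim)
}
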