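## A hue/saturation/luminance parameterization computed directly over RGB,
## designed around operations available to convolutional kernels:
##   lum = mean(R, G, B)
##   sat = Euclidean RGB distance to the neutral gray of equal lum
##   hue = angle on the circle of constant (lum, sat) in the RGB cube,
##         with 0 degrees at the point of maximal R, increasing toward G.

# Orthonormal basis of the plane R + G + B = const. e1 points toward max R;
# e2 completes the right-handed frame so hue grows in the R -> G direction.
.SHSV_E1 <- c(2, -1, -1) / sqrt(6)
.SHSV_E2 <- c(0, 1, -1) / sqrt(2)

#' Decompose RGB into synthetic HSV coordinates
#'
#' @param rgb length-3 pixel, n x 3 matrix, or h x w x 3 raster of values in
#'   \[0, 255\] (real-valued inputs accepted).
#' @return list with `lum` (mean of channels), `sat` (distance to equal-lum
#'   gray), `hue` (degrees in \[0, 360)), and `hue_defined` (FALSE where
#'   sat = 0, hue is then reported as 0 but carries no information).
#' @export
synthetic_hsv_decompose <- function(rgb) {
  p <- .as_pixel_matrix(rgb)
  m <- p$m
  lum <- rowMeans(m)
  d <- m - lum
  sat <- sqrt(rowSums(d^2))
  a <- d %*% .SHSV_E1
  b <- d %*% .SHSV_E2
  hue <- (atan2(b, a) * 180 / pi) %% 360
  defined <- sat > 0
  hue[!defined] <- 0
  list(lum = lum, sat = sat, hue = as.numeric(hue), hue_defined = defined)
}

#' Maximal admissible synthetic-HSV saturation
#'
#' Largest `sat` such that the whole iso-(lum, sat) circle stays inside the
#' RGB cube at the given luminance.
#'
#' @param lum luminance (mean RGB), in \[0, 255\].
#' @return non-negative saturation bound.
#' @export
synthetic_hsv_max_sat <- function(lum) {
  # Channel value along the circle: lum + sat * c(theta) with c in [-sqrt(2/3),
  # sqrt(2/3)] (extremes of the basis coordinates). Constraints 0 <= ch <= 255.
  amp <- sqrt(2 / 3)
  pmax(0, pmin(lum, 255 - lum) / amp)
}

#' Compose an RGB triplet from synthetic HSV coordinates
#'
#' The result is real-valued (pre-quantization): mean of channels equals `lum`
#' exactly and the distance to the equal-lum gray equals `sat` exactly.
#'
#' @param hue degrees; 0 yields the circle point maximizing R.
#' @param sat saturation (RGB-distance units), >= 0.
#' @param lum luminance (mean RGB), in \[0, 255\].
#' @param require_full_circle error when the whole iso-(lum, sat) circle
#'   exits the cube — the condition calibration needs so that every hue is
#'   representable (default FALSE: only the requested point must be inside).
#' @param strict error when the requested point itself leaves the cube
#'   (default TRUE); `strict = FALSE` returns the raw point for the caller
#'   to clip and count.
#' @return n x 3 matrix of real-valued RGB channels.
#' @export
synthetic_hsv_compose <- function(hue, sat, lum, require_full_circle = FALSE,
                                  strict = TRUE) {
  n <- max(length(hue), length(sat), length(lum))
  hue <- rep_len(hue, n); sat <- rep_len(sat, n); lum <- rep_len(lum, n)
  if (any(sat < 0)) stop("saturation must be non-negative", call. = FALSE)
  if (require_full_circle) {
    smax <- synthetic_hsv_max_sat(lum)
    bad <- sat > smax + 1e-9
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "iso-luminance circle exits the RGB cube: sat %.3f at lum %.3f exceeds the maximal admissible sat %.3f",
        sat[i], lum[i], smax[i]
      ), call. = FALSE)
    }
  }
  th <- hue * pi / 180
  dir <- cbind(cos(th)) %*% rbind(.SHSV_E1) + cbind(sin(th)) %*% rbind(.SHSV_E2)
  out <- lum + sat * dir
  if (strict && any(out < -1e-9 | out > 255 + 1e-9)) {
    stop("requested synthetic-HSV point lies outside the RGB cube", call. = FALSE)
  }
  colnames(out) <- c("r", "g", "b")
  out
}
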