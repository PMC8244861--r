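## Calibrated stimulus construction: textured recolorings, silhouettes,
## grayscale versions, oriented bars, and the dissimilar-subset selection.

#' Calibration target
#'
#' The common mean luminance and mean saturation every stimulus must reach
#' over its non-background pixels, together with the color space in which
#' both are measured.
#'
#' @param space `"cieluv"` (L* / chroma units) or `"synthetic_hsv"`
#'   (mean-RGB / RGB-distance units).
#' @param lum target mean luminance (L* in 0-100, or mean RGB in 0-255).
#' @param sat target mean saturation (chroma, or RGB distance), >= 0.
#' @return a `calibration_target` object.
#' @export
calibration_target <- function(space = c("cieluv", "synthetic_hsv"),
                               lum = 65, sat = 35) {
  space <- match.arg(space)
  if (lum < 0 || sat < 0) stop("calibration targets must be non-negative", call. = FALSE)
  structure(list(space = space, lum = lum, sat = sat),
            class = "calibration_target")
}

#' Synthetic-HSV targets matched to a CIELUV calibration
#'
#' Picks, among the 12 calibrated CIELUV hues, the composed RGB with the
#' highest red channel, and returns its synthetic-HSV luminance/saturation as
#' a matched calibration target, keeping overall levels in a similar range.
#'
#' @param cieluv_target a CIELUV `calibration_target`.
#' @param n_hues number of evenly spaced hues (default 12).
#' @return a synthetic-HSV `calibration_target`.
#' @export
synthetic_targets_from_cieluv <- function(cieluv_target, n_hues = 12) {
  stopifnot(cieluv_target$space == "cieluv")
  angles <- hue_angles(n_hues)
  luv <- cbind(cieluv_target$lum,
               cieluv_target$sat * cos(angles * pi / 180),
               cieluv_target$sat * sin(angles * pi / 180))
  rgb <- luv_to_srgb(luv, quantize = FALSE)
  best <- which.max(rgb[, 1])
  dec <- synthetic_hsv_decompose(rgb[best, , drop = FALSE])
  calibration_target("synthetic_hsv", lum = dec$lum, sat = dec$sat)
}

#' Evenly spaced hue angles
#'
#' @param n_hues number of hues around the 360-degree circle.
#' @return numeric vector of degrees, starting at 0.
#' @export
hue_angles <- function(n_hues = 12) {
  seq(0, 360, length.out = n_hues + 1)[seq_len(n_hues)]
}

#' Background mask of a near-white-background object image
#'
#' A pixel is background iff all three channels are at or above the
#' near-white threshold; the mask marks the complement (the object).
#'
#' @param raster h x w x 3 RGB array, channels 0-255.
#' @param threshold near-white channel threshold (default 250; JPEG artifacts
#'   make an exact-255 test fragile).
#' @return logical h x w matrix, TRUE on object pixels.
#' @export
background_mask <- function(raster, threshold = 250) {
  bg <- raster[, , 1] >= threshold & raster[, , 2] >= threshold &
    raster[, , 3] >= threshold
  if (all(bg)) stop("image contains no object pixels (all background)", call. = FALSE)
  !bg
}

# Calibrate the masked pixels of an image in LUV space: shift-and-shrink L to
# the target, then chroma, keeping per-pixel hue. Returns the calibrated LUV
# raster plus shrink diagnostics.
.calibrate_luv <- function(raster, mask, target) {
  luv <- srgb_to_luv(raster)
  h <- dim(raster)[1]; w <- dim(raster)[2]
  L <- matrix(luv[, , 1], h, w); U <- matrix(luv[, , 2], h, w)
  V <- matrix(luv[, , 3], h, w)
  mv <- as.vector(mask)
  eqL <- equate_channel_mean(as.vector(L), mv, target$lum, c(0, 100))
  C <- sqrt(U^2 + V^2)
  eqC <- equate_channel_mean(as.vector(C), mv, target$sat, c(0, Inf))
  C2 <- matrix(eqC$values, h, w)
  # unit hue direction per pixel; achromatic pixels (incl. numerically
  # achromatic grays) point at hue 0
  chromatic <- C > 1e-9
  safe <- pmax(C, .Machine$double.eps)
  du <- ifelse(chromatic, U / safe, 1)
  dv <- ifelse(chromatic, V / safe, 0)
  out <- array(0, dim = c(h, w, 3))
  out[, , 1] <- matrix(eqL$values, h, w)
  out[, , 2] <- ifelse(mask, C2 * du, U)
  out[, , 3] <- ifelse(mask, C2 * dv, V)
  # background keeps its original L too
  out[, , 1][!mask] <- L[!mask]
  list(luv = out, shrink_lum = eqL$shrink, shrink_sat = eqC$shrink)
}

.stimulus <- function(object_id, hue_index, variant, raster, calibration,
                      audit = NULL) {
  structure(list(object_id = object_id, hue_index = hue_index,
                 variant = variant, raster = raster,
                 calibration = calibration, audit = audit),
            class = "chromaform_stimulus")
}

#' Recolor an object image in n evenly spaced calibrated hues
#'
#' Equates the masked mean luminance and saturation to the calibration
#' targets (shift, then shrink deviations on overflow), then produces one
#' stimulus per hue by rotating every pixel's hue coordinate to each of the
#' evenly spaced angles. The relative luminance/saturation pattern of the
#' original image is preserved up to the shrink factors, so internal texture
#' survives recoloring.
#'
#' @param raster h x w x 3 RGB array (0-255) on a near-white background.
#' @param object_id identifier recorded in the output.
#' @param calibration a [calibration_target()].
#' @param n_hues number of hues (default 12).
#' @param mask optional logical object mask; computed by [background_mask()]
#'   when missing.
#' @return list of `chromaform_stimulus` objects, one per hue.
#' @export
calibrate_and_recolor <- function(raster, object_id, calibration,
                                  n_hues = 12, mask = NULL) {
  if (is.null(mask)) mask <- background_mask(raster)
  angles <- hue_angles(n_hues)
  if (calibration$space == "cieluv") {
    cal <- .calibrate_luv(raster, mask, calibration)
    lapply(seq_along(angles), function(i) {
      rot <- rotate_hue(cal$luv, angles[i])
      rgb <- luv_to_srgb(rot)
      rgb[, , 1][!mask] <- raster[, , 1][!mask]
      rgb[, , 2][!mask] <- raster[, , 2][!mask]
      rgb[, , 3][!mask] <- raster[, , 3][!mask]
      .stimulus(object_id, i - 1L, "textured", rgb, calibration,
                audit = list(shrink_lum = cal$shrink_lum,
                             shrink_sat = cal$shrink_sat,
                             gamut_clip_count = attr(rgb, "gamut_clip_count")))
    })
  } else {
    .recolor_synthetic_hsv(raster, object_id, calibration, angles, mask)
  }
}

.recolor_synthetic_hsv <- function(raster, object_id, calibration, angles, mask) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  px <- matrix(raster, ncol = 3)
  dec <- synthetic_hsv_decompose(px)
  mv <- as.vector(mask)
  eqL <- equate_channel_mean(dec$lum, mv, calibration$lum, c(0, 255))
  eqS <- equate_channel_mean(dec$sat, mv, calibration$sat, c(0, Inf))
  lapply(seq_along(angles), function(i) {
    hue <- (dec$hue + angles[i]) %% 360
    rgb <- synthetic_hsv_compose(hue, eqS$values, eqL$values, strict = FALSE)
    clipped <- sum(rowSums(rgb < -1e-9 | rgb > 255 + 1e-9) > 0 & mv)
    rgb <- pmin(pmax(rgb, 0), 255)
    out <- array(round(rgb), dim = c(h, w, 3))
    for (ch in 1:3) out[, , ch][!mask] <- raster[, , ch][!mask]
    .stimulus(object_id, i - 1L, "textured", out, calibration,
              audit = list(shrink_lum = eqL$shrink, shrink_sat = eqS$shrink,
                           gamut_clip_count = clipped))
  })
}

#' Uniform calibrated fill color for a hue index
#'
#' The single RGB triplet whose luminance and saturation sit exactly on the
#' calibration targets at the given hue angle — the fill used by silhouettes
#' and bars, identical across objects.
#'
#' @param hue_index 0-based hue index.
#' @param calibration a [calibration_target()].
#' @param n_hues number of hues on the circle.
#' @param quantize round to integer channels (default TRUE).
#' @return length-3 RGB vector.
#' @export
calibrated_fill_color <- function(hue_index, calibration, n_hues = 12,
                                  quantize = TRUE) {
  ang <- hue_angles(n_hues)[hue_index + 1L]
  if (calibration$space == "cieluv") {
    luv <- matrix(c(calibration$lum,
                    calibration$sat * cos(ang * pi / 180),
                    calibration$sat * sin(ang * pi / 180)), ncol = 3)
    rgb <- luv_to_srgb(luv, quantize = quantize)
    if (attr(rgb, "gamut_clip_count") > 0) {
      stop("calibration targets are out of the sRGB gamut at hue ", ang, call. = FALSE)
    }
    as.numeric(rgb)
  } else {
    rgb <- synthetic_hsv_compose(ang, calibration$sat, calibration$lum,
                                 require_full_circle = TRUE)
    if (quantize) rgb <- round(rgb)
    as.numeric(rgb)
  }
}

#' Uniform-color silhouette stimulus
#'
#' Replaces every object (non-background) pixel with the single calibrated
#' fill color for the requested hue; background pixels are untouched.
#'
#' @inheritParams calibrate_and_recolor
#' @param hue_index 0-based hue index.
#' @return a `chromaform_stimulus`.
#' @export
make_silhouette <- function(raster, object_id, hue_index, calibration,
                            mask = NULL) {
  if (is.null(mask)) mask <- background_mask(raster)
  fill <- calibrated_fill_color(hue_index, calibration)
  out <- raster
  for (ch in 1:3) out[, , ch][mask] <- fill[ch]
  .stimulus(object_id, as.integer(hue_index), "silhouette", out, calibration)
}

#' Grayscale (achromatic) stimulus
#'
#' Calibrates the masked mean luminance to target, then removes all chromatic
#' content (u = v = 0) while preserving the luminance pattern.
#'
#' @inheritParams calibrate_and_recolor
#' @return a `chromaform_stimulus` with `hue_index = NA`.
#' @export
make_grayscale <- function(raster, object_id, calibration, mask = NULL) {
  if (is.null(mask)) mask <- background_mask(raster)
  if (calibration$space != "cieluv") {
    stop("grayscale stimuli are defined in CIELUV", call. = FALSE)
  }
  cal <- .calibrate_luv(raster, mask, calibration)
  rgb <- luv_to_srgb(desaturate(cal$luv))
  for (ch in 1:3) rgb[, , ch][!mask] <- raster[, , ch][!mask]
  .stimulus(object_id, NA_integer_, "grayscale", rgb, calibration,
            audit = list(shrink_lum = cal$shrink_lum))
}

#' Oriented-bar specification
#'
#' @param canvas_px square canvas side (default 400).
#' @param length_px,width_px bar dimensions (defaults 300 x 60).
#' @param n_orientations orientations evenly spaced on the 0-180 degree
#'   circle, endpoint excluded (default 12, i.e. 15-degree steps).
#' @return a `bar_spec` object.
#' @export
bar_spec <- function(canvas_px = 400, length_px = 300, width_px = 60,
                     n_orientations = 12) {
  half_diag <- sqrt(length_px^2 + width_px^2) / 2
  if (half_diag > canvas_px / 2) {
    stop("bar does not fit inside the canvas at every orientation", call. = FALSE)
  }
  structure(list(canvas_px = canvas_px, length_px = length_px,
                 width_px = width_px, n_orientations = n_orientations),
            class = "bar_spec")
}

#' Orientation angles of a bar spec
#' @param spec a [bar_spec()].
#' @return degrees in \[0, 180).
#' @export
bar_orientations <- function(spec) {
  seq(0, 180, length.out = spec$n_orientations + 1)[seq_len(spec$n_orientations)]
}

# Analytic rasterization: a pixel belongs to the bar iff its center lies in
# the rotated rectangle. No raster rotation, so areas match across
# orientations up to discretization.
.bar_mask <- function(spec, orientation_deg) {
  n <- spec$canvas_px
  c0 <- (n + 1) / 2
  xy <- expand.grid(y = seq_len(n) - c0, x = seq_len(n) - c0)
  th <- orientation_deg * pi / 180
  # rotate pixel offsets into the bar frame (x along bar length)
  xr <- xy$x * cos(th) + xy$y * sin(th)
  yr <- -xy$x * sin(th) + xy$y * cos(th)
  m <- abs(xr) <= spec$length_px / 2 & abs(yr) <= spec$width_px / 2
  matrix(m, nrow = n)
}

#' Generate the full oriented-bar stimulus grid
#'
#' Orientations x hues factorial grid of uniformly filled bars on a white
#' canvas, each bar drawn analytically (point-in-rotated-rectangle) and
#' filled with the calibrated color for its hue.
#'
#' @param spec a [bar_spec()].
#' @param calibration a [calibration_target()].
#' @param n_hues number of hues (default 12).
#' @return a `chromaform_stimulus_set`: list with `stimuli` and a `manifest`
#'   data frame (one row per stimulus).
#' @export
make_bars <- function(spec, calibration, n_hues = 12) {
  orientations <- bar_orientations(spec)
  fills <- vapply(seq_len(n_hues) - 1L, calibrated_fill_color,
                  numeric(3), calibration = calibration, n_hues = n_hues)
  stimuli <- list()
  rows <- list()
  n <- spec$canvas_px
  base <- rep(255L, 3L * n * n)
  for (oi in seq_along(orientations)) {
    m <- .bar_mask(spec, orientations[oi])
    w <- which(m)
    idx <- c(w, w + n * n, w + 2L * n * n)
    oid <- sprintf("bar%02d", oi - 1L)
    for (hi in seq_len(n_hues)) {
      v <- base
      v[idx] <- rep(as.integer(fills[, hi]), each = length(w))
      ras <- array(v, dim = c(n, n, 3))
      st <- .stimulus(oid, hi - 1L, "bar", ras, calibration,
                      audit = list(orientation = orientations[oi],
                                   n_pixels = sum(m)))
      stimuli[[length(stimuli) + 1L]] <- st
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = oid, hue_index = hi - 1L, variant = "bar",
        orientation = orientations[oi], n_pixels = sum(m),
        stringsAsFactors = FALSE)
    }
  }
  stimulus_set(stimuli, extra = do.call(rbind, rows))
}

#' Bundle stimuli into a set with a manifest
#'
#' @param stimuli list of `chromaform_stimulus` objects.
#' @param extra optional data frame of additional manifest columns, one row
#'   per stimulus.
#' @return a `chromaform_stimulus_set`.
#' @export
stimulus_set <- function(stimuli, extra = NULL) {
  manifest <- data.frame(
    object_id = vapply(stimuli, function(s) s$object_id, character(1)),
    hue_index = vapply(stimuli, function(s) as.integer(s$hue_index), integer(1)),
    variant = vapply(stimuli, function(s) s$variant, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    manifest <- cbind(manifest,
                      extra[, setdiff(names(extra), names(manifest)), drop = FALSE])
  }
  structure(list(stimuli = stimuli, manifest = manifest),
            class = "chromaform_stimulus_set")
}

#' Audit a stimulus against its calibration targets
#'
#' Recomputes the masked mean luminance and saturation from the (quantized)
#' RGB raster, independently of the construction path.
#'
#' @param stimulus a `chromaform_stimulus`.
#' @param mask optional logical object mask; recomputed when missing.
#' @return data frame with achieved means and deviations from target.
#' @export
audit_calibration <- function(stimulus, mask = NULL) {
  if (is.null(mask)) mask <- background_mask(stimulus$raster)
  cal <- stimulus$calibration
  if (cal$space == "cieluv") {
    luv <- srgb_to_luv(stimulus$raster)
    h <- dim(stimulus$raster)[1]; w <- dim(stimulus$raster)[2]
    L <- matrix(luv[, , 1], h, w)
    C <- sqrt(matrix(luv[, , 2], h, w)^2 + matrix(luv[, , 3], h, w)^2)
    mean_lum <- mean(L[mask]); mean_sat <- mean(C[mask])
  } else {
    dec <- synthetic_hsv_decompose(matrix(stimulus$raster, ncol = 3))
    mv <- as.vector(mask)
    mean_lum <- mean(dec$lum[mv]); mean_sat <- mean(dec$sat[mv])
  }
  data.frame(object_id = stimulus$object_id, hue_index = stimulus$hue_index,
             variant = stimulus$variant,
             achieved_mean_lum = mean_lum, achieved_mean_sat = mean_sat,
             dev_lum = mean_lum - cal$lum, dev_sat = mean_sat - cal$sat,
             stringsAsFactors = FALSE)
}

#' Select a maximally dissimilar subset of candidates
#'
#' Given a symmetric similarity matrix over candidates, returns `k`
#' candidates minimizing mean pairwise similarity. The default greedy
#' worst-out elimination repeatedly drops the candidate with the highest mean
#' similarity to the remaining set; `method = "exhaustive"` searches all
#' subsets (small n only) and serves as the oracle for the greedy path.
#'
#' @param rsm symmetric numeric similarity matrix (diagonal ignored).
#' @param k subset size, 2 <= k <= nrow(rsm).
#' @param method `"greedy"` (default) or `"exhaustive"`.
#' @return integer vector of selected indices (or names when present),
#'   with attribute `mean_similarity`.
#' @export
select_dissimilar_subset <- function(rsm, k, method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  n <- nrow(rsm)
  if (k < 2 || k > n) stop("k must be between 2 and the number of candidates", call. = FALSE)
  if (max(abs(rsm - t(rsm))) > 1e-9) stop("similarity matrix must be symmetric", call. = FALSE)
  mean_pairwise <- function(idx) {
    sub <- rsm[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  if (method == "exhaustive") {
    if (choose(n, k) > 1e6) stop("exhaustive search infeasible for this n", call. = FALSE)
    combs <- utils::combn(n, k)
    scores <- apply(combs, 2, mean_pairwise)
    keep <- combs[, which.min(scores)]
  } else {
    keep <- seq_len(n)
    while (length(keep) > k) {
      sub <- rsm[keep, keep]
      diag(sub) <- NA
      worst <- which.max(rowMeans(sub, na.rm = TRUE))
      keep <- keep[-worst]
    }
  }
  res <- if (!is.null(rownames(rsm))) rownames(rsm)[keep] else keep
  attr(res, "mean_similarity") <- mean_pairwise(keep)
  res
}
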