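## Raster I/O. Internal representation: numeric h x w x 3 array, channels
## 0-255. PNG via the png package; plain-text P3 PPM supported for tiny
## version-controllable fixtures.

#' Read an RGB raster
#'
#' Reads PNG or plain-text PPM (P3) into an h x w x 3 array with channel
#' values in 0-255. Grayscale and alpha planes are expanded/dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return numeric h x w x 3 array.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") return(.read_ppm(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  if (dim(img)[3] == 1) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB raster
#'
#' @param raster numeric h x w x 3 array, channels in 0-255.
#' @param path output path ending in .png or .ppm.
#' @export
write_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") return(.write_ppm(raster, path))
  png::writePNG(pmin(pmax(raster / 255, 0), 1), path)
  invisible(path)
}

.read_ppm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(tok[1] == "P3")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxv)
  # PPM is row-major, pixel-interleaved
  arr <- array(0, dim = c(h, w, 3))
  m <- matrix(vals, nrow = 3)
  for (ch in 1:3) arr[, , ch] <- matrix(m[ch, ], nrow = h, byrow = TRUE)
  arr
}

.write_ppm <- function(raster, path) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  m <- rbind(
    as.vector(t(raster[, , 1])),
    as.vector(t(raster[, , 2])),
    as.vector(t(raster[, , 3]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.integer(round(as.vector(m))), collapse = " "), con)
  invisible(path)
}

# area-weighted 1-D resampling matrix mapping length n -> m
.box_weights <- function(n, m) {
  w <- matrix(0, m, n)
  scale <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    js <- floor(lo):min(ceiling(hi) - 1, n - 1)
    for (j in js) {
      w[i, j + 1] <- (min(hi, j + 1) - max(lo, j)) / scale
    }
  }
  w
}

#' Area-averaged raster resize (box filter)
#'
#' Exact area-weighted resampling to an arbitrary square size; deterministic
#' and separable. Used as the adapter preprocessing resize.
#'
#' @param raster h x w x c array.
#' @param out_px output side length.
#' @return resized array of dim c(out_px, out_px, c).
#' @export
resize_raster <- function(raster, out_px) {
  d <- dim(raster)
  if (d[1] == out_px && d[2] == out_px) return(raster)
  wr <- .box_weights(d[1], out_px)
  wc <- .box_weights(d[2], out_px)
  out <- array(0, dim = c(out_px, out_px, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- wr %*% raster[, , ch] %*% t(wc)
  }
  out
}

#' Block-mean downsampling of a raster
#'
#' Average-pool each channel over non-overlapping `factor` x `factor` blocks.
#' Used as the default adapter preprocessing step.
#'
#' @param raster h x w x 3 array; h and w must be divisible by `factor`.
#' @param factor integer block size.
#' @return downsampled raster.
#' @export
downsample_raster <- function(raster, factor) {
  d <- dim(raster)
  if (factor == 1) return(raster)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    stop("raster dimensions must be divisible by the downsampling factor", call. = FALSE)
  }
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  out <- array(0, dim = c(h2, w2, d[3]))
  for (ch in seq_len(d[3])) {
    x <- raster[, , ch]
    # fold rows then columns
    x <- matrix(colMeans(matrix(x, nrow = factor)), nrow = h2)
    x <- t(matrix(colMeans(matrix(t(x), nrow = factor)), nrow = w2))
    out[, , ch] <- x
  }
  out
}
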