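## A desk-scale layered network implemented in base R: stacked
## convolution -> rectification -> average-pooling stages with seeded random
## weights and a final global-spatial-average stage. Stands in for large
## pretrained architectures so the full pipeline runs with no downloads.

# zero-padded shift of a matrix by (dy, dx)
.shift_mat <- function(x, dy, dx) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- x[ys - dy, xs - dx, drop = FALSE]
  out
}

# same-padding 3x3 convolution: `input` list of channel matrices, `weights`
# array (3, 3, in_ch, out_ch), `bias` length out_ch
.conv3x3 <- function(input, weights, bias) {
  out_ch <- dim(weights)[4]
  lapply(seq_len(out_ch), function(oc) {
    acc <- matrix(bias[oc], nrow(input[[1]]), ncol(input[[1]]))
    for (ic in seq_along(input)) {
      for (ky in 1:3) {
        for (kx in 1:3) {
          wgt <- weights[ky, kx, ic, oc]
          if (wgt != 0) acc <- acc + wgt * .shift_mat(input[[ic]], ky - 2, kx - 2)
        }
      }
    }
    acc
  })
}

.avg_pool2 <- function(x) {
  h <- nrow(x) %/% 2; w <- ncol(x) %/% 2
  x <- x[seq_len(2 * h), seq_len(2 * w), drop = FALSE]
  0.25 * (x[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
          x[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
          x[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
          x[seq(2, 2 * h, 2), seq(2, 2 * w, 2)])
}

#' Seeded toy convolutional network adapter
#'
#' Builds `n_stages - 1` convolution/ReLU/average-pool blocks followed by a
#' global spatial-average stage, with He-scaled Gaussian random weights drawn
#' under `seed`. Each block's pooled output and the final average are exposed
#' as named layers ("stage1", ..., "gap"). Inputs are block-mean downsampled
#' to `input_px` and scaled to zero-centered \[-0.5, 0.5\] before the first
#' convolution (the recipe is recorded on the adapter). Evaluation is
#' deterministic: identical seeds give identical descriptors and activations.
#'
#' @param seed integer weight seed.
#' @param n_stages total exposed stages including the final average
#'   (default 5, i.e. 4 conv blocks).
#' @param channels feature channels per conv block (default 8).
#' @param input_px square input resolution after preprocessing (default 64).
#' @return a `model_adapter`.
#' @export
toy_network_adapter <- function(seed, n_stages = 5, channels = 8,
                                input_px = 64) {
  if (n_stages < 2) stop("need at least 2 stages", call. = FALSE)
  n_blocks <- n_stages - 1L
  if (input_px %/% 2^n_blocks < 1) {
    stop("too many stages for this input resolution", call. = FALSE)
  }
  set.seed(seed)
  weights <- vector("list", n_blocks)
  biases <- vector("list", n_blocks)
  in_ch <- 3
  for (b in seq_len(n_blocks)) {
    fan_in <- 9 * in_ch
    weights[[b]] <- array(stats::rnorm(9 * in_ch * channels, sd = sqrt(2 / fan_in)),
                          dim = c(3, 3, in_ch, channels))
    biases[[b]] <- stats::rnorm(channels, sd = 0.01)
    in_ch <- channels
  }

  # forward module sequence: (conv, relu, pool) per block, then gap
  total_modules <- 3L * n_blocks + 1L
  sizes <- input_px %/% 2^seq_len(n_blocks)
  layers <- data.frame(
    layer_label = c(paste0("stage", seq_len(n_blocks)), "gap"),
    position = c(3L * seq_len(n_blocks), total_modules),
    total_layers = total_modules,
    n_units = as.integer(c(channels * sizes^2, channels)),
    layer_class = c(rep("pool", n_blocks), "other"),
    stringsAsFactors = FALSE)
  layers$layer_fraction <- compute_layer_fraction(layers$position, total_modules)

  preprocess <- function(raster) {
    raster <- resize_raster(raster, input_px)
    lapply(1:3, function(ch) raster[, , ch] / 255 - 0.5)
  }

  forward <- function(rasters, layer_labels) {
    out <- lapply(layer_labels, function(l) NULL)
    names(out) <- layer_labels
    rows <- lapply(rasters, function(ras) {
      x <- preprocess(ras)
      feats <- list()
      for (b in seq_len(n_blocks)) {
        x <- .conv3x3(x, weights[[b]], biases[[b]])
        x <- lapply(x, function(m) pmax(m, 0))
        x <- lapply(x, .avg_pool2)
        feats[[paste0("stage", b)]] <- x
      }
      feats[["gap"]] <- lapply(x, mean)
      lapply(layer_labels, function(lab) {
        # flatten channel-major, column-major within each channel plane
        unlist(lapply(feats[[lab]], as.vector), use.names = FALSE)
      })
    })
    for (i in seq_along(layer_labels)) {
      out[[i]] <- do.call(rbind, lapply(rows, `[[`, i))
    }
    out
  }

  model_adapter(
    network_id = sprintf("toy-s%d-seed%d", n_stages, seed),
    layers = layers,
    forward = forward,
    preprocessing = sprintf(
      "block-mean downsample to %dx%d; scale to [0,1]; subtract 0.5", input_px, input_px))
}
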