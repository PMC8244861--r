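## Adapter contract for pulling flattened activations out of named layers of
## any layered model, plus layer bookkeeping (layer_fraction).

#' Fraction of a network's layers traversed at a given position
#'
#' A layer's 1-based position in the full forward sequence divided by the
#' total number of modules: the first layer of a ten-layer network scores
#' 0.1, the final layer 1.0. Used as the regression abscissa for hierarchy
#' trends, making depths comparable across architectures.
#'
#' @param position 1-based layer index in the forward sequence.
#' @param total_layers total number of modules in the forward pass.
#' @return `position / total_layers`, in (0, 1\].
#' @export
compute_layer_fraction <- function(position, total_layers) {
  if (any(position < 1) || any(position > total_layers)) {
    stop("position must lie within 1..total_layers", call. = FALSE)
  }
  position / total_layers
}

#' Construct a model adapter
#'
#' The uniform contract every activation source implements: stable layer
#' enumeration and a deterministic forward function returning flattened
#' activations for named layers.
#'
#' @param network_id identifier string.
#' @param layers data frame of layer descriptors with columns `layer_label`,
#'   `position`, `total_layers`, `layer_fraction`, `n_units`, `layer_class`.
#' @param forward function(rasters, layer_labels) returning a named list of
#'   n_stimuli x n_units matrices, one per requested label.
#' @param preprocessing human-readable recipe recorded in manifests.
#' @return a `model_adapter` object.
#' @export
model_adapter <- function(network_id, layers, forward, preprocessing = "none") {
  stopifnot(all(c("layer_label", "position", "total_layers", "layer_fraction",
                  "n_units", "layer_class") %in% names(layers)))
  if (any(diff(layers$layer_fraction) <= 0)) {
    stop("layer_fraction must be strictly increasing along the sampled layers",
         call. = FALSE)
  }
  structure(list(network_id = network_id, layers = layers, forward = forward,
                 preprocessing = preprocessing),
            class = "model_adapter")
}

#' Enumerate an adapter's layers
#' @param adapter a `model_adapter`.
#' @return the layer-descriptor data frame.
#' @export
enumerate_layers <- function(adapter) adapter$layers

#' Extract flattened activations for a stimulus set
#'
#' Runs every stimulus raster through the adapter and returns, per requested
#' layer, a matrix with one row per manifest row (same order) and one column
#' per unit. Multi-dimensional layer outputs are flattened channel-major,
#' then column-major over space — a fixed order; all downstream metrics are
#' permutation-invariant over units.
#'
#' @param adapter a `model_adapter`.
#' @param stimuli a `chromaform_stimulus_set`.
#' @param layer_labels labels to extract; default all enumerated layers.
#' @return named list of activation matrices; each carries the matching
#'   layer-descriptor row as attribute `layer` and the stimulus keys as
#'   attribute `keys`.
#' @export
extract_activations <- function(adapter, stimuli, layer_labels = NULL) {
  desc <- enumerate_layers(adapter)
  if (is.null(layer_labels)) layer_labels <- desc$layer_label
  unknown <- setdiff(layer_labels, desc$layer_label)
  if (length(unknown)) {
    stop("unknown layer label(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(desc$layer_label, collapse = ", "),
         call. = FALSE)
  }
  rasters <- lapply(stimuli$stimuli, function(s) s$raster)
  acts <- adapter$forward(rasters, layer_labels)
  keys <- stimuli$manifest[, c("object_id", "hue_index", "variant")]
  out <- lapply(layer_labels, function(lab) {
    m <- acts[[lab]]
    if (any(!is.finite(m))) {
      stop("non-finite activation in layer ", lab, call. = FALSE)
    }
    rownames(m) <- paste(keys$object_id, keys$hue_index, keys$variant, sep = ":")
    attr(m, "layer") <- desc[desc$layer_label == lab, ]
    attr(m, "keys") <- keys
    m
  })
  names(out) <- layer_labels
  out
}

#' Split an activation matrix into per-object color pattern matrices
#'
#' @param act activation matrix with a `keys` attribute (or supply `keys`).
#' @param keys optional data frame with `object_id` and `hue_index`.
#' @return named list (by object) of n_colors x n_units matrices, rows
#'   ordered by hue index.
#' @export
patterns_by_object <- function(act, keys = NULL) {
  if (is.null(keys)) keys <- attr(act, "keys")
  if (is.null(keys)) stop("activation matrix has no stimulus keys", call. = FALSE)
  objs <- unique(keys$object_id)
  out <- lapply(objs, function(o) {
    idx <- which(keys$object_id == o & !is.na(keys$hue_index))
    idx <- idx[order(keys$hue_index[idx])]
    act[idx, , drop = FALSE]
  })
  names(out) <- objs
  out
}

#' Seeded random-weight adapter for a named architecture
#'
#' Constructs an untrained instance of the architecture with weights drawn
#' by its default initialization under `seed`; two adapters with equal seeds
#' produce equal activations. Only desk-scale architectures constructible
#' without downloads are registered ("toy"); external frameworks plug in via
#' [model_adapter()].
#'
#' @param architecture_id architecture name; currently `"toy"`.
#' @param seed integer seed for weight initialization.
#' @param ... passed to the architecture constructor.
#' @return a `model_adapter`.
#' @export
random_init_adapter <- function(architecture_id, seed, ...) {
  if (architecture_id == "toy") return(toy_network_adapter(seed = seed, ...))
  stop("architecture '", architecture_id,
       "' is not constructible in this environment; provide a model_adapter",
       call. = FALSE)
}
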