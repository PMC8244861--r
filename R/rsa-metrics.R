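## Second-order representational-geometry metrics: per-object color RSMs,
## color-space vectors, between-object / cross-layer correlations, the
## normalized within-object color distance, form-similarity comparisons, and
## MDS embedding.

.check_variance <- function(m, what = "pattern") {
  v <- apply(m, 1, stats::var)
  bad <- which(v < 1e-12)
  if (length(bad)) {
    stop("degenerate ", what, " (variance < 1e-12) at index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Per-object color representational similarity matrix
#'
#' All pairwise similarities among the activation patterns evoked by the
#' n colors of one object in one layer.
#'
#' @param patterns n_colors x n_units matrix, one row per color.
#' @param metric `"pearson"` (default) or `"euclidean"` (unbounded control
#'   metric; second-order comparisons stay Pearson either way).
#' @return symmetric n_colors x n_colors matrix, attribute `metric`.
#' @export
color_rsm <- function(patterns, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (ncol(patterns) < 2) stop("need at least 2 units", call. = FALSE)
  if (metric == "pearson") {
    .check_variance(patterns, "color pattern")
    m <- stats::cor(t(patterns))
  } else {
    m <- as.matrix(stats::dist(patterns))
  }
  dimnames(m) <- NULL
  attr(m, "metric") <- metric
  m
}

#' Vectorize the off-diagonal of a symmetric RSM
#'
#' Upper triangle in row-major order; a k x k matrix yields k(k-1)/2 values.
#' This is the "color space" vector when applied to a 12-color RSM
#' (length 66), the unit of all second-order analyses.
#'
#' @param rsm symmetric numeric matrix.
#' @return numeric vector of the strict upper triangle.
#' @export
rsm_offdiag_vector <- function(rsm) {
  if (max(abs(rsm - t(rsm))) > 1e-9) {
    stop("RSM is asymmetric beyond tolerance", call. = FALSE)
  }
  # column-major lower triangle == row-major upper triangle for symmetric m
  rsm[lower.tri(rsm)]
}

#' Color-space vector of one object in one layer
#'
#' Convenience composition of [color_rsm()] and [rsm_offdiag_vector()].
#'
#' @inheritParams color_rsm
#' @return numeric vector of length n_colors*(n_colors-1)/2.
#' @export
color_space_vector <- function(patterns, metric = c("pearson", "euclidean")) {
  rsm_offdiag_vector(color_rsm(patterns, metric))
}

#' Pairwise Pearson correlations among equal-length vectors
#'
#' @param vectors matrix with one vector per row (or list of equal-length
#'   vectors).
#' @return symmetric correlation matrix with attribute `mean_offdiag`, the
#'   mean of the strict upper triangle.
#' @export
pairwise_vector_correlation_matrix <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (nrow(vectors) < 2) stop("need at least 2 vectors", call. = FALSE)
  .check_variance(vectors, "vector")
  m <- stats::cor(t(vectors))
  attr(m, "mean_offdiag") <- mean(m[upper.tri(m)])
  m
}

#' Normalized within-object color distance
#'
#' Strength of color representation for one object: unit responses to each
#' color are z-normalized (population variance, divisor n, making
#' ||z|| = sqrt(n) exact), pairwise Euclidean distances are divided by
#' 2*sqrt(n_units) — bounding each pair in \[0, 1\] regardless of layer size —
#' and averaged over all color pairs.
#'
#' @param patterns n_colors x n_units matrix.
#' @return list with `value` (mean normalized distance), `pairwise` (the
#'   per-pair values, upper triangle row-major).
#' @export
within_object_color_distance <- function(patterns) {
  n <- ncol(patterns)
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  .check_variance(patterns, "color pattern")
  mu <- rowMeans(patterns)
  sd_pop <- sqrt(rowMeans((patterns - mu)^2))
  z <- (patterns - mu) / sd_pop
  d <- as.matrix(stats::dist(z)) / (2 * sqrt(n))
  pw <- d[lower.tri(d)]
  list(value = mean(pw), pairwise = pw)
}

#' Correlate one object's color-space vector across layers
#'
#' @param vectors_by_layer matrix, one row per layer, of that object's
#'   color-space vectors.
#' @param reference row index of the reference layer (typically the first or
#'   penultimate layer).
#' @return numeric vector of Pearson r against the reference, one per layer.
#' @export
cross_layer_profile <- function(vectors_by_layer, reference) {
  .check_variance(vectors_by_layer, "color-space vector")
  ref <- vectors_by_layer[reference, ]
  apply(vectors_by_layer, 1, stats::cor, y = ref)
}

#' Color-space similarity vector of one layer
#'
#' Correlates every object's color-space vector with every other object's
#' within one layer and returns the strict upper triangle (row-major) of the
#' resulting between-object similarity matrix.
#'
#' @param cs_vectors matrix, one row per object, of color-space vectors.
#' @return numeric vector of length C(n_objects, 2).
#' @export
colorspace_similarity_vector <- function(cs_vectors) {
  if (nrow(cs_vectors) < 3) stop("need at least 3 objects", call. = FALSE)
  m <- pairwise_vector_correlation_matrix(cs_vectors)
  rsm_offdiag_vector(unclass(m))
}

#' Object form similarity vector from grayscale activations
#'
#' Pairwise Pearson correlations of the layer's responses to the grayscale
#' versions of all objects, vectorized as the strict upper triangle.
#'
#' @param grayscale_activations matrix, one row per object.
#' @return numeric vector of length C(n_objects, 2).
#' @export
form_similarity_vector <- function(grayscale_activations) {
  m <- pairwise_vector_correlation_matrix(grayscale_activations)
  rsm_offdiag_vector(unclass(m))
}

#' Correlate form similarity with color-space similarity
#'
#' Does the form similarity of two objects predict how similar their color
#' geometries are? One Pearson r per layer.
#'
#' @param form_vec,cs_sim_vec equal-length pair vectors in matching order.
#' @return scalar Pearson correlation.
#' @export
form_vs_colorspace_correlation <- function(form_vec, cs_sim_vec) {
  if (length(form_vec) != length(cs_sim_vec)) {
    stop("vectors must have equal length and matching pair order", call. = FALSE)
  }
  .check_variance(rbind(form_vec, cs_sim_vec), "similarity vector")
  stats::cor(form_vec, cs_sim_vec)
}

#' Mean between-object color-space correlation for one layer
#'
#' The layer-level summary statistic: build each object's color-space vector
#' from its 12-color patterns, correlate all object pairs, average.
#'
#' @param patterns_list list of n_colors x n_units matrices, one per object.
#' @param metric first-order metric passed to [color_rsm()].
#' @return list with `mean` (mean pairwise r), `matrix` (between-object
#'   correlation matrix), `cs_vectors` (per-object color-space vectors).
#' @export
between_object_colorspace <- function(patterns_list,
                                      metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  cs <- do.call(rbind, lapply(patterns_list, color_space_vector, metric = metric))
  m <- pairwise_vector_correlation_matrix(cs)
  list(mean = attr(m, "mean_offdiag"), matrix = unclass(m), cs_vectors = cs)
}

#' Metric multidimensional scaling by stress majorization
#'
#' Embeds a dissimilarity matrix (typically 1 - r) into `dim` dimensions
#' minimizing metric stress via SMACOF iterations initialized from classical
#' scaling, so the result is deterministic; `seed` governs the random restart
#' used only when the classical solution is degenerate.
#'
#' @param dissimilarities symmetric non-negative matrix with zero diagonal.
#' @param dim embedding dimensionality (default 2).
#' @param seed integer seed for the fallback random initialization.
#' @param max_iter,tol majorization iteration controls.
#' @return list with `points` (n x dim coordinates) and `stress`
#'   (normalized stress-1).
#' @export
mds_embed <- function(dissimilarities, dim = 2, seed = 1,
                      max_iter = 500, tol = 1e-12) {
  d <- as.matrix(dissimilarities)
  if (max(abs(d - t(d))) > 1e-9) stop("dissimilarities must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  n <- nrow(d)
  if (all(d == 0)) {
    return(list(points = matrix(0, n, dim), stress = 0))
  }
  x <- suppressWarnings(stats::cmdscale(d, k = dim))
  if (ncol(x) < dim || !all(is.finite(x)) || sum(stats::dist(x)) < 1e-12) {
    set.seed(seed)
    x <- matrix(stats::rnorm(n * dim, sd = mean(d) / 2), n, dim)
  }
  denom <- sum(d[lower.tri(d)]^2)
  stress_of <- function(x) {
    dd <- as.matrix(stats::dist(x))
    sqrt(sum((d[lower.tri(d)] - dd[lower.tri(dd)])^2) / denom)
  }
  s_prev <- stress_of(x)
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(stats::dist(x))
    ratio <- ifelse(dd > 1e-12, d / dd, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n
    s <- stress_of(x)
    if (abs(s_prev - s) < tol) break
    s_prev <- s
  }
  list(points = x, stress = stress_of(x))
}
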