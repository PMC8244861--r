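## Inferential layer: per-pair slope regressions over layer_fraction,
## one-sample and matched-pairs t tests, Fisher z, and the color-label
## shuffle null.

#' Ordinary least-squares slope of values over layer fractions
#'
#' One regression per object pair (or object): the second-order correlation
#' (or distance) values across the sampled hierarchy, regressed onto
#' layer_fraction. Slope units: correlation per unit depth fraction. Fits
#' should use the first through penultimate layers only; the classification
#' layer is excluded upstream.
#'
#' @param values response values, one per layer.
#' @param fractions strictly increasing layer_fraction abscissa.
#' @return list with `slope`, `intercept`, `n_points`.
#' @export
pair_slope <- function(values, fractions) {
  n <- length(values)
  if (n < 2 || length(fractions) != n) {
    stop("need equal-length values and fractions with n >= 2", call. = FALSE)
  }
  if (any(diff(fractions) <= 0)) {
    stop("layer fractions must be strictly increasing", call. = FALSE)
  }
  xm <- mean(fractions); ym <- mean(values)
  slope <- sum((fractions - xm) * (values - ym)) / sum((fractions - xm)^2)
  list(slope = slope, intercept = ym - slope * xm, n_points = n)
}

.t_result <- function(t, df, kind) {
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), tails = 2L,
       test_kind = kind)
}

#' One-sample t test
#'
#' Two-tailed test of the mean of `values` against `mu0`, with sample
#' standard deviation (divisor n-1) and df = n-1.
#'
#' @param values numeric sample.
#' @param mu0 null mean (default 0).
#' @return list with `t`, `df`, `p`, `tails`, `test_kind`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s < 1e-300) stop("zero sample variance", call. = FALSE)
  .t_result((mean(values) - mu0) / (s / sqrt(n)), n - 1L, "one_sample")
}

#' Matched-pairs t test
#'
#' One-sample t test on the per-pair differences a - b against zero.
#'
#' @param a,b equal-length paired samples.
#' @return list with `t`, `df`, `p`, `tails`, `test_kind`.
#' @export
matched_pairs_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
  res <- one_sample_t(a - b, 0)
  res$test_kind <- "matched_pairs"
  res
}

#' Fisher z transformation
#'
#' Variance-stabilizing atanh transform applied to correlations before
#' cross-layer regression.
#'
#' @param r correlation values with |r| < 1.
#' @param clamp clamp |r| >= 1 to 1 - 1e-7 (with a warning) instead of
#'   erroring (default FALSE).
#' @return atanh(r).
#' @export
fisher_z <- function(r, clamp = FALSE) {
  if (any(abs(r) >= 1)) {
    if (!clamp) stop("|r| must be < 1 (set clamp = TRUE to clip)", call. = FALSE)
    warning("clamping ", sum(abs(r) >= 1), " correlation(s) at 1 - 1e-7")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Color-label shuffle null for the between-object color-space correlation
#'
#' For each shuffle, the 12 color labels are permuted independently within
#' each object (equivalently: rows/columns of each object's prebuilt color
#' RSM are co-permuted), the color-space vectors are rebuilt, and the mean
#' pairwise between-object correlation is recorded. Under no shared color
#' structure the expectation is zero. One master seed spawns one sub-seed per
#' shuffle, so any single shuffle is reproducible in isolation.
#'
#' @param patterns_list list of n_colors x n_units matrices, one per object.
#' @param n_shuffles number of label shuffles (default 100).
#' @param seed master integer seed.
#' @param metric first-order metric passed to [color_rsm()].
#' @return list with `per_shuffle_means`, `mean_null`, `se_null`,
#'   `n_shuffles`.
#' @export
shuffle_color_null <- function(patterns_list, n_shuffles = 100, seed = 1,
                               metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (length(patterns_list) < 2) stop("need at least 2 objects", call. = FALSE)
  rsms <- lapply(patterns_list, color_rsm, metric = metric)
  k <- nrow(rsms[[1]])
  means <- vapply(seq_len(n_shuffles), function(sh) {
    set.seed((seed + 7919L * sh) %% .Machine$integer.max)
    cs <- do.call(rbind, lapply(rsms, function(m) {
      p <- sample.int(k)
      rsm_offdiag_vector(m[p, p])
    }))
    attr(pairwise_vector_correlation_matrix(cs), "mean_offdiag")
  }, numeric(1))
  list(per_shuffle_means = means, mean_null = mean(means),
       se_null = stats::sd(means) / sqrt(n_shuffles), n_shuffles = n_shuffles)
}

#' Slope analysis across a layer hierarchy
#'
#' Given per-layer between-object correlation matrices (first through
#' penultimate layers) and their layer fractions, extracts one OLS slope per
#' object pair and tests the slopes against zero.
#'
#' @param corr_by_layer list of between-object correlation matrices, one per
#'   layer, identical object order.
#' @param fractions layer_fraction values, one per layer.
#' @param fisher apply [fisher_z()] to correlations before regression
#'   (used for cross-layer profile regressions; between-object slope
#'   regressions operate on raw correlations).
#' @return list with `slopes` (one per pair, upper-triangle row-major order)
#'   and `test` (one-sample t of the slopes against zero).
#' @export
hierarchy_slope_test <- function(corr_by_layer, fractions, fisher = FALSE) {
  vecs <- lapply(corr_by_layer, rsm_offdiag_vector)
  m <- do.call(cbind, vecs) # pairs x layers
  if (fisher) m <- fisher_z(m, clamp = TRUE)
  slopes <- apply(m, 1, function(v) pair_slope(v, fractions)$slope)
  list(slopes = slopes, test = one_sample_t(slopes, 0))
}
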