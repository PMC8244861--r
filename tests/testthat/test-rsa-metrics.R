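random_patterns <- function(k = 12, n = 40, seed = 1) {
  set.seed(seed)
  matrix(rnorm(k * n), k, n)
}

test_that("color_rsm covers the metric contracts and degenerate guards", {
  p <- matrix(rep(c(1, 2, 3), 12), 12, 3, byrow = TRUE) +
    matrix(rnorm(36, sd = 0), 12, 3)
  # identical patterns: perfect correlation everywhere
  m <- color_rsm(p + matrix(rnorm(3), 12, 3, byrow = TRUE) * 0, "pearson")
  expect_true(all(abs(m - 1) < 1e-12))
  # perfect anti-correlation
  q <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(stats::cor(q[1, ], q[2, ]), -1)
  m2 <- color_rsm(rbind(q, q), "pearson")
  expect_equal(m2[1, 2], -1)
  # euclidean on orthonormal basis vectors
  e <- diag(12)
  m3 <- color_rsm(e, "euclidean")
  expect_true(all(abs(m3[upper.tri(m3)] - sqrt(2)) < 1e-12))
  expect_true(all(diag(m3) == 0))
  # zero-variance pattern names the color index
  bad <- random_patterns()
  bad[5, ] <- 2
  expect_error(color_rsm(bad), "index 5")
})

test_that("off-diagonal vectorization is upper-triangle row-major", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  diag(m) <- 1
  expect_equal(rsm_offdiag_vector(m), c(0.1, 0.2, 0.3))
  r <- color_rsm(random_patterns(), "pearson")
  expect_length(rsm_offdiag_vector(r), 66)
  expect_equal(rsm_offdiag_vector(r), rsm_offdiag_vector(t(r)))
  asym <- m; asym[1, 2] <- 0.5
  expect_error(rsm_offdiag_vector(asym), "asymmetric")
})

test_that("pairwise vector correlations match the explicit-sums oracle", {
  v <- random_patterns(5, 30, seed = 2)
  m <- pairwise_vector_correlation_matrix(v)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], oracle_pearson(v[i, ], v[j, ]), tolerance = 1e-12)
  }
  expect_equal(attr(m, "mean_offdiag"), mean(m[upper.tri(m)]))
  # identical copies -> all ones; v and -v -> -1
  same <- rbind(v[1, ], v[1, ], v[1, ])
  expect_true(all(abs(pairwise_vector_correlation_matrix(same) - 1) < 1e-12))
  expect_equal(pairwise_vector_correlation_matrix(rbind(v[1, ], -v[1, ]))[1, 2], -1)
  expect_error(pairwise_vector_correlation_matrix(rbind(v[1, ], rep(3, 30))),
               "degenerate")
})

test_that("normalized color distance obeys the distance-correlation identity", {
  p <- random_patterns(12, 100, seed = 3)
  res <- within_object_color_distance(p)
  r <- color_rsm(p, "pearson")
  expect_equal(res$pairwise, sqrt((1 - rsm_offdiag_vector(r)) / 2),
               tolerance = 1e-10)
  expect_true(all(res$pairwise >= 0 & res$pairwise <= 1))
  # identical patterns -> 0
  same <- matrix(rep(rnorm(50), each = 12), 12)
  expect_equal(within_object_color_distance(same)$value, 0)
  # z and -z -> exactly 1 under population z-scoring
  z <- rnorm(80)
  res2 <- within_object_color_distance(rbind(matrix(rep(z, 6), 6, byrow = TRUE),
                                             matrix(rep(-z, 6), 6, byrow = TRUE)))
  expect_equal(max(res2$pairwise), 1, tolerance = 1e-12)
})

test_that("metrics are invariant to unit permutation and positive affine gain", {
  p <- random_patterns(12, 60, seed = 4)
  perm <- sample(60)
  expect_equal(color_rsm(p[, perm]), color_rsm(p), ignore_attr = TRUE)
  expect_equal(within_object_color_distance(p[, perm])$value,
               within_object_color_distance(p)$value)
  scaled <- p * 3.7 + 11
  expect_equal(color_rsm(scaled), color_rsm(p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cross-layer profile anchors at 1 and nulls out for independence", {
  v <- random_patterns(6, 66, seed = 5)
  prof <- cross_layer_profile(v, 1)
  expect_equal(prof[1], 1)
  same <- matrix(rep(v[1, ], 4), 4, byrow = TRUE) +
    matrix(rnorm(4 * 66, sd = 1e-8), 4)
  expect_true(all(cross_layer_profile(same, 2) > 0.999))
  # Monte Carlo null: independent vectors, mean r within 3 SE of 0
  set.seed(6)
  rs <- replicate(1000, {
    m <- matrix(rnorm(2 * 66), 2)
    cross_layer_profile(m, 1)[2]
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("colorspace similarity and form similarity agree with the matrix path", {
  cs <- random_patterns(5, 66, seed = 7)
  vec <- colorspace_similarity_vector(cs)
  expect_length(vec, choose(5, 2))
  m <- pairwise_vector_correlation_matrix(cs)
  expect_equal(vec, rsm_offdiag_vector(unclass(m)))
  acts <- random_patterns(6, 120, seed = 8)
  fv <- form_similarity_vector(acts)
  expect_length(fv, 15)
  expect_equal(fv[1], oracle_pearson(acts[1, ], acts[2, ]), tolerance = 1e-12)
})

test_that("form-vs-colorspace correlation honors affine invariance and nulls", {
  f <- rnorm(45)
  expect_equal(form_vs_colorspace_correlation(f, f), 1)
  expect_equal(form_vs_colorspace_correlation(f, 2.5 * f + 3), 1,
               tolerance = 1e-12)
  expect_error(form_vs_colorspace_correlation(f, f[-1]), "equal length")
  set.seed(9)
  rs <- replicate(1000, form_vs_colorspace_correlation(rnorm(45), rnorm(45)))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("mds_embed recovers exact configurations and is deterministic", {
  z <- matrix(0, 4, 4)
  res0 <- mds_embed(z)
  expect_lt(max(abs(res0$points)), 1e-6)
  expect_equal(res0$stress, 0)
  # collinear points at distances 1,1,2: Euclidean-realizable exactly
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  res <- mds_embed(d, dim = 2, seed = 1)
  dd <- as.matrix(dist(res$points))
  expect_equal(dd[lower.tri(dd)], d[lower.tri(d)], tolerance = 1e-3)
  expect_lt(res$stress, 1e-6)
  res2 <- mds_embed(d, dim = 2, seed = 1)
  expect_identical(res$points, res2$points)
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(mds_embed(neg), "non-negative")
})
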