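test_that("background_mask applies the near-white threshold rule", {
  ras <- array(255, dim = c(10, 10, 3))
  ras[3:5, 3:5, ] <- 0
  m <- background_mask(ras)
  expect_identical(sum(m), 9L)
  expect_true(all(m[3:5, 3:5]))
  # threshold boundary: (252,251,255) background; (249,255,255) object
  ras2 <- array(255, dim = c(2, 2, 3))
  ras2[1, 1, ] <- c(252, 251, 255)
  ras2[1, 2, ] <- c(249, 255, 255)
  m2 <- background_mask(ras2)
  expect_false(m2[1, 1])
  expect_true(m2[1, 2])
  expect_error(background_mask(array(255, dim = c(4, 4, 3))), "background")
})

test_that("background_mask recovers a known mask under compression speckle", {
  obj <- make_test_object(40)
  expect_identical(background_mask(obj$raster), obj$mask)
})

test_that("uniform disc recoloring matches the closed-form rotations", {
  # uniform mid-gray disc on white: all masked pixels identical, so the 12
  # outputs must each be uniform and equal the single rotated LUV point
  n <- 32
  ras <- array(255, dim = c(n, n, 3))
  mask <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - n / 2)^2 + (j - n / 2)^2 < 100)
  for (ch in 1:3) ras[, , ch][mask] <- 128
  cal <- calibration_target("cieluv", lum = 60, sat = 40)
  out <- calibrate_and_recolor(ras, "disc", cal)
  expect_length(out, 12)
  angles <- hue_angles(12)
  for (i in seq_along(out)) {
    px <- matrix(out[[i]]$raster, ncol = 3)[as.vector(mask), , drop = FALSE]
    expect_equal(nrow(unique(px)), 1) # uniform disc stays uniform
    expected <- luv_to_srgb(c(60, 40 * cos(angles[i] * pi / 180),
                              40 * sin(angles[i] * pi / 180)))
    expect_equal(as.numeric(px[1, ]), as.numeric(expected))
    # background untouched
    expect_true(all(out[[i]]$raster[, , 1][!mask] == 255))
  }
})

test_that("opposite hues are anti-parallel and L is hue-invariant", {
  obj <- make_test_object(40)
  cal <- calibration_target("cieluv", lum = 60, sat = 30)
  out <- calibrate_and_recolor(obj$raster, "obj", cal, mask = obj$mask)
  luv0 <- srgb_to_luv(out[[1]]$raster)
  luv6 <- srgb_to_luv(out[[7]]$raster) # 180 degrees away
  mv <- as.vector(obj$mask)
  u0 <- matrix(luv0, ncol = 3)[mv, 2:3]
  u6 <- matrix(luv6, ncol = 3)[mv, 2:3]
  # anti-parallel up to quantization noise on the strongly chromatic pixels
  strong <- sqrt(rowSums(u0^2)) > 5
  cosang <- rowSums(u0 * u6)[strong] /
    (sqrt(rowSums(u0^2))[strong] * sqrt(rowSums(u6^2))[strong])
  expect_lt(max(cosang), -0.98)
  audits <- vapply(out, function(s) audit_calibration(s, obj$mask)$achieved_mean_lum,
                   numeric(1))
  expect_lt(max(abs(audits - 60)), 1.0)
})

test_that("all recolored variants pass the independent calibration audit", {
  obj <- make_test_object(40)
  for (space in c("cieluv", "synthetic_hsv")) {
    cal <- if (space == "cieluv") calibration_target(space, 60, 30) else
      calibration_target(space, 140, 60)
    out <- calibrate_and_recolor(obj$raster, "obj", cal, mask = obj$mask)
    aud <- do.call(rbind, lapply(out, audit_calibration, mask = obj$mask))
    expect_lt(max(abs(aud$dev_lum)), 1.0)
    expect_lt(max(abs(aud$dev_sat)), 1.0)
  }
})

test_that("silhouettes are uniform, form-independent, and match the disc fill", {
  obj <- make_test_object(40)
  cal <- calibration_target("cieluv", 60, 40)
  sil <- make_silhouette(obj$raster, "obj", 2, cal, mask = obj$mask)
  px <- matrix(sil$raster, ncol = 3)[as.vector(obj$mask), , drop = FALSE]
  expect_equal(nrow(unique(px)), 1)
  # independent of object form
  obj2 <- make_test_object(40, seed = 99)
  sil2 <- make_silhouette(obj2$raster, "obj2", 2, cal, mask = obj2$mask)
  px2 <- matrix(sil2$raster, ncol = 3)[as.vector(obj2$mask), , drop = FALSE]
  expect_identical(px[1, ], px2[1, ])
  # equals the closed-form uniform fill
  expect_equal(as.numeric(px[1, ]), calibrated_fill_color(2, cal))
})

test_that("grayscale stimuli are achromatic with mean L on target", {
  obj <- make_test_object(40)
  cal <- calibration_target("cieluv", 60, 30)
  g <- make_grayscale(obj$raster, "obj", cal, mask = obj$mask)
  luv <- srgb_to_luv(g$raster)
  mv <- as.vector(obj$mask)
  m <- matrix(luv, ncol = 3)[mv, ]
  expect_lt(max(sqrt(m[, 2]^2 + m[, 3]^2)), 1.0)
  expect_lt(abs(mean(m[, 1]) - 60), 1.0)
  px <- matrix(g$raster, ncol = 3)[mv, ]
  expect_lte(max(abs(px[, 1] - px[, 2])), 1)
  expect_lte(max(abs(px[, 2] - px[, 3])), 1)
})

test_that("bar grids are factorial, deterministic, and area-equated", {
  cal <- calibration_target("cieluv")
  sp <- bar_spec(canvas_px = 400, length_px = 300, width_px = 60)
  expect_equal(bar_orientations(sp), seq(0, 165, by = 15))
  set <- make_bars(sp, cal)
  expect_length(set$stimuli, 144)
  expect_identical(nrow(set$manifest), 144L)
  counts <- unique(set$manifest[, c("orientation", "n_pixels")])
  expect_identical(counts$n_pixels[counts$orientation == 0],
                   counts$n_pixels[counts$orientation == 90])
  expect_lt(max(abs(counts$n_pixels - counts$n_pixels[1])) /
              counts$n_pixels[1], 0.01)
  set2 <- make_bars(sp, cal)
  expect_identical(set$stimuli[[5]]$raster, set2$stimuli[[5]]$raster)
  expect_error(bar_spec(canvas_px = 100, length_px = 120), "fit")
})

test_that("dissimilar-subset selection matches the exhaustive oracle", {
  # toy case: object 1 highly similar to everything
  m <- matrix(0.1, 4, 4)
  m[1, ] <- m[, 1] <- 0.9
  diag(m) <- 1
  g <- select_dissimilar_subset(m, 3)
  e <- select_dissimilar_subset(m, 3, method = "exhaustive")
  expect_setequal(as.integer(g), c(2L, 3L, 4L))
  expect_setequal(as.integer(g), as.integer(e))
  # k = n returns everything unchanged
  all4 <- select_dissimilar_subset(m, 4)
  expect_setequal(as.integer(all4), 1:4)
  expect_equal(attr(all4, "mean_similarity"), mean(m[upper.tri(m)]))
  # random matrices: greedy equals exhaustive optimum at small n, and the
  # subset mean never exceeds the full-set mean
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(runif(100), 10)
    s <- (x + t(x)) / 2
    diag(s) <- 1
    g <- select_dissimilar_subset(s, 6)
    full_mean <- mean(s[upper.tri(s)])
    expect_lte(attr(g, "mean_similarity"), full_mean)
  }
  expect_error(select_dissimilar_subset(m, 1), "between")
})
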