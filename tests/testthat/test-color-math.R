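test_that("srgb_to_luv maps the white point and grays to achromatic", {
  w <- srgb_to_luv(c(255, 255, 255))
  expect_equal(w[1], 100, tolerance = 1e-6)
  expect_lt(abs(w[2]), 1e-6)
  expect_lt(abs(w[3]), 1e-6)
  for (g in c(1, 64, 128, 200, 254)) {
    expect_lt(luv_chroma(srgb_to_luv(c(g, g, g))), 1e-6)
  }
  expect_error(srgb_to_luv(c(-1, 0, 0)), "within")
  expect_error(srgb_to_luv(c(0, 0, 300)), "within")
})

test_that("luv_to_srgb inverts the extremes and round-trips random pixels", {
  expect_equal(as.numeric(luv_to_srgb(c(100, 0, 0))), c(255, 255, 255))
  expect_equal(as.numeric(luv_to_srgb(c(0, 0, 0))), c(0, 0, 0))
  set.seed(11)
  px <- matrix(sample(0:255, 30000, replace = TRUE), ncol = 3)
  rt <- luv_to_srgb(srgb_to_luv(px))
  expect_lte(max(abs(rt - px)), 1)
  expect_identical(attr(rt, "gamut_clip_count"), 0L)
})

test_that("forward conversion agrees with an independent colorimetry library", {
  skip_if_not_installed("farver")
  set.seed(3)
  px <- matrix(sample(0:255, 600, replace = TRUE), ncol = 3)
  ref <- farver::convert_colour(px, "rgb", "luv")
  expect_lt(max(abs(srgb_to_luv(px) - ref)), 0.05)
})

test_that("chroma is the Euclidean norm and is rotation-invariant", {
  expect_identical(luv_chroma(0, 0), 0)
  expect_identical(luv_chroma(3, 4), 5)
  set.seed(5)
  luv <- cbind(runif(200, 0, 100), rnorm(200, sd = 40), rnorm(200, sd = 40))
  for (ang in c(17, 90, 133.5, 280)) {
    rot <- rotate_hue(luv, ang)
    expect_equal(luv_chroma(rot), luv_chroma(luv), tolerance = 1e-9)
    expect_identical(rot[, 1], luv[, 1])
  }
})

test_that("rotate_hue composes to the identity over a full turn", {
  expect_equal(rotate_hue(c(50, 13, 0), 90), cbind(50, 0, 13),
               tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(6)
  luv <- cbind(runif(50, 0, 100), rnorm(50, sd = 30), rnorm(50, sd = 30))
  out <- luv
  for (i in 1:12) out <- rotate_hue(out, 30)
  expect_equal(out, luv, tolerance = 1e-6)
  expect_equal(rotate_hue(luv, 0), luv, tolerance = 1e-12)
})

test_that("desaturate zeroes chroma, preserves L bitwise, and is idempotent", {
  set.seed(8)
  luv <- cbind(runif(100, 0, 100), rnorm(100, sd = 50), rnorm(100, sd = 50))
  d <- desaturate(luv)
  expect_true(all(luv_chroma(d) == 0))
  expect_identical(d[, 1], luv[, 1])
  expect_identical(desaturate(d), d)
})

test_that("equate_channel_mean shifts, preserves pattern, and respects bounds", {
  r <- equate_channel_mean(c(10, 20, 30), target = 25, bounds = c(0, 100))
  expect_equal(r$values, c(15, 25, 35))
  expect_identical(r$shrink, 1)
  # already on target: identity
  r2 <- equate_channel_mean(c(40, 50, 60), target = 50, bounds = c(0, 100))
  expect_equal(r2$values, c(40, 50, 60))
  # unmasked values untouched
  r3 <- equate_channel_mean(c(10, 20, 99), mask = c(TRUE, TRUE, FALSE),
                            target = 20, bounds = c(0, 100))
  expect_equal(r3$values, c(15, 25, 99))
  expect_error(equate_channel_mean(numeric(3), mask = rep(FALSE, 3),
                                   target = 1, bounds = c(0, 2)), "mask")
  expect_error(equate_channel_mean(1:3, target = 200, bounds = c(0, 100)),
               "outside")
})

test_that("overflow shrinkage matches the bisection oracle", {
  cases <- list(
    list(values = c(90, 100), target = 98, bounds = c(0, 100)),
    list(values = c(0, 10, 95), target = 80, bounds = c(0, 100)),
    list(values = c(5, 50, 70), target = 10, bounds = c(0, 100))
  )
  for (cs in cases) {
    mask <- rep(TRUE, length(cs$values))
    r <- equate_channel_mean(cs$values, mask, cs$target, cs$bounds)
    s_oracle <- oracle_shrink_bisection(cs$values, mask, cs$target, cs$bounds)
    expect_equal(r$shrink, s_oracle, tolerance = 1e-5)
    expect_equal(mean(r$values), cs$target, tolerance = 1e-9)
    expect_true(all(r$values >= cs$bounds[1] - 1e-9 &
                      r$values <= cs$bounds[2] + 1e-9))
    # pattern preserved up to the single scalar factor
    dev <- cs$values - mean(cs$values)
    expect_equal(r$values - cs$target, r$shrink * dev, tolerance = 1e-9)
  }
})

test_that("synthetic HSV decompose/compose are mutually inverse in-gamut", {
  d <- synthetic_hsv_decompose(c(80, 80, 80))
  expect_equal(d$lum, 80)
  expect_equal(d$sat, 0)
  expect_false(d$hue_defined)
  expect_equal(synthetic_hsv_decompose(c(60, 120, 180))$lum, 120)
  # grid round trip
  for (lum in c(60, 120, 200)) {
    smax <- synthetic_hsv_max_sat(lum)
    for (sat in c(0.2, 0.6, 0.95) * smax) {
      for (hue in seq(0, 330, by = 30)) {
        rgb <- synthetic_hsv_compose(hue, sat, lum)
        d <- synthetic_hsv_decompose(rgb)
        expect_equal(d$lum, lum, tolerance = 1e-6)
        expect_equal(d$sat, sat, tolerance = 1e-6)
        expect_equal(d$hue %% 360, hue %% 360, tolerance = 1e-6)
      }
    }
  }
  # arbitrary in-cube pixels round-trip through decompose -> compose
  set.seed(4)
  px <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  d <- synthetic_hsv_decompose(px)
  back <- synthetic_hsv_compose(d$hue, d$sat, d$lum)
  expect_lt(max(abs(back - px)), 1e-6)
})

test_that("synthetic HSV geometry: gray axis, cyclic symmetry, mean constraint", {
  expect_equal(as.numeric(synthetic_hsv_compose(0, 0, 77)), c(77, 77, 77))
  tri <- synthetic_hsv_compose(c(0, 120, 240), 40, 120)
  expect_equal(as.numeric(tri[2, ]), as.numeric(tri[1, c(3, 1, 2)]),
               tolerance = 1e-9)
  expect_equal(as.numeric(tri[3, ]), as.numeric(tri[1, c(2, 3, 1)]),
               tolerance = 1e-9)
  set.seed(9)
  hue <- runif(50, 0, 360); lum <- runif(50, 40, 200)
  sat <- runif(50) * synthetic_hsv_max_sat(lum)
  out <- synthetic_hsv_compose(hue, sat, lum)
  expect_lt(max(abs(rowMeans(out) - lum)), 1e-9)
  expect_error(
    synthetic_hsv_compose(0, 200, 240, require_full_circle = TRUE),
    "maximal admissible")
})
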