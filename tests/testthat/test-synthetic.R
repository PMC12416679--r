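test_that("scenes are deterministic in their seed and depth models behave", {
  s1 <- make_scene(32, 24, "flat", seed = 9)
  s2 <- make_scene(32, 24, "flat", seed = 9)
  expect_identical(s1, s2)
  s3 <- make_scene(32, 24, "flat", seed = 10)
  expect_false(identical(s1$sharp_texture, s3$sharp_texture))
  expect_equal(length(unique(as.numeric(s1$depth_map))), 1L)
  ramp <- make_scene(16, 40, "ramp", depth_range = c(0.43, 0.47), seed = 1)
  expect_true(all(diff(ramp$depth_map[, 1]) > 0))
  expect_equal(range(ramp$depth_map), c(0.43, 0.47))
  bump <- make_scene(30, 30, "bump", seed = 1)
  center <- bump$depth_map[15, 15]
  expect_lt(center, bump$depth_map[1, 1])
  expect_error(make_scene(0, 5), "invalid scene")
})

test_that("rendered stacks obey the defocus geometry", {
  sw <- plan_focus_sweep(0.45, 5, 0.02)
  sc <- make_scene(48, 48, "flat", depth_range = c(0.45, 0.45), seed = 2)
  st <- render_stack(sc, sw, optics_config(), noise_config(), seed = 1)
  # frame focused exactly at the scene depth is the sharpest
  mf <- vapply(st$frames, function(f) mean(focus_map(f)$values), numeric(1))
  expect_equal(which.max(mf), which.min(abs(sw - 0.45)))
  expect_equal(focal_planes(st), sw)
  # blur off, drift off, noise off: all frames identical to the texture
  st0 <- render_stack(sc, sw, optics_config(blur_scale = 0), noise_config(),
                      seed = 1)
  for (i in 2:5) expect_identical(st0$frames[[i]], st0$frames[[1]])
  expect_equal(st0$frames[[1]], sc$sharp_texture)
  expect_error(render_stack(sc, c(0.4, -0.1)), "invalid optics")
})

test_that("blur conserves mean intensity within 1% per frame", {
  sc <- make_scene(40, 40, "ramp", seed = 5)
  sw <- plan_focus_sweep(0.45, 6, 0.02)
  st <- render_stack(sc, sw, optics_config(magnification_drift = 0),
                     noise_config(), seed = 1)
  m0 <- mean(sc$sharp_texture)
  for (f in st$frames) expect_equal(mean(f), m0, tolerance = 0.01)
})

test_that("the sharpest frame follows the depth map along a ramp", {
  sw <- plan_focus_sweep(0.45, 10, 0.02)
  sc <- make_scene(64, 64, "ramp", seed = 12)
  st <- render_stack(sc, sw, optics_config(), noise_config(), seed = 2)
  vals <- vapply(st$frames, function(f) as.numeric(focus_map(f)$values),
                 numeric(64 * 64))
  best <- apply(vals, 1L, which.max)
  oracle <- apply(vapply(sw, function(U) abs(1 / U - 1 / as.numeric(sc$depth_map)),
                         numeric(64 * 64)), 1L, which.min)
  # agreement with the direct defocus argmin (adjacent planes nearly tie,
  # so exact argmax agreement is weaker than the within-one-plane rate)
  expect_gt(mean(abs(best - oracle) <= 1), 0.98)
  expect_gt(mean(best == oracle), 0.6)
  row_med <- apply(matrix(best, 64, 64), 1L, stats::median)
  expect_true(all(diff(row_med) >= 0))
})

test_that("rendering is a pure function of its seed", {
  sc <- make_scene(24, 24, "bump", seed = 3)
  sw <- plan_focus_sweep(0.45, 3, 0.02)
  noisy <- noise_config(photon_gain = 1e4, read_sigma = 0.01,
                        fixed_pattern_sigma = 0.02)
  a <- render_stack(sc, sw, optics_config(), noisy, seed = 8)
  b <- render_stack(sc, sw, optics_config(), noisy, seed = 8)
  expect_identical(a$frames, b$frames)
  c <- render_stack(sc, sw, optics_config(), noisy, seed = 9)
  expect_false(identical(a$frames, c$frames))
})

test_that("noise model matches its stated statistics", {
  x <- matrix(0.5, 1000, 1000)
  # all parameters zero: identity
  expect_identical(apply_noise(x, noise_config(), seed = 1), x)
  # Poisson variance: var = mean/gain within 5% at 1e6 pixels
  y <- apply_noise(x, noise_config(photon_gain = 1e4), seed = 9)
  expect_equal(stats::var(as.numeric(y)), 0.5 / 1e4, tolerance = 0.05)
  # fixed pattern is fixed: same field under different noise seeds
  nc <- noise_config(fixed_pattern_sigma = 0.05, fixed_pattern_seed = 77L)
  small <- matrix(0.5, 32, 32)
  a <- apply_noise(small, nc, seed = 1)
  b <- apply_noise(small, nc, seed = 2)
  expect_identical(a, b)
  nc2 <- noise_config(fixed_pattern_sigma = 0.05, fixed_pattern_seed = 78L)
  expect_false(identical(a, apply_noise(small, nc2, seed = 1)))
  expect_error(noise_config(read_sigma = -1), ">= 0")
})

test_that("synthetic charts carry the requested distortion", {
  chart <- make_color_chart()
  measured <- extract_patch_colors(chart$raster, chart$geometry)
  expect_equal(unname(measured), unname(colorchecker_srgb()), tolerance = 1e-9)
  gains <- c(0.8, 0.9, 1.1)
  chart2 <- make_color_chart(distortion = list(type = "gain", gains = gains))
  measured2 <- extract_patch_colors(chart2$raster, chart2$geometry)
  expected <- hyperstack:::clip_rgb255(sweep(colorchecker_srgb(), 2, gains, `*`))
  expect_equal(unname(measured2), unname(expected), tolerance = 1e-6)
  # cubic distortion moves colors by a reproducible, nonzero Lab distance
  chart3 <- make_color_chart(distortion = list(type = "cubic", strength = 0.15))
  chart3b <- make_color_chart(distortion = list(type = "cubic", strength = 0.15))
  expect_identical(chart3$raster, chart3b$raster)
  m3 <- extract_patch_colors(chart3$raster, chart3$geometry)
  dl <- color_distance(srgb_to_lab(m3), srgb_to_lab(colorchecker_srgb()), "lab")
  expect_gt(mean(dl), 0.5)
  expect_error(make_color_chart(colorchecker_srgb()[1, , drop = FALSE]),
               "unusable chart")
})

test_that("USAF element geometry follows the 2^(1/6) progression", {
  u <- make_usaf_image(2:3, pixels_per_mm = 200)
  lw <- u$element_table$line_width_um
  ratios <- lw[-length(lw)] / lw[-1L]
  expect_equal(ratios, rep(2^(1 / 6), length(ratios)), tolerance = 1e-9)
})

test_that("unblurred bars reach full modulation and heavy blur kills it", {
  u <- make_usaf_image(2, pixels_per_mm = 300, contrast = 0.9, elements = 1:2)
  p <- sample_profile(u$raster, c(u$specs$x0[1], u$specs$y0[1]),
                      c(u$specs$x1[1], u$specs$y1[1]))
  expect_equal(min(p$intensities), 1 - 0.9, tolerance = 0.02)
  expect_equal(max(p$intensities), 1, tolerance = 0.02)
  # blur much larger than the line width flattens the finest element
  lw_um <- u$element_table$line_width_um[2]
  u2 <- make_usaf_image(2, blur_sigma = 3 * lw_um, pixels_per_mm = 300,
                        contrast = 0.9, elements = 1:2)
  p2 <- sample_profile(u2$raster, c(u2$specs$x0[2], u2$specs$y0[2]),
                       c(u2$specs$x1[2], u2$specs$y1[2]))
  # bar modulation is wiped out; only a broad low-frequency dip survives
  expect_lt(max(p2$intensities) - min(p2$intensities), 0.3)
  expect_false(judge_element(smooth_profile(p2, window = 9))$resolved)
  expect_error(make_usaf_image(7, pixels_per_mm = 100), "aliasing risk")
})

test_that("Gaussian blur attenuates a square wave per its analytic MTF", {
  p <- 16; sig <- 2.5
  x <- matrix(rep(rep(c(1, 0), each = p / 2), length.out = 512), 64, 512,
              byrow = TRUE)
  b <- hyperstack:::gaussian_blur(x, sig, mode = "circular")
  prof <- b[32, ]
  measured <- max(prof) - min(prof)
  # Fourier series of the 0/1 square wave with Gaussian attenuation
  pred <- 0
  for (n in seq(1, 41, 2)) {
    pred <- pred + (2 / (pi * n)) * (-1)^((n - 1) / 2) *
      exp(-2 * pi^2 * n^2 * sig^2 / p^2)
  }
  expect_equal(measured, 2 * pred, tolerance = 0.02)
})
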