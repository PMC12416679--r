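identical_stack_fixture <- function(h = 24, w = 24, k = 3, seed = 6) {
  f <- hyperstack:::with_seed(seed, array(runif(h * w * 3), c(h, w, 3)))
  list(fused = f, stack = image_stack(rep(list(f), k)))
}

test_that("all four metrics hit their perfect-fusion limits exactly", {
  fx <- identical_stack_fixture()
  expect_equal(nmi_metric(fx$fused, fx$stack), 1, tolerance = 1e-9)
  expect_equal(spatial_frequency_error(fx$fused, fx$stack), 0, tolerance = 1e-9)
  expect_equal(yang_ssim(fx$fused, fx$stack), 1, tolerance = 1e-9)
  expect_equal(chen_varshney(fx$fused, fx$stack), 0, tolerance = 1e-9)
  rep <- assess(fx$fused, fx$stack)
  expect_equal(c(rep$nmi_score, rep$spatial_frequency_error,
                 rep$yang_ssim_score, rep$chen_varshney_score),
               c(1, 0, 1, 0), tolerance = 1e-9)
})

test_that("NMI matches a hand-computed joint histogram on a tiny pair", {
  # 8x8 two-level images
  a <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  b <- matrix(rep(c(0.2, 0.8, 0.2, 0.8), each = 16), 8, 8)
  st <- image_stack(list(array(rep(b, 3), c(8, 8, 3))))
  got <- nmi_metric(array(rep(a, 3), c(8, 8, 3)), st, bins = 4)
  want <- oracle_nmi(as.numeric(a), as.numeric(b), 4L)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("NMI of independent noise images vanishes", {
  set.seed(123)
  a <- matrix(runif(512 * 512), 512, 512)
  b <- matrix(runif(512 * 512), 512, 512)
  st <- image_stack(list(b))
  expect_lt(nmi_metric(a, st), 0.05)
})

test_that("single-frame self-comparison gives nmi 1 and sf_error 0", {
  f <- hyperstack:::with_seed(3, array(runif(10 * 10 * 3), c(10, 10, 3)))
  st <- image_stack(list(f))
  expect_equal(nmi_metric(f, st), 1, tolerance = 1e-12)
  expect_equal(spatial_frequency_error(f, st), 0, tolerance = 1e-12)
})

test_that("spatial frequency error matches hand computation and blur is negative", {
  set.seed(9)
  a <- matrix(sample(0:4, 16, replace = TRUE) / 4, 4, 4)
  b <- matrix(sample(0:4, 16, replace = TRUE) / 4, 4, 4)
  st <- image_stack(list(array(rep(b, 3), c(4, 4, 3))))
  got <- spatial_frequency_error(array(rep(a, 3), c(4, 4, 3)), st)
  # reference from per-pixel max |difference| over the 1-frame stack = |diffs of b|
  want <- (oracle_sf(a) - oracle_sf_abs_ref(list(b))) / oracle_sf_abs_ref(list(b))
  expect_equal(got, want, tolerance = 1e-12)
  fx <- mosaic_fixture()
  ideal <- fx$sharp
  blurred <- hyperstack:::gaussian_blur(ideal, 1.5)
  expect_lt(spatial_frequency_error(blurred, fx$stack), 0)
  const <- image_stack(list(array(0.5, c(4, 4, 3))))
  expect_error(spatial_frequency_error(array(0.5, c(4, 4, 3)), const),
               "undefined")
})

test_that("Yang's score matches the closed-form SSIM on one full window", {
  set.seed(31)
  a <- matrix(runif(121, 0.3, 0.7), 11, 11)
  b <- matrix(runif(121, 0.3, 0.7), 11, 11)
  smap <- hyperstack:::ssim_map(a, b, 11L, 0.01^2, 0.03^2)
  want <- oracle_ssim_window(as.numeric(a), as.numeric(b))
  expect_equal(smap[6, 6], want, tolerance = 1e-9)
})

test_that("the ideal mosaic scores higher on Yang than either input frame", {
  fx <- mosaic_fixture()
  ideal <- fuse_stack(fx$stack, fx$maps)$raster
  s_ideal <- yang_ssim(ideal, fx$stack)
  s_f1 <- yang_ssim(fx$stack$frames[[1]], fx$stack)
  s_f2 <- yang_ssim(fx$stack$frames[[2]], fx$stack)
  expect_gt(s_ideal, s_f1)
  expect_gt(s_ideal, s_f2)
})

test_that("Chen-Varshney matches its brute-force evaluation and ranks noise", {
  set.seed(15)
  f1 <- matrix(runif(256), 16, 16)
  f2 <- matrix(runif(256), 16, 16)
  fused <- (f1 + f2) / 2
  st <- image_stack(list(array(rep(f1, 3), c(16, 16, 3)),
                         array(rep(f2, 3), c(16, 16, 3))))
  got <- chen_varshney(array(rep(fused, 3), c(16, 16, 3)), st,
                       region_size = 16L, csf_sigma = 2)
  want <- oracle_cv(fused, list(f1, f2), 16L, 2)
  expect_equal(got, want, tolerance = 1e-9)
  # additive noise strictly increases the error score
  fx <- mosaic_fixture()
  ideal <- fuse_stack(fx$stack, fx$maps)$raster
  noisy <- hyperstack:::clip01(ideal +
    hyperstack:::with_seed(2, array(rnorm(length(ideal), sd = 0.05),
                                    dim(ideal))))
  expect_gt(chen_varshney(noisy, fx$stack), chen_varshney(ideal, fx$stack))
  blank <- image_stack(list(array(0.5, c(8, 8, 3))))
  expect_error(chen_varshney(array(0.5, c(8, 8, 3)), blank), "undefined")
})

test_that("all metrics degrade monotonically under increasing blur", {
  fx <- mosaic_fixture()
  ideal <- fuse_stack(fx$stack, fx$maps)$raster
  # start from a mildly degraded image: full-reference scores against a
  # stack whose frames are themselves half defocused are maximized near,
  # not at, the all-sharp mosaic, so the monotone regime begins just off it
  sigmas <- c(0.5, 1, 2, 4, 8)
  scores <- sapply(sigmas, function(s) {
    f <- hyperstack:::gaussian_blur(ideal, s)
    r <- assess(f, fx$stack)
    c(r$nmi_score, r$spatial_frequency_error, r$yang_ssim_score,
      r$chen_varshney_score)
  })
  tol <- 1e-9
  expect_true(all(diff(scores[1, ]) <= tol))   # nmi non-increasing
  expect_true(all(diff(scores[2, ]) <= tol))   # sf drops below 0
  expect_true(all(diff(scores[3, ]) <= tol))   # yang non-increasing
  expect_true(all(diff(scores[4, ]) >= -tol))  # cv error non-decreasing
})

test_that("metrics are deterministic and the report serializes", {
  fx <- mosaic_fixture()
  ideal <- fuse_stack(fx$stack, fx$maps)$raster
  r1 <- assess(ideal, fx$stack)
  r2 <- assess(ideal, fx$stack)
  expect_identical(as.data.frame(r1)$score, as.data.frame(r2)$score)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(r1, path = f)
  back <- utils::read.csv(f)
  expect_equal(back$score, df$score, tolerance = 1e-12)
  expect_equal(back$metric, df$metric)
})
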