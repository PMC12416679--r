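# Internal raster helpers shared by all pipeline stages.
#
# Conventions (package-wide):
#  * a frame is an H x W x 3 numeric array with intensities in [0, 1];
#    single-channel rasters are H x W matrices,
#  * pixel coordinates are (x, y) = (column, row), 1-based, where integer
#    coordinates address pixel centers (R matrix indexing order is [y, x]).

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_raster <- function(x) {
  is.numeric(x) && (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L))
}

raster_dim <- function(x) dim(x)[1:2]

n_channels <- function(x) if (is.matrix(x)) 1L else dim(x)[3L]

#' Rec. 709 luminance of a raster
#'
#' Collapses a 3-channel raster to a single luminance plane with the
#' Rec. 709 weights (0.2126, 0.7152, 0.0722). Single-channel input is
#' returned unchanged.
#'
#' @param x raster (`H x W` matrix or `H x W x 3` array) in `[0, 1]`.
#' @return `H x W` matrix.
#' @export
luminance <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[3L] == 1L) return(x[, , 1L])
  0.2126 * x[, , 1L] + 0.7152 * x[, , 2L] + 0.0722 * x[, , 3L]
}

# Reflected ("symmetric") index sequence of length n + 2 * pad: the border
# samples mirror without repeating the edge twice beyond the raster
# (1-based: pad 2 on n = 4 gives 2 1 | 1 2 3 4 | 4 3).
reflect_index <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  pos <- (1L - pad):(n + pad)
  m <- 2L * n
  p <- ((pos - 1L) %% m + m) %% m      # 0 .. 2n-1
  ifelse(p < n, p + 1L, m - p)
}

pad_matrix <- function(m, py, px, mode = c("symmetric", "replicate", "circular")) {
  mode <- match.arg(mode)
  h <- nrow(m); w <- ncol(m)
  iy <- switch(mode,
    symmetric = reflect_index(h, py),
    replicate = pmin(pmax((1L - py):(h + py), 1L), h),
    circular  = ((((1L - py):(h + py)) - 1L) %% h) + 1L)
  ix <- switch(mode,
    symmetric = reflect_index(w, px),
    replicate = pmin(pmax((1L - px):(w + px), 1L), w),
    circular  = ((((1L - px):(w + px)) - 1L) %% w) + 1L)
  m[iy, ix, drop = FALSE]
}

# 2-D convolution (correlation with the flipped kernel is not needed for the
# symmetric kernels used here) by shift-and-add; exact arithmetic, chosen
# boundary handling. Kernel dimensions must be odd.
conv2_kernel <- function(m, kernel, mode = "symmetric") {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  p <- pad_matrix(m, ry, rx, mode)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      k <- kernel[i, j]
      if (k == 0) next
      out <- out + k * p[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
    }
  }
  out
}

# Box mean over an odd window using summed-area tables on a padded matrix.
box_mean <- function(m, window, mode = "symmetric") {
  stopifnot(window %% 2L == 1L, window >= 1L)
  if (window == 1L) return(m)
  r <- (window - 1L) %/% 2L
  p <- pad_matrix(m, r, r, mode)
  ph <- nrow(p); pw <- ncol(p)
  s <- matrix(0, ph + 1L, pw + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  h <- nrow(m); w <- ncol(m)
  y0 <- seq_len(h); x0 <- seq_len(w)
  # window for output (y, x) spans padded rows y .. y + 2r, cols x .. x + 2r
  tot <- s[y0 + window, x0 + window + 0L, drop = FALSE] -
    s[y0, x0 + window, drop = FALSE] -
    s[y0 + window, x0, drop = FALSE] +
    s[y0, x0, drop = FALSE]
  tot / (window * window)
}

gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur; sigma in pixels. sigma = 0 returns the input.
gaussian_blur <- function(x, sigma, mode = "symmetric") {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel1d(sigma)
  blur_plane <- function(m) {
    r <- (length(k) - 1L) %/% 2L
    p <- pad_matrix(m, r, 0L, mode)
    h <- nrow(m)
    out <- matrix(0, h, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[i:(i + h - 1L), , drop = FALSE]
    }
    p <- pad_matrix(out, 0L, r, mode)
    w <- ncol(m)
    out <- matrix(0, nrow(m), w)
    for (i in seq_along(k)) {
      out <- out + k[i] * p[, i:(i + w - 1L), drop = FALSE]
    }
    out
  }
  apply_planes(x, blur_plane)
}

# Apply a matrix -> matrix function to every channel of a raster.
apply_planes <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  out <- x
  for (c in seq_len(dim(x)[3L])) out[, , c] <- f(x[, , c])
  out
}

# Bilinear sampling of a single plane at continuous (x, y) positions
# (1-based pixel-center coordinates). Out-of-range positions are clamped
# to the border (replicate) and flagged in the "inside" attribute.
bilinear_sample <- function(m, xs, ys) {
  h <- nrow(m); w <- ncol(m)
  inside <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  x <- pmin(pmax(xs, 1), w)
  y <- pmin(pmax(ys, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  if (w == 1L) x0 <- rep(1, length(x))
  if (h == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1L, w); y1 <- pmin(y0 + 1L, h)
  i00 <- (x0 - 1) * h + y0
  i10 <- (x1 - 1) * h + y0
  i01 <- (x0 - 1) * h + y1
  i11 <- (x1 - 1) * h + y1
  v <- (1 - fy) * ((1 - fx) * m[i00] + fx * m[i10]) +
    fy * ((1 - fx) * m[i01] + fx * m[i11])
  attr(v, "inside") <- inside
  v
}

# Warp a raster by a 2x3 affine matrix mapping output (reference) pixel
# coordinates to input coordinates: (x', y') = A %*% c(x, y, 1).
warp_affine_raster <- function(x, A) {
  h <- raster_dim(x)[1L]; w <- raster_dim(x)[2L]
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  xs <- A[1, 1] * g$x + A[1, 2] * g$y + A[1, 3]
  ys <- A[2, 1] * g$x + A[2, 2] * g$y + A[2, 3]
  warp_plane <- function(m) {
    v <- bilinear_sample(m, xs, ys)
    matrix(as.numeric(v), h, w)
  }
  apply_planes(x, warp_plane)
}

# Scale a raster about its center by factor s (s > 1 magnifies).
scale_about_center <- function(x, s) {
  h <- raster_dim(x)[1L]; w <- raster_dim(x)[2L]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  A <- matrix(c(1 / s, 0, cx - cx / s,
                0, 1 / s, cy - cy / s), 2, 3, byrow = TRUE)
  warp_affine_raster(x, A)
}

# Evaluate code with a temporarily fixed RNG state; restores (or removes)
# .Random.seed afterwards so generators are pure functions of their seeds.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2017L + as.integer(stream) * 7919L
}

stop_hs <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
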