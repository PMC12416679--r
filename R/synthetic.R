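# Seeded synthetic inputs: defocus-blurred depth scenes, sensor noise,
# distorted color charts and tri-bar resolution targets. Everything here is a
# pure function of its seed and parameters.

#' Sensor-noise configuration
#'
#' Models the three noise sources applied to raw frames, in physical order:
#' shot (photon) noise whose standard deviation is the square root of the
#' collected signal, Gaussian readout noise with identical fluctuations
#' across pixels, and static fixed-pattern gain variation appearing as a
#' repeatable bright/dark pixel pattern.
#'
#' @param photon_gain expected photoelectrons at intensity 1.0; 0 disables
#'   shot noise.
#' @param read_sigma readout-noise standard deviation in intensity units;
#'   0 disables.
#' @param fixed_pattern_sigma relative standard deviation of the per-pixel
#'   gain field; 0 disables.
#' @param fixed_pattern_seed seed generating the gain field; the field
#'   depends on this seed only, so it is identical across exposures.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(photon_gain = 0, read_sigma = 0,
                         fixed_pattern_sigma = 0, fixed_pattern_seed = 0L) {
  if (any(c(photon_gain, read_sigma, fixed_pattern_sigma) < 0)) {
    stop_hs("synthetic", "noise parameters must be >= 0")
  }
  structure(list(photon_gain = photon_gain, read_sigma = read_sigma,
                 fixed_pattern_sigma = fixed_pattern_sigma,
                 fixed_pattern_seed = as.integer(fixed_pattern_seed)),
            class = "noise_config")
}

#' Rendering optics configuration
#'
#' @param lens a [thin_lens_config()] (kept for provenance; the renderer works
#'   from focal-plane distances directly).
#' @param blur_scale pixels of Gaussian PSF sigma per unit defocus
#'   `|1/U_i - 1/z|` (1/m); the circle-of-confusion surrogate. The default
#'   80 makes the ends of a +/- 2 cm sweep at the 0.45 m working distance
#'   strongly defocused (sigma ~ 8 px) while keeping the per-plane depth of
#'   field comparable to the plane spacing of a 10-20 frame stack, i.e. a
#'   sweep designed the way the acquisition plans it.
#' @param magnification_drift relative scale change per meter of focal-plane
#'   shift away from the sweep median.
#' @param depth_layers number of quantized depth layers used for spatially
#'   varying blur.
#' @return object of class `optics_config`.
#' @export
optics_config <- function(lens = thin_lens_config(), blur_scale = 80,
                          magnification_drift = 0, depth_layers = 16L) {
  if (blur_scale < 0) stop_hs("synthetic", "blur_scale must be >= 0")
  if (depth_layers < 1L) stop_hs("synthetic", "depth_layers must be >= 1")
  structure(list(lens = lens, blur_scale = blur_scale,
                 magnification_drift = magnification_drift,
                 depth_layers = as.integer(depth_layers)),
            class = "optics_config")
}

#' Generate a synthetic skin-like scene with a depth map
#'
#' The texture is a skin-toned base carrying band-limited speckle plus dark
#' lesion-like blobs, so local focus measures are informative everywhere.
#' Depth models: `flat` (constant depth), `ramp` (depth strictly increasing
#' with the row index), `bump` (a central protrusion toward the camera).
#'
#' @param width,height scene size in pixels.
#' @param depth_model one of `"flat"`, `"ramp"`, `"bump"`.
#' @param depth_range length-2 numeric, near and far depth (m); default the
#'   0.43–0.47 m working-distance regime.
#' @param n_lesions number of dark blobs.
#' @param seed RNG seed; output is a pure function of it.
#' @return object of class `synthetic_scene`: list with `sharp_texture`
#'   (`H x W x 3`, `[0,1]`), `depth_map` (`H x W`, meters) and `seed`.
#' @export
make_scene <- function(width, height, depth_model = c("flat", "ramp", "bump"),
                       depth_range = c(0.43, 0.47), n_lesions = 3L, seed = 1L) {
  depth_model <- match.arg(depth_model)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop_hs("synthetic", "invalid scene dimensions")
  if (any(depth_range <= 0) || depth_range[1L] > depth_range[2L]) {
    stop_hs("synthetic", "depth_range must be positive and ordered")
  }
  tex <- with_seed(derive_seed(seed, 1L), {
    speckle <- gaussian_blur(matrix(rnorm(height * width), height, width), 1.5)
    speckle <- speckle / max(abs(range(speckle)), 1e-12)
    fine <- matrix(rnorm(height * width, sd = 0.25), height, width)
    base <- c(0.80, 0.62, 0.55)                     # skin tone
    out <- array(0, c(height, width, 3L))
    xg <- matrix(seq_len(width), height, width, byrow = TRUE)
    yg <- matrix(seq_len(height), height, width)
    blob <- matrix(0, height, width)
    for (b in seq_len(n_lesions)) {
      cx <- runif(1, 0.2, 0.8) * width
      cy <- runif(1, 0.2, 0.8) * height
      r <- runif(1, 0.08, 0.2) * min(width, height)
      blob <- blob + 0.55 * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * r^2))
    }
    blob <- pmin(blob, 0.7)
    for (c in 1:3) {
      amp <- c(0.12, 0.10, 0.09)[c]
      plane <- base[c] + amp * speckle + 0.03 * fine - blob * c(0.55, 0.45, 0.35)[c]
      out[, , c] <- pmin(pmax(plane, 0.05), 0.95)
    }
    out
  })
  zn <- depth_range[1L]; zf <- depth_range[2L]
  depth <- switch(depth_model,
    flat = matrix((zn + zf) / 2, height, width),
    ramp = matrix(seq(zn, zf, length.out = height), height, width),
    bump = {
      xg <- matrix(seq_len(width), height, width, byrow = TRUE)
      yg <- matrix(seq_len(height), height, width)
      cx <- (width + 1) / 2; cy <- (height + 1) / 2
      s <- 0.25 * min(width, height)
      g <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * s^2))
      zf - (zf - zn) * g
    })
  structure(list(sharp_texture = tex, depth_map = depth, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Apply the sensor-noise model to a raster
#'
#' Order: shot noise (`Poisson(value * photon_gain) / photon_gain`), then
#' additive Gaussian readout noise, then multiplication by the fixed-pattern
#' gain field `N(1, fixed_pattern_sigma)` (a function of `fixed_pattern_seed`
#' only), then clipping to `[0, 1]`.
#'
#' @param raster raster in `[0, 1]`.
#' @param noise a [noise_config()].
#' @param seed seed for the shot/read noise draws.
#' @return raster of the same shape, in `[0, 1]`.
#' @export
apply_noise <- function(raster, noise = noise_config(), seed = 0L) {
  stopifnot(inherits(noise, "noise_config"))
  x <- raster
  if (noise$photon_gain > 0 || noise$read_sigma > 0) {
    x <- with_seed(derive_seed(seed, 2L), {
      y <- x
      if (noise$photon_gain > 0) {
        y[] <- stats::rpois(length(y), pmax(y, 0) * noise$photon_gain) /
          noise$photon_gain
      }
      if (noise$read_sigma > 0) {
        y <- y + stats::rnorm(length(y), sd = noise$read_sigma)
      }
      y
    })
  }
  if (noise$fixed_pattern_sigma > 0) {
    h <- raster_dim(raster)[1L]; w <- raster_dim(raster)[2L]
    gain <- with_seed(noise$fixed_pattern_seed,
                      matrix(stats::rnorm(h * w, 1, noise$fixed_pattern_sigma),
                             h, w))
    x <- apply_planes(x, function(m) m * gain)
  }
  clip01(x)
}

#' Render a focus stack from a synthetic scene
#'
#' For each focal-plane distance `U_i` in the sweep, every pixel at scene
#' depth `z` is blurred with a Gaussian PSF of sigma
#' `blur_scale * |1/U_i - 1/z|` pixels (circle-of-confusion surrogate,
#' computed on quantized depth layers), the frame is scaled about its center
#' by `1 + magnification_drift * (U_i - median(sweep))`, and sensor noise is
#' applied last. Frame metadata records `U_i`.
#'
#' @param scene a [make_scene()] result.
#' @param sweep focal-plane distances (m), e.g. from [plan_focus_sweep()].
#' @param optics an [optics_config()].
#' @param noise a [noise_config()].
#' @param seed base seed for the per-frame noise draws.
#' @return an [image_stack()].
#' @export
render_stack <- function(scene, sweep, optics = optics_config(),
                         noise = noise_config(), seed = 0L) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(optics, "optics_config"))
  if (length(sweep) < 1L) stop_hs("synthetic", "sweep must be non-empty")
  if (any(sweep <= 0)) stop_hs("synthetic", "invalid optics: sweep distances must be positive")
  z <- scene$depth_map
  zq <- quantize_depth(z, optics$depth_layers)
  med <- stats::median(sweep)
  frames <- vector("list", length(sweep))
  metas <- vector("list", length(sweep))
  for (i in seq_along(sweep)) {
    Ui <- sweep[i]
    img <- scene$sharp_texture
    if (optics$blur_scale > 0) {
      img <- composite_depth_blur(scene$sharp_texture, zq, Ui, optics$blur_scale)
    }
    s <- 1 + optics$magnification_drift * (Ui - med)
    if (abs(s - 1) > 1e-12) img <- scale_about_center(img, s)
    img <- clip01(img)
    img <- apply_noise(img, noise, seed = derive_seed(seed, 100L + i))
    frames[[i]] <- img
    metas[[i]] <- frame_meta(index = i - 1L, focal_plane_distance = Ui)
  }
  image_stack(frames, metas)
}

# Quantize a depth map into <= n_layers representative depths; returns
# list(layers = depths, index = integer matrix of layer assignment).
quantize_depth <- function(z, n_layers) {
  u <- sort(unique(as.numeric(z)))
  if (length(u) <= n_layers) {
    idx <- matrix(match(as.numeric(z), u), nrow(z), ncol(z))
    return(list(layers = u, index = idx))
  }
  br <- seq(min(u), max(u), length.out = n_layers + 1L)
  idx <- matrix(findInterval(as.numeric(z), br, rightmost.closed = TRUE),
                nrow(z), ncol(z))
  centers <- vapply(seq_len(n_layers),
                    function(k) mean(z[idx == k]), numeric(1))
  centers[is.nan(centers)] <- (br[-length(br)] + br[-1L])[is.nan(centers)] / 2
  list(layers = centers, index = idx)
}

# Scatter-form layer compositing: each quantized depth layer spreads its
# own masked light through the layer's defocus PSF and the contributions
# are summed. Every source pixel distributes unit mass, so total intensity
# is conserved exactly (up to border reflection and final clipping); mild
# weight banding at layer boundaries is second-order.
composite_depth_blur <- function(tex, zq, Ui, blur_scale) {
  num <- array(0, dim(tex))
  for (k in seq_along(zq$layers)) {
    mask <- (zq$index == k) * 1
    if (!any(mask > 0)) next
    sig <- blur_scale * abs(1 / Ui - 1 / zq$layers[k])
    if (sig > 1e-4) {
      for (c in 1:3) {
        num[, , c] <- num[, , c] +
          gaussian_blur(tex[, , c] * mask, sig, mode = "symmetric")
      }
    } else {
      for (c in 1:3) num[, , c] <- num[, , c] + tex[, , c] * mask
    }
  }
  num
}

#' Published 24-patch ColorChecker sRGB reference values
#'
#' The widely published sRGB coordinates (0–255, D65) of the classic
#' 24-patch chart, row-major from dark skin to black.
#'
#' @return 24 x 3 numeric matrix with rownames naming the patches.
#' @export
colorchecker_srgb <- function() {
  m <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52),
    ncol = 3L, byrow = TRUE)
  rownames(m) <- c("dark skin", "light skin", "blue sky", "foliage",
                   "blue flower", "bluish green", "orange", "purplish blue",
                   "moderate red", "purple", "yellow green", "orange yellow",
                   "blue", "green", "red", "yellow", "magenta", "cyan",
                   "white", "neutral 8", "neutral 6.5", "neutral 5",
                   "neutral 3.5", "black")
  colnames(m) <- c("R", "G", "B")
  m
}

#' Render a synthetic 24-patch color chart
#'
#' Produces a 4 x 6 patch-grid image whose patches carry
#' `distortion(reference color)` plus sensor noise, together with the patch
#' rectangle geometry needed by [extract_patch_colors()].
#'
#' @param reference_patches `n x 3` matrix of reference RGB values (0–255);
#'   default [colorchecker_srgb()].
#' @param distortion either a function mapping an `n x 3` RGB (0–255) matrix
#'   to distorted values, or a spec list: `list(type = "identity")`,
#'   `list(type = "gain", gains = c(r, g, b))`, or
#'   `list(type = "cubic", strength = s)` applying
#'   `c' = c + s * (c/255)^3 * 255` per channel.
#' @param noise a [noise_config()].
#' @param patch_size patch side length in pixels.
#' @param margin gap between patches in pixels.
#' @param seed noise seed.
#' @return list with `raster` (`H x W x 3`, `[0,1]`) and `geometry`, a
#'   data.frame `(patch, row0, row1, col0, col1)` of 1-based inclusive
#'   patch rectangles.
#' @export
make_color_chart <- function(reference_patches = colorchecker_srgb(),
                             distortion = list(type = "identity"),
                             noise = noise_config(), patch_size = 48L,
                             margin = 8L, seed = 0L) {
  ref <- as.matrix(reference_patches)
  if (nrow(ref) < 2L) stop_hs("synthetic", "unusable chart: need >= 2 patches")
  dist_fun <- distortion_fun(distortion)
  vals <- clip_rgb255(dist_fun(ref))
  ncol_grid <- 6L
  nrow_grid <- ceiling(nrow(ref) / ncol_grid)
  h <- nrow_grid * patch_size + (nrow_grid + 1L) * margin
  w <- ncol_grid * patch_size + (ncol_grid + 1L) * margin
  raster <- array(0.5, c(h, w, 3L))
  geom <- data.frame(patch = seq_len(nrow(ref)), row0 = NA_integer_,
                     row1 = NA_integer_, col0 = NA_integer_, col1 = NA_integer_)
  for (p in seq_len(nrow(ref))) {
    gr <- (p - 1L) %/% ncol_grid
    gc <- (p - 1L) %% ncol_grid
    r0 <- margin + gr * (patch_size + margin) + 1L
    c0 <- margin + gc * (patch_size + margin) + 1L
    r1 <- r0 + patch_size - 1L
    c1 <- c0 + patch_size - 1L
    for (ch in 1:3) raster[r0:r1, c0:c1, ch] <- vals[p, ch] / 255
    geom[p, 2:5] <- c(r0, r1, c0, c1)
  }
  raster <- apply_noise(raster, noise, seed = seed)
  list(raster = raster, geometry = geom)
}

distortion_fun <- function(distortion) {
  if (is.function(distortion)) return(distortion)
  stopifnot(is.list(distortion), !is.null(distortion$type))
  switch(distortion$type,
    identity = function(m) m,
    gain = {
      g <- distortion$gains
      stopifnot(length(g) == 3L)
      function(m) sweep(m, 2L, g, `*`)
    },
    cubic = {
      s <- if (is.null(distortion$strength)) 0.15 else distortion$strength
      function(m) m + s * (m / 255)^3 * 255
    },
    stop_hs("synthetic", "unknown distortion type: ", distortion$type))
}

clip_rgb255 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Render a synthetic USAF 1951 tri-bar target
#'
#' Draws, for each (group, element) pair, three vertical dark bars of the
#' standard line width (bar length 5x width, bar spacing one width) on a
#' white background, applies a Gaussian blur, and returns per-element probe
#' segments crossing the three bars perpendicularly with margin on both
#' sides.
#'
#' @param groups integer vector of group numbers to render.
#' @param blur_sigma Gaussian blur sigma in micrometers (0 = none).
#' @param pixels_per_mm sampling density; the finest rendered element must
#'   span at least 4 pixels per line.
#' @param contrast bar depth in `[0, 1]`: bars are drawn at `1 - contrast`.
#' @param elements element numbers to render within each group (default 1:6).
#' @return list with `raster` (`H x W` matrix), `specs` (data.frame
#'   `group, element, x0, y0, x1, y1` probe segments in 1-based pixel-center
#'   coordinates) and `element_table` (geometry with `lp_per_mm`,
#'   `line_width_um`).
#' @export
make_usaf_image <- function(groups, blur_sigma = 0, pixels_per_mm = 400,
                            contrast = 1, elements = 1:6) {
  stopifnot(length(groups) >= 1L, contrast >= 0, contrast <= 1)
  grid <- expand.grid(element = elements, group = groups)[, 2:1]
  lw_mm <- 0.5 / 2^(grid$group + (grid$element - 1) / 6)
  lw_px <- lw_mm * pixels_per_mm
  if (min(lw_px) < 4) {
    stop_hs("resolution", "aliasing risk: finest element spans ",
            sprintf("%.2f", min(lw_px)), " px per line; need >= 4")
  }
  pad <- ceiling(2 * max(lw_px)) + 4
  el_w <- 5 * lw_px          # 3 bars + 2 gaps
  el_h <- 5 * lw_px          # bar length
  width <- ceiling(sum(el_w) + pad * (length(el_w) + 1L))
  height <- ceiling(max(el_h) + 2 * pad)
  img <- matrix(1, height, width)
  specs <- data.frame(group = grid$group, element = grid$element,
                      x0 = NA_real_, y0 = NA_real_, x1 = NA_real_, y1 = NA_real_)
  x_cursor <- pad
  xs <- seq_len(width)        # pixel centers
  for (i in seq_len(nrow(grid))) {
    w <- lw_px[i]
    y_mid <- height / 2
    y0 <- y_mid - el_h[i] / 2; y1 <- y_mid + el_h[i] / 2
    rows <- which(seq_len(height) >= y0 & seq_len(height) <= y1)
    for (bar in 0:2) {
      bx0 <- x_cursor + bar * 2 * w
      bx1 <- bx0 + w
      # anti-aliased coverage of [bx0, bx1] over pixel [x - .5, x + .5]
      cov <- pmax(0, pmin(xs + 0.5, bx1) - pmax(xs - 0.5, bx0))
      cols <- which(cov > 0)
      for (cc in cols) {
        img[rows, cc] <- img[rows, cc] - contrast * cov[cc]
      }
    }
    margin <- 2 * w
    specs$x0[i] <- x_cursor - margin
    specs$x1[i] <- x_cursor + 5 * w + margin
    specs$y0[i] <- y_mid
    specs$y1[i] <- y_mid
    x_cursor <- x_cursor + el_w[i] + pad
  }
  specs$x0 <- pmax(specs$x0, 1)
  specs$x1 <- pmin(specs$x1, width)
  img <- clip01(img)
  if (blur_sigma > 0) {
    img <- gaussian_blur(img, blur_sigma / 1000 * pixels_per_mm,
                         mode = "replicate")
  }
  res <- element_resolution(grid$group, grid$element)
  element_table <- cbind(grid, lp_per_mm = res$lp_per_mm,
                         line_width_um = res$line_width_um,
                         line_width_px = lw_px)
  attr(specs, "pixels_per_mm") <- pixels_per_mm
  list(raster = img, specs = specs, element_table = element_table)
}
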