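# Raw-data preprocessing: non-local means denoising and the color machinery
# (sRGB -> CIELab, Euclidean color distances, patch extraction).

#' Non-local means parameters
#'
#' @param degree_of_smoothing filter bandwidth `h` in intensity units; larger
#'   values smooth more.
#' @param search_window odd side length of the window searched for similar
#'   patches (default 21).
#' @param comparison_window odd side length of the patches compared
#'   (default 5); must not exceed `search_window`.
#' @return object of class `nlm_params`.
#' @export
nlm_params <- function(degree_of_smoothing = 0.05, search_window = 21L,
                       comparison_window = 5L) {
  search_window <- as.integer(search_window)
  comparison_window <- as.integer(comparison_window)
  if (search_window %% 2L == 0L || comparison_window %% 2L == 0L) {
    stop_hs("preprocess", "parameter error: window sizes must be odd")
  }
  if (search_window < 3L || comparison_window < 3L) {
    stop_hs("preprocess", "parameter error: window sizes must be >= 3")
  }
  if (comparison_window > search_window) {
    stop_hs("preprocess", "comparison_window must not exceed search_window")
  }
  if (degree_of_smoothing <= 0) {
    stop_hs("preprocess", "degree_of_smoothing must be positive")
  }
  structure(list(degree_of_smoothing = degree_of_smoothing,
                 search_window = search_window,
                 comparison_window = comparison_window),
            class = "nlm_params")
}

# Robust noise-level estimate: 1.4826 * median(|x - 3x3 box mean|), the MAD
# of a high-pass residual (symmetric borders).
estimate_noise_sigma <- function(m) {
  r <- m - box_mean(m, 3L)
  1.4826 * stats::median(abs(r))
}

#' Non-local means denoising
#'
#' Each output pixel is a convex combination of the pixels in its search
#' window, weighted by patch similarity: for candidate pixel `q` with mean
#' squared patch difference `d2` to the center patch, the weight is
#' `exp(-max(d2 - 2 * sigma_est^2, 0) / h^2)` where `h` is
#' `degree_of_smoothing` and `sigma_est` is a per-channel noise estimate
#' (median absolute deviation of a high-pass residual). Borders are handled
#' by symmetric padding; channels are processed independently.
#'
#' @param raster raster in `[0, 1]`.
#' @param params an [nlm_params()].
#' @return denoised raster of the same shape.
#' @export
nlm_denoise <- function(raster, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  rng <- range(raster)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    stop_hs("preprocess", "raster intensities must lie in [0, 1]")
  }
  apply_planes(raster, function(m) nlm_plane(m, params))
}

nlm_plane <- function(m, params) {
  h2 <- params$degree_of_smoothing^2
  sr <- (params$search_window - 1L) %/% 2L
  cr <- (params$comparison_window - 1L) %/% 2L
  sig2 <- estimate_noise_sigma(m)^2
  H <- nrow(m); W <- ncol(m)
  p <- pad_matrix(m, sr + cr, sr + cr, "symmetric")
  # region of p holding the original image plus a comparison-window halo
  halo_rows <- (sr + 1L):(sr + H + 2L * cr)
  halo_cols <- (sr + 1L):(sr + W + 2L * cr)
  A <- p[halo_rows, halo_cols, drop = FALSE]
  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  core_rows <- (cr + 1L):(cr + H)
  core_cols <- (cr + 1L):(cr + W)
  for (dy in -sr:sr) {
    for (dx in -sr:sr) {
      B <- p[halo_rows + dy, halo_cols + dx, drop = FALSE]
      D <- (A - B)^2
      # mean squared patch difference over the comparison window (exact sums)
      d2 <- box_sum_valid(D, cr)
      w <- exp(-pmax(d2 / (params$comparison_window^2) - 2 * sig2, 0) / h2)
      v <- B[core_rows, core_cols, drop = FALSE]
      num <- num + w * v
      den <- den + w
    }
  }
  num / den
}

# Sum of D over (2r+1)^2 windows, evaluated only where the full window lies
# inside D ("valid" region); D is sized (H + 2r) x (W + 2r).
box_sum_valid <- function(D, r) {
  win <- 2L * r + 1L
  H <- nrow(D) - 2L * r; W <- ncol(D) - 2L * r
  out <- matrix(0, H, W)
  for (i in seq_len(win)) {
    for (j in seq_len(win)) {
      out <- out + D[i:(i + H - 1L), j:(j + W - 1L), drop = FALSE]
    }
  }
  out
}

#' Euclidean color distance
#'
#' The Euclidean distance between two colors in the stated space: RGB
#' coordinates on the 0–255 scale, or CIELab coordinates `(L, a, b)`.
#'
#' @param c1,c2 length-3 numeric colors, or `n x 3` matrices (row-wise
#'   distances).
#' @param space `"rgb"` or `"lab"`; both colors must share it.
#' @return nonnegative distance(s).
#' @examples
#' color_distance(c(0, 0, 0), c(255, 255, 255), "rgb")  # 441.673
#' color_distance(c(50, 0, 0), c(50, 3, 4), "lab")      # 5
#' @export
color_distance <- function(c1, c2, space = c("rgb", "lab")) {
  space <- match.arg(space)
  m1 <- if (is.matrix(c1)) c1 else matrix(c1, nrow = 1L)
  m2 <- if (is.matrix(c2)) c2 else matrix(c2, nrow = 1L)
  if (ncol(m1) != 3L || ncol(m2) != 3L || nrow(m1) != nrow(m2)) {
    stop_hs("preprocess", "usage error: colors must be 3-component, same count")
  }
  d <- sqrt(rowSums((m1 - m2)^2))
  if (!is.matrix(c1)) d <- d[[1L]]
  d
}

# sRGB D65 -> XYZ matrix and CIELab constants.
.srgb_to_xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                         0.2126729, 0.7151522, 0.0721750,
                         0.0193339, 0.1191920, 0.9503041),
                       3L, 3L, byrow = TRUE)
.d65_white <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Convert sRGB colors to CIELab
#'
#' Standard path: sRGB companding removed, linear RGB to CIE XYZ (D65, 2
#' degree observer), XYZ to CIELab against the D65 white point. `L` lies in
#' `[0, 100]`.
#'
#' @param x colors as a length-3 vector, `n x 3` matrix, or `H x W x 3`
#'   raster. Values in `[0, 1]`, or 0–255 (detected when any value
#'   exceeds 1 and normalized internally).
#' @return Lab values with the same layout as the input.
#' @examples
#' srgb_to_lab(c(1, 1, 1))  # L = 100, a = b = 0
#' @export
srgb_to_lab <- function(x) {
  shape <- dim(x)
  if (is.null(shape)) {
    m <- matrix(x, nrow = 1L)
  } else if (length(shape) == 3L) {
    m <- cbind(as.numeric(x[, , 1L]), as.numeric(x[, , 2L]), as.numeric(x[, , 3L]))
  } else {
    m <- as.matrix(x)
  }
  if (max(m) > 1 + 1e-9) m <- m / 255
  m <- clip01(m)
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz)
  xyz <- sweep(xyz, 2L, .d65_white, `/`)
  eps <- (6 / 29)^3
  fx <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * fx[, 2L] - 16
  a <- 500 * (fx[, 1L] - fx[, 2L])
  b <- 200 * (fx[, 2L] - fx[, 3L])
  out <- cbind(L = L, a = a, b = b)
  if (is.null(shape)) return(out[1L, ])
  if (length(shape) == 3L) return(array(out, c(shape[1:2], 3L)))
  rownames(out) <- rownames(x)
  out
}

#' Mean patch colors from a chart image
#'
#' Averages each patch over the central 50% of its rectangle (the margin
#' avoids edge bleed between tiles).
#'
#' @param raster chart raster (`H x W x 3`, `[0, 1]`).
#' @param geometry data.frame `(patch, row0, row1, col0, col1)` of 1-based
#'   inclusive patch rectangles, as produced by [make_color_chart()].
#' @return `n x 3` matrix of measured RGB values on the 0–255 scale.
#' @export
extract_patch_colors <- function(raster, geometry) {
  stopifnot(is_raster(raster), n_channels(raster) == 3L)
  need <- c("row0", "row1", "col0", "col1")
  if (!all(need %in% names(geometry))) {
    stop_hs("preprocess", "geometry error: need columns ", paste(need, collapse = ", "))
  }
  H <- raster_dim(raster)[1L]; W <- raster_dim(raster)[2L]
  out <- matrix(NA_real_, nrow(geometry), 3L)
  colnames(out) <- c("R", "G", "B")
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    if (g$row0 > g$row1 || g$col0 > g$col1 ||
        g$row0 < 1L || g$col0 < 1L || g$row1 > H || g$col1 > W) {
      stop_hs("preprocess", "geometry error: invalid rectangle for patch ", i)
    }
    # central 50% (half the side length, centered)
    rh <- g$row1 - g$row0 + 1L; cw <- g$col1 - g$col0 + 1L
    r0 <- g$row0 + floor(rh / 4); r1 <- g$row1 - floor(rh / 4)
    c0 <- g$col0 + floor(cw / 4); c1 <- g$col1 - floor(cw / 4)
    for (ch in 1:3) out[i, ch] <- mean(raster[r0:r1, c0:c1, ch]) * 255
  }
  out
}

#' A measured-versus-reference color patch set
#'
#' Pairs each chart patch's reference sRGB (0–255) and CIELab coordinates
#' with the RGB values measured from an acquired chart image; the input to
#' calibration fitting. Reference Lab values default to the module's own
#' sRGB-to-Lab conversion of the reference RGB and must agree with it within
#' a Lab distance of 1.
#'
#' @param measured_rgb `n x 3` measured RGB (0–255).
#' @param reference_rgb `n x 3` reference RGB (0–255); default
#'   [colorchecker_srgb()].
#' @param reference_lab optional `n x 3` reference Lab.
#' @return object of class `color_patch_set` (a list with the three
#'   matrices and `n`).
#' @export
color_patch_set <- function(measured_rgb,
                            reference_rgb = colorchecker_srgb(),
                            reference_lab = NULL) {
  measured_rgb <- as.matrix(measured_rgb)
  reference_rgb <- as.matrix(reference_rgb)
  if (nrow(measured_rgb) != nrow(reference_rgb)) {
    stop_hs("preprocess", "measured and reference patch counts differ")
  }
  own_lab <- srgb_to_lab(reference_rgb)
  if (is.null(reference_lab)) {
    reference_lab <- own_lab
  } else {
    reference_lab <- as.matrix(reference_lab)
    if (any(color_distance(reference_lab, own_lab, "lab") > 1)) {
      stop_hs("preprocess",
              "reference_lab inconsistent with reference_rgb (Lab distance > 1)")
    }
  }
  structure(list(measured_rgb = measured_rgb, reference_rgb = reference_rgb,
                 reference_lab = reference_lab, n = nrow(measured_rgb)),
            class = "color_patch_set")
}
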