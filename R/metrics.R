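# Multifocus fusion-quality metrics. Four families: normalized mutual
# information (information theory), spatial-frequency error (image feature),
# Yang's SSIM (structural similarity) and a Chen-Varshney-style perceptual
# index. All operate on luminance and are deterministic for fixed
# parameters. Orientation: nmi and yang are higher-better (1 = perfect);
# sf_error is 0 at perfect fusion and goes negative with detail loss;
# cv is an error, lower-better with 0 at perfect fusion.

metric_params_default <- function() {
  list(bins = 256L, ssim_window = 7L, K1 = 0.01, K2 = 0.03,
       complementarity_threshold = 0.75, region_size = 16L, csf_sigma = 2)
}

as_lum_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(stack$frames, luminance)
}

as_lum_fused <- function(fused) {
  if (inherits(fused, "fused_image")) fused <- fused$raster
  luminance(fused)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mi_pair <- function(a, b, bins) {
  ia <- pmin(pmax(floor(a * bins), 0), bins - 1L)
  ib <- pmin(pmax(floor(b * bins), 0), bins - 1L)
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  pj <- joint / sum(joint)
  pj_m <- matrix(pj, bins, bins, byrow = TRUE)   # rows = a bins, cols = b bins
  pa <- rowSums(pj_m); pb <- colSums(pj_m)
  ha <- entropy_nats(pa); hb <- entropy_nats(pb)
  hj <- entropy_nats(pj)
  mi <- ha + hb - hj
  list(mi = mi, ha = ha, hb = hb)
}

#' Normalized mutual information between a fused image and its stack
#'
#' Images are quantized to `bins` gray levels; for each frame the mutual
#' information with the fused image is normalized by half the sum of the two
#' marginal entropies, and the scores are averaged over the stack. Values
#' lie in `[0, 1]`; 1 means the fused image carries exactly the frame's
#' information.
#'
#' @param fused fused raster (or [fuse_stack()] result).
#' @param stack the input [image_stack()].
#' @param bins histogram bin count (default 256).
#' @return scalar score in `[0, 1]`.
#' @export
nmi_metric <- function(fused, stack, bins = 256L) {
  f <- as_lum_fused(fused)
  frames <- as_lum_stack(stack)
  scores <- vapply(frames, function(fr) {
    if (!identical(dim(fr), dim(f))) stop_hs("metrics", "shape mismatch")
    r <- mi_pair(as.numeric(f), as.numeric(fr), as.integer(bins))
    if (r$ha == 0 || r$hb == 0) {
      warning("constant image in NMI: zero entropy")
      return(if (r$ha == 0 && r$hb == 0 && all(f == fr)) 1 else 0)
    }
    r$mi / (0.5 * (r$ha + r$hb))
  }, numeric(1))
  mean(scores)
}

directional_diffs <- function(m) {
  h <- nrow(m); w <- ncol(m)
  list(
    horiz = m[, 2:w, drop = FALSE] - m[, 1:(w - 1L), drop = FALSE],
    vert  = m[2:h, , drop = FALSE] - m[1:(h - 1L), , drop = FALSE],
    diag1 = m[2:h, 2:w, drop = FALSE] - m[1:(h - 1L), 1:(w - 1L), drop = FALSE],
    diag2 = m[2:h, 1:(w - 1L), drop = FALSE] - m[1:(h - 1L), 2:w, drop = FALSE])
}

sf_from_diffs <- function(d) {
  wd <- 1 / sqrt(2)   # diagonal weight
  sqrt(mean(d$horiz^2) + mean(d$vert^2) +
       wd * mean(d$diag1^2) + wd * mean(d$diag2^2))
}

#' Spatial-frequency error of a fused image
#'
#' The spatial frequency of the fused image (root-mean first differences in
#' four directions: horizontal, vertical and the two diagonals, the diagonal
#' terms weighted by `1/sqrt(2)`) is compared against a reference spatial
#' frequency built from the per-pixel maximum absolute directional
#' differences over the stack — the gradient content an ideal all-in-focus
#' image could attain. The score is
#' `(SF_fused - SF_reference) / SF_reference`: 0 is ideal, negative values
#' indicate loss of detail.
#'
#' @param fused fused raster (or [fuse_stack()] result).
#' @param stack the input [image_stack()].
#' @return scalar score (typically `<= 0` for real fusions).
#' @export
spatial_frequency_error <- function(fused, stack) {
  f <- as_lum_fused(fused)
  frames <- as_lum_stack(stack)
  df <- directional_diffs(f)
  sf_f <- sf_from_diffs(df)
  ref <- NULL
  for (fr in frames) {
    if (!identical(dim(fr), dim(f))) stop_hs("metrics", "shape mismatch")
    d <- directional_diffs(fr)
    if (is.null(ref)) {
      ref <- lapply(d, abs)
    } else {
      ref <- Map(function(a, b) pmax(a, abs(b)), ref, d)
    }
  }
  sf_ref <- sf_from_diffs(ref)
  if (sf_ref == 0) stop_hs("metrics", "undefined score: constant stack has zero spatial frequency")
  (sf_f - sf_ref) / sf_ref
}

# Per-pixel local SSIM map between two luminance planes.
ssim_map <- function(a, b, window, C1, C2) {
  mu_a <- box_mean(a, window); mu_b <- box_mean(b, window)
  va <- pmax(box_mean(a^2, window) - mu_a^2, 0)
  vb <- pmax(box_mean(b^2, window) - mu_b^2, 0)
  cab <- box_mean(a * b, window) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Yang's SSIM-based fusion quality score
#'
#' Local structural similarity between the fused image and the stack,
#' adapted to fusion: at each pixel the two frames with the highest local
#' variance (the most informative ones) are selected; where they are
#' complementary (their mutual local SSIM falls below
#' `complementarity_threshold`) the better of the two fused-to-frame SSIMs
#' is taken, otherwise their local-variance-weighted average. The final
#' score is the mean over all pixels; 1 is perfect.
#'
#' @param fused fused raster (or [fuse_stack()] result).
#' @param stack the input [image_stack()].
#' @param window odd local window (default 7).
#' @param K1,K2 SSIM stability constants (default 0.01, 0.03).
#' @param complementarity_threshold SSIM level below which the two frames
#'   are treated as complementary (default 0.75).
#' @return scalar score in `[-1, 1]`.
#' @export
yang_ssim <- function(fused, stack, window = 7L, K1 = 0.01, K2 = 0.03,
                      complementarity_threshold = 0.75) {
  f <- as_lum_fused(fused)
  frames <- as_lum_stack(stack)
  k <- length(frames)
  C1 <- K1^2; C2 <- K2^2
  if (k == 1L) {
    return(mean(ssim_map(f, frames[[1L]], window, C1, C2)))
  }
  n <- length(f)
  vars <- vapply(frames, function(fr) {
    mu <- box_mean(fr, window)
    as.numeric(pmax(box_mean(fr^2, window) - mu^2, 0))
  }, numeric(n))
  # two most informative frames per pixel
  a_idx <- max.col(vars, ties.method = "first")
  vars2 <- vars
  vars2[cbind(seq_len(n), a_idx)] <- -Inf
  b_idx <- max.col(vars2, ties.method = "first")
  sf <- vapply(frames, function(fr) as.numeric(ssim_map(f, fr, window, C1, C2)),
               numeric(n))
  # pairwise frame-to-frame SSIM, evaluated lazily per occurring pair
  pair_key <- paste(pmin(a_idx, b_idx), pmax(a_idx, b_idx))
  s_ab <- numeric(n)
  for (key in unique(pair_key)) {
    ij <- as.integer(strsplit(key, " ")[[1L]])
    sel <- pair_key == key
    smap <- as.numeric(ssim_map(frames[[ij[1L]]], frames[[ij[2L]]], window, C1, C2))
    s_ab[sel] <- smap[sel]
  }
  sa <- sf[cbind(seq_len(n), a_idx)]
  sb <- sf[cbind(seq_len(n), b_idx)]
  va <- vars[cbind(seq_len(n), a_idx)]
  vb <- vars[cbind(seq_len(n), b_idx)]
  comp <- s_ab < complementarity_threshold
  wsum <- va + vb
  weighted <- ifelse(wsum > 0, (va * sa + vb * sb) / wsum, (sa + sb) / 2)
  mean(ifelse(comp, pmax(sa, sb), weighted))
}

sobel_energy <- function(m) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  sy <- t(sx)
  gx <- conv2_kernel(m, sx, mode = "symmetric")
  gy <- conv2_kernel(m, sy, mode = "symmetric")
  gx^2 + gy^2
}

#' Chen-Varshney-style perceptual fusion error
#'
#' The image is tiled into `region_size` x `region_size` regions. Per
#' region, each frame's saliency is the sum of its squared Sobel edge
#' response; the squared difference between the fused image and the frame,
#' low-pass filtered by a Gaussian contrast-sensitivity surrogate
#' (`csf_sigma` px), is averaged over the region and the frames' errors are
#' combined with saliency weights. The global score is the saliency-weighted
#' mean over regions. 0 is perfect; larger is worse.
#'
#' @param fused fused raster (or [fuse_stack()] result).
#' @param stack the input [image_stack()].
#' @param region_size square region side (default 16).
#' @param csf_sigma Gaussian CSF surrogate sigma in pixels (default 2).
#' @return nonnegative scalar.
#' @export
chen_varshney <- function(fused, stack, region_size = 16L, csf_sigma = 2) {
  f <- as_lum_fused(fused)
  frames <- as_lum_stack(stack)
  h <- nrow(f); w <- ncol(f)
  region_size <- as.integer(region_size)
  ry <- ceiling(h / region_size); rx <- ceiling(w / region_size)
  sal <- lapply(frames, sobel_energy)
  derr <- lapply(frames, function(fr) gaussian_blur(f - fr, csf_sigma)^2)
  region_idx <- function(i, n) ((i - 1L) * region_size + 1L):min(i * region_size, n)
  num <- 0; den <- 0
  for (iy in seq_len(ry)) {
    rows <- region_idx(iy, h)
    for (ix in seq_len(rx)) {
      cols <- region_idx(ix, w)
      lam <- vapply(sal, function(s) sum(s[rows, cols]), numeric(1))
      tot <- sum(lam)
      wts <- if (tot > 0) lam / tot else rep(1 / length(lam), length(lam))
      errs <- vapply(derr, function(d) mean(d[rows, cols]), numeric(1))
      e_r <- sum(wts * errs)
      num <- num + tot * e_r
      den <- den + tot
    }
  }
  if (den == 0) stop_hs("metrics", "undefined score: blank stack has zero saliency")
  num / den
}

#' Full fusion-quality report
#'
#' Runs all four metrics with their default parameters. Per-metric
#' undefined cases (constant stack, blank stack) are recorded as `NA`
#' rather than failing the report.
#'
#' @param fused fused raster (or [fuse_stack()] result).
#' @param stack the input [image_stack()].
#' @param params parameter list, see `metric_params_default()` entries
#'   `bins`, `ssim_window`, `K1`, `K2`, `complementarity_threshold`,
#'   `region_size`, `csf_sigma`.
#' @return object of class `fusion_quality_report`: the four scores, their
#'   orientations and a parameter digest.
#' @export
assess <- function(fused, stack, params = metric_params_default()) {
  p <- utils::modifyList(metric_params_default(), params)
  safe <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e))
    NA_real_
  })
  rep <- list(
    nmi_score = safe(nmi_metric(fused, stack, bins = p$bins)),
    spatial_frequency_error = safe(spatial_frequency_error(fused, stack)),
    yang_ssim_score = safe(yang_ssim(fused, stack, window = p$ssim_window,
                                     K1 = p$K1, K2 = p$K2,
                                     complementarity_threshold =
                                       p$complementarity_threshold)),
    chen_varshney_score = safe(chen_varshney(fused, stack,
                                             region_size = p$region_size,
                                             csf_sigma = p$csf_sigma)),
    orientation = c(nmi_score = "higher", spatial_frequency_error = "zero",
                    yang_ssim_score = "higher", chen_varshney_score = "lower"),
    params = p)
  structure(rep, class = "fusion_quality_report")
}

#' @export
print.fusion_quality_report <- function(x, ...) {
  cat("<fusion_quality_report>\n")
  cat(sprintf("  nmi                 %.6f  (1 = perfect)\n", x$nmi_score))
  cat(sprintf("  sf_error            %+.6f  (0 = ideal, <0 = detail loss)\n",
              x$spatial_frequency_error))
  cat(sprintf("  yang_ssim           %.6f  (1 = perfect)\n", x$yang_ssim_score))
  cat(sprintf("  chen_varshney       %.6g  (0 = perfect)\n", x$chen_varshney_score))
  invisible(x)
}

#' Serialize a fusion-quality report to a data frame / CSV
#'
#' @param x a [assess()] report.
#' @param path optional CSV output path.
#' @param ... unused.
#' @return data.frame `(metric, score, orientation, params_digest)`.
#' @export
as.data.frame.fusion_quality_report <- function(x, path = NULL, ...) {
  digest <- paste(names(unlist(x$params)), unlist(x$params),
                  sep = "=", collapse = ";")
  df <- data.frame(
    metric = c("nmi", "sf_error", "yang_ssim", "chen_varshney"),
    score = c(x$nmi_score, x$spatial_frequency_error, x$yang_ssim_score,
              x$chen_varshney_score),
    orientation = unname(x$orientation),
    params_digest = digest)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
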