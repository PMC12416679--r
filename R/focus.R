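# Focus measurement and multifocus fusion: Laplacian-variance focus maps,
# stack alignment to the most magnified frame, and the weighted fusion of
# the aligned frames into the all-in-focus ("hyperfocus") image.

laplacian_kernel_default <- function() {
  matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L, byrow = TRUE)
}

#' Laplacian-variance focus map
#'
#' Per-pixel focus measure: the raster is collapsed to luminance, filtered
#' with a Laplacian kernel to highlight rapid intensity changes, and the
#' local variance of the response (mean of squares minus squared mean) is
#' computed over an odd window. Sharp regions score high; constant regions
#' score exactly zero. Borders use symmetric padding.
#'
#' @param raster raster in `[0, 1]`.
#' @param laplacian_kernel odd-sized kernel matrix; default the 3x3
#'   4-neighbor Laplacian `[[0,1,0],[1,-4,1],[0,1,0]]`.
#' @param variance_window odd local-variance window (default 9).
#' @return object of class `focus_map`: `values` (`H x W`, nonnegative) and
#'   `window`.
#' @export
focus_map <- function(raster, laplacian_kernel = laplacian_kernel_default(),
                      variance_window = 9L) {
  variance_window <- as.integer(variance_window)
  if (variance_window %% 2L == 0L || variance_window < 1L) {
    stop_hs("focus", "parameter error: variance_window must be odd and >= 1")
  }
  lum <- luminance(raster)
  resp <- conv2_kernel(lum, laplacian_kernel, mode = "symmetric")
  m1 <- box_mean(resp, variance_window, mode = "symmetric")
  m2 <- box_mean(resp^2, variance_window, mode = "symmetric")
  v <- pmax(m2 - m1^2, 0)
  structure(list(values = v, window = variance_window), class = "focus_map")
}

#' @export
print.focus_map <- function(x, ...) {
  cat(sprintf("<focus_map> %d x %d, window %d, mean %.3g\n",
              nrow(x$values), ncol(x$values), x$window, mean(x$values)))
  invisible(x)
}

focus_values <- function(fm) if (inherits(fm, "focus_map")) fm$values else fm

#' Fuse an aligned stack by focus-measure weighting
#'
#' Per pixel `(u, v)` and channel, the fused value is the weighted sum of
#' the input frames, each frame weighted by its share of the total focus
#' measure at that pixel: `w_i = fm_i / sum_j fm_j`. The same
#' luminance-derived weights apply to all three channels, so the result is
#' a per-pixel convex combination of the frames. Where the total focus
#' measure is zero, uniform weights `1/k` are used.
#'
#' @param aligned an [image_stack()] of mutually aligned frames.
#' @param maps list of [focus_map()]s (or matrices), one per frame.
#' @param exclude optional integer indices of frames to leave out (e.g.
#'   frames whose alignment failed).
#' @param weight_exponent optional sharpening exponent on the focus values
#'   (default 1: the literal weighted sum).
#' @return object of class `fused_image`: `raster` (same shape as the
#'   frames), `weights` (list of weight matrices) and `provenance`.
#' @export
fuse_stack <- function(aligned, maps, exclude = integer(0), weight_exponent = 1) {
  stopifnot(inherits(aligned, "image_stack"))
  if (length(maps) != length(aligned$frames)) {
    stop_hs("fuse", "pipeline error: ", length(maps), " focus maps for ",
            length(aligned$frames), " frames")
  }
  keep <- setdiff(seq_along(aligned$frames), exclude)
  if (length(keep) == 0L) stop_hs("fuse", "no frames left to fuse")
  d <- dim(aligned$frames[[1L]])
  vals <- lapply(maps[keep], focus_values)
  for (v in vals) {
    if (!identical(dim(v), d[1:2])) {
      stop_hs("fuse", "pipeline error: focus map shape differs from frames")
    }
  }
  if (weight_exponent != 1) vals <- lapply(vals, function(v) v^weight_exponent)
  total <- Reduce(`+`, vals)
  k <- length(keep)
  zero <- total == 0
  weights <- lapply(vals, function(v) {
    w <- v / total
    w[zero] <- 1 / k
    w
  })
  fused <- array(0, d)
  for (i in seq_along(keep)) {
    f <- aligned$frames[[keep[i]]]
    if (is.matrix(fused)) {
      fused <- fused + weights[[i]] * f
    } else {
      for (c in seq_len(d[3L])) {
        fused[, , c] <- fused[, , c] + weights[[i]] * f[, , c]
      }
    }
  }
  structure(list(raster = fused, weights = weights, frames_used = keep,
                 provenance = list(k = k, weight_exponent = weight_exponent)),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<fused_image> %d x %d x %d from %d frame(s)\n",
              d[1L], d[2L], if (length(d) == 3L) d[3L] else 1L,
              length(x$frames_used)))
  invisible(x)
}

#' Align a focus stack to its most magnified frame
#'
#' The frame with the smallest focal-plane distance (the most magnified one
#' at fixed image distance) is the reference; when focal-plane metadata is
#' absent, the frame with the largest mean gradient magnitude is used.
#' Every other frame is ECC-registered to the reference and warped into its
#' geometry. Frames are solved outward from the reference, each solve
#' initialized from the nearest already-solved neighbor, which tracks the
#' slowly varying magnification across the sweep. Frames that fail to
#' converge are flagged and, by convention, excluded from fusion.
#'
#' @param stack an [image_stack()].
#' @param model ECC warp model (default `"affine"`).
#' @param max_iterations,epsilon passed to [ecc_register()].
#' @return list: `aligned` ([image_stack()]), `transforms` (list of
#'   [ecc_register()] results; identity for the reference),
#'   `reference` (index), `failed` (indices of non-converged frames).
#' @export
align_stack <- function(stack, model = "affine", max_iterations = 100L,
                        epsilon = 1e-6) {
  stopifnot(inherits(stack, "image_stack"))
  k <- length(stack$frames)
  fp <- focal_planes(stack)
  ref_idx <- if (any(!is.na(fp))) {
    which.min(fp)
  } else {
    grads <- vapply(stack$frames, function(f) {
      g <- central_gradient(luminance(f))
      mean(sqrt(g$gx^2 + g$gy^2))
    }, numeric(1))
    which.max(grads)
  }
  transforms <- vector("list", k)
  aligned <- stack$frames
  id <- structure(list(matrix = identity_transform(), ecc_value = 1,
                       converged = TRUE, iterations = 0L, model = model),
                  class = "ecc_transform")
  transforms[[ref_idx]] <- id
  if (k > 1L) {
    order_out <- order(abs(seq_len(k) - ref_idx))[-1L]
    ref_frame <- stack$frames[[ref_idx]]
    for (j in order_out) {
      neighbor <- if (j > ref_idx) j - 1L else j + 1L
      init <- if (!is.null(transforms[[neighbor]])) {
        transforms[[neighbor]]$matrix
      } else NULL
      tr <- ecc_register(ref_frame, stack$frames[[j]], model = model,
                         max_iterations = max_iterations, epsilon = epsilon,
                         init = init)
      transforms[[j]] <- tr
      aligned[[j]] <- clip01(apply_transform(stack$frames[[j]], tr))
    }
  }
  failed <- which(!vapply(transforms, function(t) t$converged, logical(1)))
  if (length(failed) > 0L) {
    warning(sprintf("alignment did not converge for frame(s) %s; excluded from fusion",
                    paste(failed, collapse = ", ")))
  }
  list(aligned = image_stack(aligned, stack$metas), transforms = transforms,
       reference = ref_idx, failed = failed)
}

#' Run the full processing pipeline on a stack
#'
#' Fixed stage order: denoise, color-calibrate, align, focus-measure, fuse.
#' Each stage is individually switchable; with a stage disabled the stack
#' passes through unchanged.
#'
#' @param stack an [image_stack()].
#' @param config a [pipeline_config()] (or a plain list with the same
#'   fields).
#' @param keep_intermediates retain the aligned stack and focus maps in the
#'   result (default `TRUE`).
#' @return list: `fused` ([fuse_stack()] result), and when requested
#'   `aligned`, `transforms`, `focus_maps`, `excluded`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(),
                         keep_intermediates = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  cfg <- as_pipeline_config(config)
  frames <- stack$frames
  if (isTRUE(cfg$denoise$enabled)) {
    params <- nlm_params(cfg$denoise$degree_of_smoothing,
                         cfg$denoise$search_window,
                         cfg$denoise$comparison_window)
    frames <- lapply(frames, nlm_denoise, params = params)
  }
  if (isTRUE(cfg$calibrate$enabled)) {
    model <- cfg$calibrate$model
    if (is.character(model)) model <- load_calibration(model)
    if (!inherits(model, "calibration_model")) {
      stop_hs("calibrate", "config error: no calibration model supplied")
    }
    frames <- lapply(frames, apply_calibration, model = model)
  }
  work <- image_stack(frames, stack$metas)
  excluded <- integer(0)
  transforms <- NULL
  if (isTRUE(cfg$align$enabled) && length(work$frames) > 1L) {
    al <- align_stack(work, model = cfg$align$model,
                      max_iterations = cfg$align$max_iterations,
                      epsilon = cfg$align$epsilon)
    work <- al$aligned
    transforms <- al$transforms
    excluded <- al$failed
  }
  maps <- lapply(work$frames, focus_map,
                 variance_window = cfg$fuse$variance_window)
  fused <- fuse_stack(work, maps, exclude = excluded,
                      weight_exponent = cfg$fuse$weight_exponent)
  out <- list(fused = fused)
  if (keep_intermediates) {
    out$aligned <- work
    out$transforms <- transforms
    out$focus_maps <- maps
    out$excluded <- excluded
  }
  out
}

#' Render a focus map as a false-color heatmap PNG
#'
#' Writes the normalized focus values through a perceptually ordered
#' dark-blue-to-yellow colormap, the usual visualization of per-frame focus
#' weight masks.
#'
#' @param fm a [focus_map()] (or matrix).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_focus_heatmap <- function(fm, path) {
  v <- focus_values(fm)
  rng <- range(v)
  u <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
  # compact viridis-like ramp
  anchors <- matrix(c(0.267, 0.005, 0.329,
                      0.283, 0.141, 0.458,
                      0.254, 0.265, 0.530,
                      0.207, 0.372, 0.553,
                      0.164, 0.471, 0.558,
                      0.128, 0.567, 0.551,
                      0.135, 0.659, 0.518,
                      0.267, 0.749, 0.441,
                      0.478, 0.821, 0.318,
                      0.741, 0.873, 0.150,
                      0.993, 0.906, 0.144), ncol = 3L, byrow = TRUE)
  pos <- seq(0, 1, length.out = nrow(anchors))
  out <- array(0, c(dim(u), 3L))
  for (c in 1:3) {
    out[, , c] <- matrix(stats::approx(pos, anchors[, c], xout = as.numeric(u))$y,
                         nrow(u), ncol(u))
  }
  save_image(out, path, bit_depth = 8L)
}
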