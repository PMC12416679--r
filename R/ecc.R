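# Enhanced-correlation-coefficient (ECC) image registration: iterative
# maximization of the zero-mean normalized correlation between a reference
# image and a warped input image over a translation / euclidean / affine
# warp, with a coarse-to-fine pyramid.

warp_n_params <- function(model) {
  switch(model, translation = 2L, euclidean = 3L, affine = 6L,
         stop_hs("align", "unknown warp model: ", model))
}

params_to_matrix <- function(p, model) {
  switch(model,
    translation = matrix(c(1, 0, p[1L], 0, 1, p[2L]), 2L, 3L, byrow = TRUE),
    euclidean = {
      th <- p[1L]
      matrix(c(cos(th), -sin(th), p[2L], sin(th), cos(th), p[3L]),
             2L, 3L, byrow = TRUE)
    },
    affine = matrix(c(1 + p[1L], p[3L], p[5L], p[2L], 1 + p[4L], p[6L]),
                    2L, 3L, byrow = TRUE))
}

matrix_to_params <- function(A, model) {
  switch(model,
    translation = c(A[1L, 3L], A[2L, 3L]),
    euclidean = c(atan2(A[2L, 1L], A[1L, 1L]), A[1L, 3L], A[2L, 3L]),
    affine = c(A[1L, 1L] - 1, A[2L, 1L], A[1L, 2L], A[2L, 2L] - 1,
               A[1L, 3L], A[2L, 3L]))
}

identity_transform <- function() matrix(c(1, 0, 0, 0, 1, 0), 2L, 3L, byrow = TRUE)

# Halve an image by 2x2 block averaging (odd trailing row/col dropped).
downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  (m[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE] +
   m[seq(2L, h, 2L), seq(1L, w, 2L), drop = FALSE] +
   m[seq(1L, h, 2L), seq(2L, w, 2L), drop = FALSE] +
   m[seq(2L, h, 2L), seq(2L, w, 2L), drop = FALSE]) / 4
}

central_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- (m[, 3:w] - m[, 1:(w - 2L)]) / 2
  gx[, 1L] <- m[, 2L] - m[, 1L]; gx[, w] <- m[, w] - m[, w - 1L]
  gy[2:(h - 1L), ] <- (m[3:h, ] - m[1:(h - 2L), ]) / 2
  gy[1L, ] <- m[2L, ] - m[1L, ]; gy[h, ] <- m[h, ] - m[h - 1L, ]
  list(gx = gx, gy = gy)
}

ecc_level <- function(ref, mov, model, p, max_iterations, epsilon) {
  h <- nrow(ref); w <- ncol(ref)
  grid <- expand.grid(y = seq_len(h), x = seq_len(w))
  gx <- grid$x; gy <- grid$y
  grad <- central_gradient(mov)
  ir_full <- as.numeric(ref)
  np <- warp_n_params(model)
  rho <- -Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    A <- params_to_matrix(p, model)
    xs <- A[1L, 1L] * gx + A[1L, 2L] * gy + A[1L, 3L]
    ys <- A[2L, 1L] * gx + A[2L, 2L] * gy + A[2L, 3L]
    iwv <- bilinear_sample(mov, xs, ys)
    mask <- attr(iwv, "inside")
    if (sum(mask) < 16L) break
    iw <- as.numeric(iwv)[mask]
    ir <- ir_full[mask]
    Ix <- as.numeric(bilinear_sample(grad$gx, xs, ys))[mask]
    Iy <- as.numeric(bilinear_sample(grad$gy, xs, ys))[mask]
    mx <- gx[mask]; my <- gy[mask]
    G <- switch(model,
      translation = cbind(Ix, Iy),
      euclidean = {
        th <- p[1L]
        dxdth <- -sin(th) * mx - cos(th) * my
        dydth <- cos(th) * mx - sin(th) * my
        cbind(Ix * dxdth + Iy * dydth, Ix, Iy)
      },
      affine = cbind(Ix * mx, Iy * mx, Ix * my, Iy * my, Ix, Iy))
    iw <- iw - mean(iw)
    ir <- ir - mean(ir)
    G <- sweep(G, 2L, colMeans(G))
    GG <- crossprod(G)
    GGi <- tryCatch(solve(GG), error = function(e) NULL)
    if (is.null(GGi)) break
    Gw <- crossprod(G, iw)
    Gr <- crossprod(G, ir)
    nw2 <- sum(iw^2); nr2 <- sum(ir^2)
    if (nw2 == 0 || nr2 == 0) break
    rho_new <- sum(ir * iw) / sqrt(nr2 * nw2)
    num <- nw2 - crossprod(Gw, GGi %*% Gw)[1L]
    den <- sum(ir * iw) - crossprod(Gr, GGi %*% Gw)[1L]
    if (den <= 0) break   # correlation cannot be improved along this model
    lambda <- num / den
    err <- lambda * ir - iw
    dp <- as.numeric(GGi %*% crossprod(G, err))
    p <- p + dp
    if (rho_new >= 1 - 1e-12 || max(abs(dp)) < epsilon) {
      rho <- max(rho, rho_new)
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  # final correlation at the returned parameters
  A <- params_to_matrix(p, model)
  xs <- A[1L, 1L] * gx + A[1L, 2L] * gy + A[1L, 3L]
  ys <- A[2L, 1L] * gx + A[2L, 2L] * gy + A[2L, 3L]
  iwv <- bilinear_sample(mov, xs, ys)
  mask <- attr(iwv, "inside")
  if (sum(mask) >= 16L) {
    iw <- as.numeric(iwv)[mask]; ir <- ir_full[mask]
    iw <- iw - mean(iw); ir <- ir - mean(ir)
    d <- sqrt(sum(iw^2) * sum(ir^2))
    if (d > 0) rho <- sum(ir * iw) / d
  }
  list(p = p, rho = rho, converged = converged, iterations = iterations)
}

#' ECC registration of one image onto a reference
#'
#' Iteratively maximizes the zero-mean normalized correlation coefficient
#' between the reference and the warped moving image (equivalently,
#' minimizes the ECC error norm) over the chosen warp model, coarse-to-fine
#' over an image pyramid. Color images are collapsed to luminance first.
#'
#' The returned transform maps reference pixel coordinates to moving-image
#' coordinates, i.e. sampling the moving image through it produces the
#' aligned frame.
#'
#' @param reference,moving rasters of identical shape.
#' @param model `"translation"`, `"euclidean"` or `"affine"`.
#' @param max_iterations per pyramid level (default 100).
#' @param epsilon parameter-update convergence threshold (default 1e-6).
#' @param pyramid_levels number of pyramid levels (default: enough to bring
#'   the coarsest level near 32 px).
#' @param init optional 2x3 initial transform.
#' @return object of class `ecc_transform`: `matrix` (2x3), `ecc_value`
#'   (final correlation), `converged`, `iterations`, `model`.
#' @export
ecc_register <- function(reference, moving,
                         model = c("affine", "euclidean", "translation"),
                         max_iterations = 100L, epsilon = 1e-6,
                         pyramid_levels = NULL, init = NULL) {
  model <- match.arg(model)
  if (!identical(raster_dim(reference), raster_dim(moving))) {
    stop_hs("align", "reference and moving images must share shape")
  }
  ref <- luminance(reference)
  mov <- luminance(moving)
  if (is.null(pyramid_levels)) {
    pyramid_levels <- max(1L, floor(log2(min(dim(ref)) / 32)) + 1L)
  }
  refs <- list(ref); movs <- list(mov)
  for (l in seq_len(pyramid_levels - 1L)) {
    if (min(dim(refs[[l]])) < 16L) { pyramid_levels <- l; break }
    refs[[l + 1L]] <- downsample2(refs[[l]])
    movs[[l + 1L]] <- downsample2(movs[[l]])
  }
  A <- if (is.null(init)) identity_transform() else init
  # at level l, translations scale by 1/2^(l-1); the linear part is unchanged
  lv <- pyramid_levels
  A_l <- A
  A_l[, 3L] <- A[, 3L] / 2^(lv - 1L)
  res <- NULL
  for (l in rev(seq_len(lv))) {
    p <- matrix_to_params(A_l, model)
    res <- ecc_level(refs[[l]], movs[[l]], model, p,
                     max_iterations, epsilon)
    A_l <- params_to_matrix(res$p, model)
    if (l > 1L) A_l[, 3L] <- A_l[, 3L] * 2
  }
  Afin <- A_l
  if (abs(det(Afin[, 1:2])) <= 1e-8) {
    warning("ECC produced a near-singular transform; flagging non-convergence")
    res$converged <- FALSE
  }
  structure(list(matrix = Afin, ecc_value = res$rho,
                 converged = res$converged, iterations = res$iterations,
                 model = model),
            class = "ecc_transform")
}

#' @export
print.ecc_transform <- function(x, ...) {
  cat(sprintf("<ecc_transform> model = %s, ecc = %.6f, converged = %s (%d it)\n",
              x$model, x$ecc_value, x$converged, x$iterations))
  print(round(x$matrix, 5))
  invisible(x)
}

#' Warp a frame by an ECC transform into reference geometry
#'
#' @param raster raster to warp.
#' @param transform an [ecc_register()] result or a 2x3 matrix.
#' @return warped raster, same shape.
#' @export
apply_transform <- function(raster, transform) {
  A <- if (inherits(transform, "ecc_transform")) transform$matrix else transform
  warp_affine_raster(raster, A)
}
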