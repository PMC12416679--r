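# Color calibration: fit a measured -> reference RGB transform on a chart
# patch set, apply it to images, and score methods by mean RGB / CIELab
# distance. Method families: affine ("linear"), full multivariate polynomial
# bases of total degree 2 and 3 ("poly2"/"poly3"), and k-means-clustered
# per-cluster affine maps ("kmeans2".."kmeans4").

calibration_methods <- c("linear", "poly2", "poly3",
                         "kmeans2", "kmeans3", "kmeans4")

# Full multivariate monomial basis of (R, G, B) up to total degree d,
# including the intercept and all cross terms; inputs scaled to [0, 1]
# for conditioning.
poly_basis <- function(rgb01, degree) {
  r <- rgb01[, 1L]; g <- rgb01[, 2L]; b <- rgb01[, 3L]
  cols <- list(`1` = rep(1, length(r)), R = r, G = g, B = b)
  if (degree >= 2L) {
    cols <- c(cols, list(R2 = r^2, G2 = g^2, B2 = b^2,
                         RG = r * g, RB = r * b, GB = g * b))
  }
  if (degree >= 3L) {
    cols <- c(cols, list(R3 = r^3, G3 = g^3, B3 = b^3,
                         R2G = r^2 * g, R2B = r^2 * b,
                         G2R = g^2 * r, G2B = g^2 * b,
                         B2R = b^2 * r, B2G = b^2 * g,
                         RGB = r * g * b))
  }
  do.call(cbind, cols)
}

method_degree <- function(method) {
  switch(method, linear = 1L, poly2 = 2L, poly3 = 3L, 1L)
}

least_squares_map <- function(X, Y) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop_hs("calibration", "degenerate patch set: rank-deficient design")
  }
  qr.coef(q, Y)
}

# k-means++ initialization: first center uniform, then proportional to
# squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

seeded_kmeans <- function(x, k, restarts = 50L, seed = 0L) {
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_centers(x, k)
      km <- suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

#' Fit a color-calibration model to a chart patch set
#'
#' Least-squares fit of a measured-to-reference RGB map on the chart
#' patches. `linear` fits an affine map; `poly2`/`poly3` fit the full
#' multivariate polynomial basis (all cross terms) of total degree 2/3;
#' `kmeans2`–`kmeans4` cluster the measured colors (seeded k-means++) and
#' fit one affine map per cluster, falling back to the global affine map for
#' clusters with fewer than 4 members. Fitting is done in RGB; CIELab is an
#' evaluation space only.
#'
#' @param patches a [color_patch_set()].
#' @param method one of `"linear"`, `"poly2"`, `"poly3"`, `"kmeans2"`,
#'   `"kmeans3"`, `"kmeans4"`.
#' @param seed seed for the k-means initialization.
#' @return object of class `calibration_model`: method, coefficient
#'   matrices, centroids (k-means only) and per-patch residual RGB
#'   distances.
#' @export
fit_calibration <- function(patches, method = "linear", seed = 0L) {
  stopifnot(inherits(patches, "color_patch_set"))
  method <- match.arg(method, calibration_methods)
  M01 <- patches$measured_rgb / 255
  R01 <- patches$reference_rgb / 255
  n <- nrow(M01)
  model <- list(method = method, centroids = NULL, coefficients = NULL,
                cluster_coefficients = NULL)
  if (method %in% c("linear", "poly2", "poly3")) {
    deg <- method_degree(method)
    X <- poly_basis(M01, deg)
    if (n < ncol(X)) {
      stop_hs("calibration", method, " needs >= ", ncol(X), " patches, got ", n)
    }
    model$coefficients <- least_squares_map(X, R01)
  } else {
    k <- as.integer(substring(method, 7L))
    if (n < k) stop_hs("calibration", "fewer patches than clusters")
    km <- seeded_kmeans(M01, k, seed = seed)
    Xg <- poly_basis(M01, 1L)
    global <- least_squares_map(Xg, R01)
    model$coefficients <- global
    model$centroids <- km$centers
    model$cluster_coefficients <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- which(km$cluster == j)
      model$cluster_coefficients[[j]] <-
        if (length(idx) >= 4L) {
          Xj <- poly_basis(M01[idx, , drop = FALSE], 1L)
          qj <- qr(Xj)
          if (qj$rank < ncol(Xj)) global else qr.coef(qj, R01[idx, , drop = FALSE])
        } else global
    }
  }
  model <- structure(model, class = "calibration_model")
  pred <- predict_calibration(model, patches$measured_rgb, clip = FALSE)
  model$residuals <- color_distance(pred, patches$reference_rgb, "rgb")
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> method = %s, mean RGB residual = %.4g\n",
              x$method, mean(x$residuals)))
  invisible(x)
}

#' Apply a calibration model to RGB colors
#'
#' @param model a fitted [fit_calibration()] model.
#' @param rgb255 `n x 3` matrix of RGB colors on the 0–255 scale.
#' @param clip clip the output to `[0, 255]` (default `TRUE`).
#' @return `n x 3` matrix of calibrated RGB (0–255).
#' @export
predict_calibration <- function(model, rgb255, clip = TRUE) {
  if (!inherits(model, "calibration_model") || is.null(model$coefficients)) {
    stop_hs("calibration", "usage error: model is not fitted")
  }
  m01 <- as.matrix(rgb255) / 255
  if (startsWith(model$method, "kmeans")) {
    k <- nrow(model$centroids)
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((m01 - matrix(model$centroids[j, ], nrow(m01), 3L, byrow = TRUE))^2)
    })
    cl <- max.col(-matrix(d2, nrow(m01), k), ties.method = "first")
    out <- matrix(NA_real_, nrow(m01), 3L)
    X <- poly_basis(m01, 1L)
    for (j in seq_len(k)) {
      idx <- which(cl == j)
      if (length(idx) > 0L) {
        out[idx, ] <- X[idx, , drop = FALSE] %*% model$cluster_coefficients[[j]]
      }
    }
  } else {
    X <- poly_basis(m01, method_degree(model$method))
    out <- X %*% model$coefficients
  }
  out <- out * 255
  if (clip) out <- clip_rgb255(out)
  colnames(out) <- c("R", "G", "B")
  out
}

#' Apply a calibration model to an image
#'
#' Per-pixel application of the fitted transform (k-means models select the
#' map of the nearest centroid in measured RGB); output clipped to `[0, 1]`.
#'
#' @param raster `H x W x 3` raster in `[0, 1]`.
#' @param model a fitted [fit_calibration()] model.
#' @return calibrated raster, same shape, in `[0, 1]`.
#' @export
apply_calibration <- function(raster, model) {
  stopifnot(is_raster(raster), n_channels(raster) == 3L)
  d <- dim(raster)
  px <- cbind(as.numeric(raster[, , 1L]), as.numeric(raster[, , 2L]),
              as.numeric(raster[, , 3L])) * 255
  out <- predict_calibration(model, px) / 255
  array(out, d)
}

#' Compare calibration methods on a patch set
#'
#' For each model, the measured patch colors are calibrated and scored
#' against the references by the mean Euclidean RGB distance and the mean
#' Euclidean CIELab distance; `reduction_pct` is the percentage reduction of
#' the mean CIELab distance relative to the uncalibrated measurement. The
#' report is sorted ascending by mean CIELab distance (best first).
#'
#' @param models list of fitted [fit_calibration()] models.
#' @param patches a [color_patch_set()].
#' @return data.frame `(method, mean_rgb_distance, mean_lab_distance,
#'   reduction_pct)`, one row per model, plus an `"uncalibrated"` baseline
#'   attribute row.
#' @export
evaluate_calibration <- function(models, patches) {
  stopifnot(inherits(patches, "color_patch_set"))
  if (inherits(models, "calibration_model")) models <- list(models)
  base_rgb <- mean(color_distance(patches$measured_rgb,
                                  patches$reference_rgb, "rgb"))
  base_lab <- mean(color_distance(srgb_to_lab(patches$measured_rgb),
                                  patches$reference_lab, "lab"))
  rows <- lapply(models, function(m) {
    cal <- predict_calibration(m, patches$measured_rgb)
    rgb_d <- mean(color_distance(cal, patches$reference_rgb, "rgb"))
    lab_d <- mean(color_distance(srgb_to_lab(cal), patches$reference_lab, "lab"))
    data.frame(method = m$method, mean_rgb_distance = rgb_d,
               mean_lab_distance = lab_d,
               reduction_pct = 100 * (1 - lab_d / base_lab))
  })
  report <- do.call(rbind, rows)
  report <- report[order(report$mean_lab_distance), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "uncalibrated") <- data.frame(
    method = "uncalibrated", mean_rgb_distance = base_rgb,
    mean_lab_distance = base_lab, reduction_pct = 0)
  report
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a fitted [fit_calibration()] model.
#' @param path JSON file path.
#' @return `save_calibration`: `path` invisibly; `load_calibration`: the
#'   restored model.
#' @export
save_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(method = model$method,
              coefficients = model$coefficients,
              centroids = model$centroids,
              cluster_coefficients = model$cluster_coefficients,
              residuals = model$residuals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) if (is.null(x)) NULL else as.matrix(x)
  model <- list(method = obj$method,
                coefficients = to_mat(obj$coefficients),
                centroids = to_mat(obj$centroids),
                cluster_coefficients = restore_cluster_coefs(obj$cluster_coefficients),
                residuals = obj$residuals)
  structure(model, class = "calibration_model")
}

# jsonlite simplifies a list of equally-shaped matrices to a 3-d array
# (clusters x rows x cols); split it back into per-cluster matrices.
restore_cluster_coefs <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[1L]), function(j) {
      matrix(x[j, , ], dim(x)[2L], dim(x)[3L])
    }))
  }
  lapply(x, as.matrix)
}
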