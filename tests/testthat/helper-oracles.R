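# Independent brute-force oracles used to pin down the vectorized
# implementations. These deliberately use naive double loops and their own
# padding/index arithmetic so they share no code path with the package.

# symmetric (mirror) index into 1..n
sym_idx <- function(i, n) {
  m <- 2L * n
  p <- ((i - 1L) %% m + m) %% m
  ifelse(p < n, p + 1L, m - p)
}

# Brute-force local variance of a matrix over an odd window, symmetric pad.
oracle_local_variance <- function(m, window) {
  r <- (window - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      vals <- numeric(window^2)
      k <- 0L
      for (dy in -r:r) {
        for (dx in -r:r) {
          k <- k + 1L
          vals[k] <- m[sym_idx(y + dy, h), sym_idx(x + dx, w)]
        }
      }
      out[y, x] <- mean(vals^2) - mean(vals)^2
    }
  }
  out
}

# Brute-force convolution with an odd kernel, symmetric pad.
oracle_conv2 <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1L) %/% 2L; rx <- (kw - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      acc <- 0
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          acc <- acc + kernel[i, j] *
            m[sym_idx(y + i - ry - 1L, h), sym_idx(x + j - rx - 1L, w)]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# Direct per-pixel evaluation of the focus-weighted fusion rule.
oracle_fuse <- function(frames, maps) {
  d <- dim(frames[[1L]])
  k <- length(frames)
  out <- array(0, d)
  for (y in seq_len(d[1L])) {
    for (x in seq_len(d[2L])) {
      fm <- vapply(maps, function(m) m[y, x], numeric(1))
      tot <- sum(fm)
      w <- if (tot == 0) rep(1 / k, k) else fm / tot
      for (c in seq_len(d[3L])) {
        out[y, x, c] <- sum(w * vapply(frames, function(f) f[y, x, c],
                                       numeric(1)))
      }
    }
  }
  out
}

# Brute-force non-local means on one plane, same weight formula as the
# documented algorithm, built from scratch with loops.
oracle_nlm <- function(m, h_par, search, comparison) {
  sr <- (search - 1L) %/% 2L
  cr <- (comparison - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # noise estimate: MAD of (x - 3x3 mean), symmetric pad, by loops
  resid <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      s <- 0
      for (dy in -1:1) for (dx in -1:1) {
        s <- s + m[sym_idx(y + dy, H), sym_idx(x + dx, W)]
      }
      resid[y, x] <- m[y, x] - s / 9
    }
  }
  sig2 <- (1.4826 * stats::median(abs(resid)))^2
  patch <- function(y, x) {
    out <- numeric(comparison^2)
    k <- 0L
    for (dy in -cr:cr) for (dx in -cr:cr) {
      k <- k + 1L
      out[k] <- m[sym_idx(y + dy, H), sym_idx(x + dx, W)]
    }
    out
  }
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      p0 <- patch(y, x)
      num <- 0; den <- 0
      for (dy in -sr:sr) {
        for (dx in -sr:sr) {
          yy <- y + dy; xx <- x + dx
          pq <- patch(yy, xx)
          d2 <- mean((p0 - pq)^2)
          w <- exp(-max(d2 - 2 * sig2, 0) / h_par^2)
          num <- num + w * m[sym_idx(yy, H), sym_idx(xx, W)]
          den <- den + w
        }
      }
      out[y, x] <- num / den
    }
  }
  out
}

# Closed-form SSIM of two equal-size windows from their raw moments.
oracle_ssim_window <- function(a, b, K1 = 0.01, K2 = 0.03) {
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean(a^2) - mu_a^2
  vb <- mean(b^2) - mu_b^2
  cab <- mean(a * b) - mu_a * mu_b
  C1 <- K1^2; C2 <- K2^2
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

# Hand-computed mutual information of two quantized vectors (nats),
# normalized by half the entropy sum.
oracle_nmi <- function(a, b, bins) {
  ia <- pmin(floor(a * bins), bins - 1L)
  ib <- pmin(floor(b * bins), bins - 1L)
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ia)) {
    joint[ia[k] + 1L, ib[k] + 1L] <- joint[ia[k] + 1L, ib[k] + 1L] + 1L
  }
  pj <- joint / length(ia)
  pa <- rowSums(pj); pb <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (pj[i, j] > 0) {
      mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
    }
  }
  mi / (0.5 * (ent(pa) + ent(pb)))
}

# Spatial frequency of a plane, hand-written.
oracle_sf <- function(m) {
  h <- nrow(m); w <- ncol(m)
  dh <- dv <- d1 <- d2 <- c()
  for (y in 1:h) for (x in 2:w) dh <- c(dh, m[y, x] - m[y, x - 1])
  for (y in 2:h) for (x in 1:w) dv <- c(dv, m[y, x] - m[y - 1, x])
  for (y in 2:h) for (x in 2:w) d1 <- c(d1, m[y, x] - m[y - 1, x - 1])
  for (y in 2:h) for (x in 1:(w - 1)) d2 <- c(d2, m[y, x] - m[y - 1, x + 1])
  wd <- 1 / sqrt(2)
  sqrt(mean(dh^2) + mean(dv^2) + wd * mean(d1^2) + wd * mean(d2^2))
}

# Reference spatial frequency from per-pixel maximum absolute directional
# differences over a list of frames, hand-written.
oracle_sf_abs_ref <- function(frames) {
  diffs <- function(m) {
    h <- nrow(m); w <- ncol(m)
    list(dh = m[, 2:w, drop = FALSE] - m[, 1:(w - 1), drop = FALSE],
         dv = m[2:h, , drop = FALSE] - m[1:(h - 1), , drop = FALSE],
         d1 = m[2:h, 2:w, drop = FALSE] - m[1:(h - 1), 1:(w - 1), drop = FALSE],
         d2 = m[2:h, 1:(w - 1), drop = FALSE] - m[1:(h - 1), 2:w, drop = FALSE])
  }
  ref <- NULL
  for (f in frames) {
    d <- diffs(f)
    ref <- if (is.null(ref)) lapply(d, abs) else Map(function(a, b) pmax(a, abs(b)), ref, d)
  }
  wd <- 1 / sqrt(2)
  sqrt(mean(ref$dh^2) + mean(ref$dv^2) + wd * mean(ref$d1^2) + wd * mean(ref$d2^2))
}

# Exhaustive resolved-criterion check: scans every triple of detected deep
# minima for an alternating min-max-min-max-min pattern.
oracle_resolved <- function(minima, maxima, y, threshold) {
  deep <- sort(minima[y[minima] < threshold])
  if (length(deep) < 3L) return(FALSE)
  combs <- utils::combn(deep, 3L)
  for (c in seq_len(ncol(combs))) {
    m1 <- combs[1L, c]; m2 <- combs[2L, c]; m3 <- combs[3L, c]
    if (any(maxima > m1 & maxima < m2) && any(maxima > m2 & maxima < m3)) {
      return(TRUE)
    }
  }
  FALSE
}

# Brute-force Savitzky-Golay on interior samples: per-sample least-squares
# polynomial fit over the centered window, evaluated at the center
# (the intercept at t = 0). End transients are not replicated.
oracle_sg_interior <- function(y, window, polyorder) {
  r <- (window - 1L) %/% 2L
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (r + 1L):(n - r)) {
    t <- (-r):r
    X <- outer(t, 0:polyorder, `^`)
    beta <- qr.coef(qr(X), y[(i - r):(i + r)])
    out[i] <- beta[1L]
  }
  out
}

# Chen-Varshney-style score by direct evaluation, sharing only the kernel
# definition (truncated normalized Gaussian, radius 3 sigma).
oracle_cv <- function(fused, frames, region_size, csf_sigma) {
  gk <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    k / sum(k)
  }
  blur_sym <- function(m, sigma) {
    k <- gk(sigma); r <- (length(k) - 1L) %/% 2L
    h <- nrow(m); w <- ncol(m)
    tmp <- matrix(0, h, w)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      tmp[y, x] <- sum(k * m[sym_idx(y + (-r):r, h), x])
    }
    out <- matrix(0, h, w)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      out[y, x] <- sum(k * tmp[y, sym_idx(x + (-r):r, w)])
    }
    out
  }
  sobel <- function(m) {
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- oracle_conv2(m, sx)
    gy <- oracle_conv2(m, t(sx))
    gx^2 + gy^2
  }
  h <- nrow(fused); w <- ncol(fused)
  sal <- lapply(frames, sobel)
  derr <- lapply(frames, function(fr) blur_sym(fused - fr, csf_sigma)^2)
  num <- 0; den <- 0
  for (y0 in seq(1, h, region_size)) {
    for (x0 in seq(1, w, region_size)) {
      rows <- y0:min(y0 + region_size - 1L, h)
      cols <- x0:min(x0 + region_size - 1L, w)
      lam <- vapply(sal, function(s) sum(s[rows, cols]), numeric(1))
      tot <- sum(lam)
      wts <- if (tot > 0) lam / tot else rep(1 / length(lam), length(lam))
      errs <- vapply(derr, function(d) mean(d[rows, cols]), numeric(1))
      num <- num + tot * sum(wts * errs)
      den <- den + tot
    }
  }
  num / den
}

# Ideal three-bar intensity profile with minima at the given level,
# pre-smoothed for judging.
make_shallow_bar_profile <- function(minima_level) {
  vals <- rep(c(1, minima_level, 1, minima_level, 1, minima_level, 1),
              each = 20)
  prof <- structure(list(positions = seq_along(vals) - 1, intensities = vals,
                         segment = NULL, smoothed = FALSE),
                    class = "intensity_profile")
  smooth_profile(prof, window = 9, polyorder = 2)
}

# Small random 3-channel stack for fusion tests.
random_stack <- function(k, h, w, seed) {
  hyperstack:::with_seed(seed, {
    frames <- lapply(seq_len(k), function(i) array(runif(h * w * 3), c(h, w, 3)))
    image_stack(frames)
  })
}

# A two-frame mosaic fixture: frame A sharp on the left half, frame B sharp
# on the right, with one-hot focus maps. The texture is band-limited
# (speckle-like) so local structure, not per-pixel noise, carries the
# similarity signal.
mosaic_fixture <- function(h = 64, w = 64, seed = 4) {
  hyperstack:::with_seed(seed, {
    base <- array(runif(h * w * 3), c(h, w, 3))
    sharp <- hyperstack:::clip01(hyperstack:::apply_planes(base, function(m) {
      s <- hyperstack:::gaussian_blur(m, 1.5)
      0.5 + (s - mean(s)) * 3
    }))
    left <- sharp; right <- sharp
    blur <- hyperstack:::gaussian_blur(sharp, 1.5)
    for (c in 1:3) {
      left[, (w %/% 2 + 1):w, c] <- blur[, (w %/% 2 + 1):w, c]
      right[, 1:(w %/% 2), c] <- blur[, 1:(w %/% 2), c]
    }
    m1 <- matrix(0, h, w); m1[, 1:(w %/% 2)] <- 1
    m2 <- 1 - m1
    list(stack = image_stack(list(left, right)), maps = list(m1, m2),
         sharp = sharp)
  })
}
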