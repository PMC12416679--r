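# Objective USAF 1951 resolution analysis: intensity-profile extraction,
# Savitzky-Golay smoothing, prominence-filtered extrema detection, the
# three-minima / two-maxima resolved criterion with an 80% depth threshold,
# and conversion of the finest resolved element to a physical resolution.

#' USAF 1951 element spatial frequency and line width
#'
#' Element `e` of group `g` has spatial frequency `2^(g + (e - 1)/6)` line
#' pairs per millimeter; the line width in micrometers is `500 / lp_per_mm`.
#' Group 4 element 2 gives 27.84 um, presented as 28 um at integer rounding.
#'
#' @param group group number (integer, may be negative); vectorized.
#' @param element element number 1–6; vectorized.
#' @return list with `lp_per_mm` and `line_width_um`.
#' @examples
#' element_resolution(4, 2)$line_width_um   # 27.84
#' element_resolution(0, 1)                 # 1 lp/mm, 500 um
#' @export
element_resolution <- function(group, element) {
  if (!all(element %in% 1:6)) stop_hs("resolution", "element must be in 1..6")
  lp <- 2^(group + (element - 1) / 6)
  list(lp_per_mm = lp, line_width_um = 500 / lp)
}

#' Sample an intensity profile along a line segment
#'
#' The raster is collapsed to grayscale (luminance) and bilinearly
#' interpolated at `step`-pixel spacing along the segment from `p0` to
#' `p1` (1-based pixel-center `(x, y)` coordinates).
#'
#' @param raster raster in `[0, 1]`.
#' @param p0,p1 numeric `(x, y)` segment endpoints inside the raster.
#' @param step sample spacing in pixels (default 0.25).
#' @return object of class `intensity_profile`: `positions` (distance along
#'   the segment, pixels), `intensities`, `segment`, `smoothed = FALSE`.
#' @export
sample_profile <- function(raster, p0, p1, step = 0.25) {
  lum <- luminance(raster)
  h <- nrow(lum); w <- ncol(lum)
  if (any(c(p0[1L], p1[1L]) < 1) || any(c(p0[1L], p1[1L]) > w) ||
      any(c(p0[2L], p1[2L]) < 1) || any(c(p0[2L], p1[2L]) > h)) {
    stop_hs("resolution", "probe endpoints must lie inside the raster")
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len < 8 * step) {
    stop_hs("resolution", "unusable probe: segment shorter than 8 samples")
  }
  pos <- seq(0, len, by = step)
  t <- pos / len
  xs <- p0[1L] + t * (p1[1L] - p0[1L])
  ys <- p0[2L] + t * (p1[2L] - p0[2L])
  vals <- as.numeric(bilinear_sample(lum, xs, ys))
  structure(list(positions = pos, intensities = vals,
                 segment = list(p0 = p0, p1 = p1), smoothed = FALSE),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples over %.1f px%s\n",
              length(x$positions), max(x$positions),
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Savitzky-Golay smoothing of an intensity profile
#'
#' Local least-squares polynomial smoothing: polynomial signals of degree
#' at most `polyorder` pass through unchanged, which preserves bar-profile
#' shape while suppressing noise and minor fluctuations.
#'
#' @param profile an [sample_profile()] result.
#' @param window odd window length in samples; default the nearest odd
#'   number not below half the samples-per-line-width implied by the
#'   profile, floored at 5 (callers that know the bar width should pass an
#'   explicit window).
#' @param polyorder polynomial order (default 2), must be `< window`.
#' @return the profile with smoothed intensities and `smoothed = TRUE`.
#' @export
smooth_profile <- function(profile, window = NULL, polyorder = 2L) {
  stopifnot(inherits(profile, "intensity_profile"))
  n <- length(profile$intensities)
  if (is.null(window)) {
    window <- max(5L, as.integer(round(n / 30)))
    if (window %% 2L == 0L) window <- window + 1L
  }
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder) {
    stop_hs("resolution", "parameter error: window must be odd and > polyorder")
  }
  if (window > n) {
    stop_hs("resolution", "parameter error: window longer than profile")
  }
  out <- profile
  out$intensities <- as.numeric(
    signal::sgolayfilt(profile$intensities, p = polyorder, n = window))
  out$smoothed <- TRUE
  out
}

# Local extrema of y with at least the given prominence. Returns maxima
# indices (plateaus contribute their first sample). Standard prominence:
# height above the higher of the two key saddles toward the nearest
# higher peaks (or the signal ends).
find_peaks <- function(y, prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L || prominence <= 0) return(cand)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]
    # walk left to the nearest strictly higher sample (or the start)
    left_min <- y[p]
    i <- p
    while (i > 1L) {
      i <- i - 1L
      if (y[i] > y[p]) break
      left_min <- min(left_min, y[i])
      if (i == 1L) break
    }
    if (y[i] <= y[p]) left_min <- min(left_min, y[i])
    right_min <- y[p]
    i <- p
    while (i < n) {
      i <- i + 1L
      if (y[i] > y[p]) break
      right_min <- min(right_min, y[i])
      if (i == n) break
    }
    if (y[i] <= y[p]) right_min <- min(right_min, y[i])
    keep[k] <- (y[p] - max(left_min, right_min)) >= prominence
  }
  cand[keep]
}

#' Judge whether a tri-bar element is resolved
#'
#' Detects significant minima and maxima in the smoothed profile
#' (prominence at least `prominence_fraction` of the profile's dynamic
#' range) and applies the resolved criterion for three dark lines on a
#' bright background: the element is resolved if three detected minima,
#' each falling below `threshold_fraction` of the profile's maximum
#' intensity, alternate with detected maxima in a min–max–min–max–min
#' pattern. Flanking extrema outside the pattern are ignored.
#'
#' @param profile an [intensity_profile()]; unsmoothed profiles are
#'   smoothed with defaults first (with a warning).
#' @param prominence_fraction extremum prominence as a fraction of the
#'   profile's dynamic range (default 0.05).
#' @param threshold_fraction minima must fall below this fraction of the
#'   profile maximum (default 0.80).
#' @return list: `resolved` (flag), `minima`, `maxima` (sample indices of
#'   detected extrema), `deep_minima` (minima below the threshold),
#'   `threshold` (absolute intensity threshold).
#' @export
judge_element <- function(profile, prominence_fraction = 0.05,
                          threshold_fraction = 0.80) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (!profile$smoothed) {
    warning("judging an unsmoothed profile; smoothing with defaults")
    profile <- smooth_profile(profile)
  }
  y <- profile$intensities
  rng <- diff(range(y))
  prom <- prominence_fraction * rng
  maxima <- find_peaks(y, prom)
  minima <- find_peaks(-y, prom)
  thr <- threshold_fraction * max(y)
  deep <- minima[y[minima] < thr]
  resolved <- FALSE
  if (length(deep) >= 3L && length(maxima) >= 2L) {
    deep <- sort(deep)
    # any three deep minima with >= 1 detected maximum strictly between
    # each consecutive pair
    for (a in seq_len(length(deep) - 2L)) {
      for (b in (a + 1L):(length(deep) - 1L)) {
        if (!any(maxima > deep[a] & maxima < deep[b])) next
        for (c in (b + 1L):length(deep)) {
          if (any(maxima > deep[b] & maxima < deep[c])) {
            resolved <- TRUE
            break
          }
        }
        if (resolved) break
      }
      if (resolved) break
    }
  }
  list(resolved = resolved, minima = minima, maxima = maxima,
       deep_minima = deep, threshold = thr)
}

#' Analyze a USAF target image element by element
#'
#' Runs sample–smooth–judge over an ordered (coarse to fine) sequence of
#' per-element probe segments and reports the resolved status of each
#' element, the strict finest resolved element (the last one before the
#' first unresolved element) and, separately, the full resolved set.
#'
#' @param raster target image.
#' @param specs data.frame `(group, element, x0, y0, x1, y1)` of probe
#'   segments in 1-based pixel-center coordinates, coarse to fine (e.g.
#'   from [make_usaf_image()]).
#' @param step profile sample spacing in pixels (default 0.25).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters; by default the
#'   window adapts to each element's bar width (half the samples per line
#'   width, odd, floored at 5).
#' @param prominence_fraction,threshold_fraction passed to
#'   [judge_element()].
#' @return list: `report` (data.frame `group, element, resolved, n_minima,
#'   n_maxima, lp_per_mm, line_width_um`), `finest_resolved` (row of the
#'   strict cutoff element, or `NULL`), `resolved_set` (indices of all
#'   resolved elements).
#' @export
analyze_target <- function(raster, specs, step = 0.25, sg_window = NULL,
                           sg_polyorder = 2L, prominence_fraction = 0.05,
                           threshold_fraction = 0.80) {
  if (is.null(specs) || nrow(specs) == 0L) {
    stop_hs("resolution", "usage error: empty element specs")
  }
  fr <- specs$group + (specs$element - 1) / 6
  if (is.unsorted(fr)) {
    warning("element specs are not ordered coarse to fine; results keep input order")
  } else if (nrow(specs) > 1L && any(abs(diff(fr) - 1 / 6) > 1e-9)) {
    warning("element specs are not contiguous; the strict cutoff may skip elements")
  }
  res <- element_resolution(specs$group, specs$element)
  report <- data.frame(group = specs$group, element = specs$element,
                       resolved = NA, n_minima = NA_integer_,
                       n_maxima = NA_integer_, lp_per_mm = res$lp_per_mm,
                       line_width_um = res$line_width_um)
  for (i in seq_len(nrow(specs))) {
    prof <- sample_profile(raster, c(specs$x0[i], specs$y0[i]),
                           c(specs$x1[i], specs$y1[i]), step = step)
    win <- sg_window
    if (is.null(win)) {
      # samples per line width: width in px / step; window ~ half of that
      lw_px <- report$line_width_um[i] / 1000 *
        attr(specs, "pixels_per_mm") %||% NA
      spl <- if (is.na(lw_px)) length(prof$positions) / 9 else lw_px / step
      win <- max(5L, as.integer(round(spl / 2)))
      if (win %% 2L == 0L) win <- win + 1L
      win <- min(win, length(prof$intensities) -
                   (1 - length(prof$intensities) %% 2L))
    }
    prof <- smooth_profile(prof, window = win, polyorder = sg_polyorder)
    j <- judge_element(prof, prominence_fraction, threshold_fraction)
    report$resolved[i] <- j$resolved
    report$n_minima[i] <- length(j$minima)
    report$n_maxima[i] <- length(j$maxima)
  }
  first_fail <- which(!report$resolved)[1L]
  finest <- if (is.na(first_fail)) {
    report[nrow(report), ]
  } else if (first_fail == 1L) {
    NULL
  } else {
    report[first_fail - 1L, ]
  }
  list(report = report, finest_resolved = finest,
       resolved_set = which(report$resolved))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
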