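#' Thin-lens configuration
#'
#' Bundles the focal geometry of a focus-sweep acquisition: the thin-lens
#' conjugates (focal length `f`, object distance `U`, image distance `V`, all
#' in meters, related by `1/f = 1/U + 1/V`), the focal-length sweep
#' (`sweep_start`, `sweep_end`, `sweep_interval`) and the corresponding
#' focal-plane sweep (`plane_start`, `plane_end`), plus the aperture diameter.
#' Unset quantities are `NA`.
#'
#' @param f,U,V focal length, object distance, image distance (m).
#' @param sweep_start,sweep_end,sweep_interval focal-length sweep (m).
#' @param plane_start,plane_end focal-plane sweep bounds (m).
#' @param aperture_diameter aperture diameter (m).
#' @return object of class `thin_lens_config`.
#' @examples
#' thin_lens_config(f = 0.2, U = 0.6, V = 0.3)
#' @export
thin_lens_config <- function(f = NA_real_, U = NA_real_, V = NA_real_,
                             sweep_start = NA_real_, sweep_end = NA_real_,
                             sweep_interval = NA_real_,
                             plane_start = NA_real_, plane_end = NA_real_,
                             aperture_diameter = NA_real_) {
  cfg <- list(f = f, U = U, V = V,
              sweep_start = sweep_start, sweep_end = sweep_end,
              sweep_interval = sweep_interval,
              plane_start = plane_start, plane_end = plane_end,
              aperture_diameter = aperture_diameter)
  vals <- unlist(cfg)
  if (any(!is.na(vals) & vals <= 0)) {
    stop_hs("optics", "all thin-lens distances must be strictly positive")
  }
  if (!is.na(sweep_start) && !is.na(sweep_end) && sweep_start > sweep_end) {
    stop_hs("optics", "sweep_start must not exceed sweep_end")
  }
  if (!is.na(plane_start) && !is.na(plane_end) && plane_start > plane_end) {
    stop_hs("optics", "plane_start must not exceed plane_end")
  }
  if (!is.na(f) && !is.na(U) && !is.na(V)) {
    lhs <- 1 / f; rhs <- 1 / U + 1 / V
    if (abs(lhs - rhs) > 1e-9 * abs(lhs)) {
      stop_hs("optics", "f, U, V violate the thin-lens equation 1/f = 1/U + 1/V")
    }
  }
  structure(cfg, class = "thin_lens_config")
}

#' @export
print.thin_lens_config <- function(x, ...) {
  cat("<thin_lens_config>\n")
  set <- Filter(function(v) !is.na(v), unclass(x))
  for (nm in names(set)) cat(sprintf("  %-18s %g m\n", nm, set[[nm]]))
  invisible(x)
}

#' Solve the thin-lens equation for the missing conjugate
#'
#' Given two of focal length `f`, object distance `U` and image distance `V`
#' (meters), fills in the third from `1/f = 1/U + 1/V`.
#'
#' @param f,U,V two of the three must be given (positive, meters).
#' @return [thin_lens_config()] with all of `f`, `U`, `V` set.
#' @examples
#' solve_thin_lens(U = 0.6, V = 0.3)$f  # 0.2
#' @export
solve_thin_lens <- function(f = NA_real_, U = NA_real_, V = NA_real_) {
  given <- c(f = !is.na(f), U = !is.na(U), V = !is.na(V))
  if (sum(given) != 2L) {
    stop_hs("optics", "exactly two of f, U, V must be supplied")
  }
  if (any(c(f, U, V)[given] <= 0)) {
    stop_hs("optics", "thin-lens distances must be positive")
  }
  if (!given["f"]) {
    f <- U * V / (U + V)
  } else if (!given["U"]) {
    if (abs(V - f) < .Machine$double.eps * max(V, f)) {
      stop_hs("optics", "no finite conjugate: V = f")
    }
    U <- 1 / (1 / f - 1 / V)
    if (U <= 0) stop_hs("optics", "no finite conjugate: V < f forces U <= 0")
  } else {
    if (abs(U - f) < .Machine$double.eps * max(U, f)) {
      stop_hs("optics", "no finite conjugate: U = f")
    }
    V <- 1 / (1 / f - 1 / U)
    if (V <= 0) stop_hs("optics", "no finite conjugate: U < f forces V <= 0")
  }
  thin_lens_config(f = f, U = U, V = V)
}

#' Plan a focal-plane sweep around an estimated working distance
#'
#' Returns `n` focal-plane distances evenly spaced on
#' `[estimated_distance - half_range, estimated_distance + half_range]`,
#' the stack-planning rule for a focus sweep centered on the measured
#' distance to the skin. With `n = 1` the estimate itself is returned.
#' When `n` is omitted it is drawn from the typical stack-size range
#' 10 to 20.
#'
#' @param estimated_distance estimated distance to the subject (m).
#' @param n number of frames (default: sampled from 10..20).
#' @param half_range half-width of the sweep (m), default 0.02.
#' @param seed RNG seed used only when `n` is omitted.
#' @return increasing numeric vector of `n` focal-plane distances (m).
#' @examples
#' plan_focus_sweep(0.45, n = 15, half_range = 0.02)
#' @export
plan_focus_sweep <- function(estimated_distance, n = NULL, half_range = 0.02,
                             seed = 0L) {
  if (!is.numeric(estimated_distance) || estimated_distance <= 0) {
    stop_hs("optics", "invalid geometry: estimated distance must be positive")
  }
  if (half_range < 0) stop_hs("optics", "half_range must be >= 0")
  if (estimated_distance <= half_range) {
    stop_hs("optics", "invalid geometry: estimated distance must exceed half_range")
  }
  if (is.null(n)) n <- with_seed(seed, sample(10:20, 1L))
  n <- as.integer(n)
  if (n < 1L) stop_hs("optics", "n must be >= 1")
  if (n == 1L) return(estimated_distance)
  seq(estimated_distance - half_range, estimated_distance + half_range,
      length.out = n)
}
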