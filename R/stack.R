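#' Per-frame acquisition metadata
#'
#' @param index 0-based frame index, unique within a stack.
#' @param focal_plane_distance distance of the in-focus object plane (m),
#'   `NA` when unknown.
#' @param lens_power optional lens power (diopters).
#' @param exposure optional free-text exposure tag.
#' @return object of class `frame_meta`.
#' @export
frame_meta <- function(index, focal_plane_distance = NA_real_,
                       lens_power = NA_real_, exposure = NA_character_) {
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop_hs("stack", "frame index must be >= 0")
  if (!is.na(focal_plane_distance) && focal_plane_distance <= 0) {
    stop_hs("stack", "focal_plane_distance must be positive when set")
  }
  structure(list(index = index,
                 focal_plane_distance = as.numeric(focal_plane_distance),
                 lens_power = as.numeric(lens_power),
                 exposure = as.character(exposure)),
            class = "frame_meta")
}

#' An ordered stack of differently-focused frames
#'
#' The container every pipeline stage transforms: `k` frames of identical
#' height, width and channel count with intensities in `[0, 1]`, paired with
#' per-frame [frame_meta()] records (typically one focal-plane distance per
#' frame).
#'
#' @param frames list of `H x W x 3` arrays (or `H x W` matrices) in `[0, 1]`.
#' @param metas list of [frame_meta()], same length as `frames`; by default
#'   frames are indexed 0..k-1 with unknown focal planes.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, metas = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop_hs("stack", "a stack needs at least one frame")
  }
  if (is.null(metas)) {
    metas <- lapply(seq_along(frames) - 1L, frame_meta)
  }
  if (length(metas) != length(frames)) {
    stop_hs("stack", "manifest error: ", length(frames), " frames but ",
            length(metas), " metadata entries")
  }
  d1 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is_raster(f)) stop_hs("stack", "frame ", i, " is not a numeric raster")
    if (!identical(dim(f), d1)) {
      stop_hs("stack", "corrupt stack: frame ", i, " shape differs from frame 1")
    }
    rng <- range(f)
    if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
      stop_hs("stack", "frame ", i, " intensities outside [0, 1]")
    }
    if (!inherits(metas[[i]], "frame_meta")) {
      stop_hs("stack", "metadata entry ", i, " is not a frame_meta")
    }
  }
  idx <- vapply(metas, function(m) m$index, integer(1))
  if (anyDuplicated(idx)) stop_hs("stack", "frame indices must be unique")
  structure(list(frames = frames, metas = metas), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  fp <- focal_planes(x)
  cat(sprintf("<image_stack> %d frame(s), %d x %d x %d\n",
              length(x$frames), d[1L], d[2L],
              if (length(d) == 3L) d[3L] else 1L))
  if (any(!is.na(fp))) {
    cat(sprintf("  focal planes: %s m\n",
                paste(signif(fp, 4), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Focal-plane distances of a stack
#' @param stack an [image_stack()].
#' @return numeric vector (m), `NA` where unknown.
#' @export
focal_planes <- function(stack) {
  vapply(stack$metas, function(m) m$focal_plane_distance, numeric(1))
}

quantize_levels <- function(bit_depth) {
  if (!bit_depth %in% c(8L, 16L)) stop_hs("io", "bit_depth must be 8 or 16")
  2^bit_depth - 1
}

#' Save a raster to TIFF or PNG
#'
#' Intensities in `[0, 1]` are quantized to the requested bit depth before
#' writing, so a save/load round trip reproduces values to within half a
#' quantization step. 16-bit output requires TIFF (`.tif`/`.tiff`); PNG
#' carries 8-bit.
#'
#' @param raster `H x W x 3` array or `H x W` matrix in `[0, 1]`.
#' @param path output file, extension selects the format.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
save_image <- function(raster, path, bit_depth = 16L) {
  levels <- quantize_levels(bit_depth)
  x <- round(clip01(raster) * levels) / levels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    if (bit_depth != 8L) stop_hs("io", "PNG output is written at 8 bit")
    png::writePNG(x, path)
  } else {
    stop_hs("io", "unsupported image format: .", ext)
  }
  invisible(path)
}

#' Load a TIFF or PNG raster
#' @param path image file.
#' @return `H x W x C` numeric array in `[0, 1]` (alpha dropped), or
#'   `H x W` matrix for single-channel files.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_hs("io", "missing image file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_hs("io", "unsupported image format: .", ext))
  if (length(dim(x)) == 3L && dim(x)[3L] == 4L) x <- x[, , 1:3]
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  x
}

#' Write an image stack to disk with a JSON manifest
#'
#' Frames are written as numbered TIFF (or PNG) files next to a `stack.json`
#' sidecar listing, per frame, the file name, focal-plane distance and lens
#' power. [load_stack()] reads the pair back; frame order follows the
#' manifest.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param bit_depth 8 (PNG) or 16 (TIFF) per frame file.
#' @return path to the manifest, invisibly.
#' @export
save_stack <- function(stack, dir, bit_depth = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (bit_depth == 16L) "tiff" else "png"
  entries <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    fn <- sprintf("frame_%03d.%s", i - 1L, ext)
    save_image(stack$frames[[i]], file.path(dir, fn), bit_depth)
    m <- stack$metas[[i]]
    entries[[i]] <- list(file = fn, index = m$index,
                         focal_plane_distance = m$focal_plane_distance,
                         lens_power = m$lens_power,
                         exposure = m$exposure)
  }
  manifest <- file.path(dir, "stack.json")
  jsonlite::write_json(list(frames = entries), manifest,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(manifest)
}

#' Load an image stack from a JSON manifest
#'
#' @param manifest_path path to a `stack.json` written by [save_stack()] (or
#'   by hand: a `frames` array of `{file, index, focal_plane_distance,
#'   lens_power}` records; file paths are resolved relative to the manifest).
#' @return an [image_stack()].
#' @export
load_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_hs("io", "missing stack manifest: ", manifest_path)
  }
  man <- jsonlite::read_json(manifest_path)
  if (is.null(man$frames) || length(man$frames) == 0L) {
    stop_hs("io", "manifest error: no frames listed")
  }
  base <- dirname(manifest_path)
  frames <- vector("list", length(man$frames))
  metas <- vector("list", length(man$frames))
  for (i in seq_along(man$frames)) {
    e <- man$frames[[i]]
    if (is.null(e$file)) stop_hs("io", "manifest error: frame ", i, " has no file")
    frames[[i]] <- load_image(file.path(base, e$file))
    metas[[i]] <- frame_meta(
      index = if (is.null(e$index)) i - 1L else e$index,
      focal_plane_distance =
        if (is.null(e$focal_plane_distance)) NA_real_ else e$focal_plane_distance,
      lens_power = if (is.null(e$lens_power)) NA_real_ else e$lens_power,
      exposure = if (is.null(e$exposure)) NA_character_ else e$exposure)
  }
  image_stack(frames, metas)
}
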