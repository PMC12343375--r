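#' Construct a raw angiographic frame series
#'
#' Time-ordered stack of strictly positive detector intensities with
#' acquisition metadata. Intensities must stay positive because both imaging
#' engines work in the log (attenuation) domain.
#'
#' @param frames numeric H x W x T array, all values > 0.
#' @param fps frame rate (frames/s).
#' @param timestamps optional acquisition times (s); default `(0:(T-1))/fps`.
#' @param mask_candidates indices (1-based) of known pre-contrast frames.
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(frames, fps, timestamps = NULL,
                         mask_candidates = integer(0)) {
  if (length(dim(frames)) != 3) stopf("frames must be an H x W x T array")
  if (any(!is.finite(frames)) || any(frames <= 0))
    stopf("all frame intensities must be finite and > 0")
  T_ <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- (seq_len(T_) - 1) / fps
  if (length(timestamps) != T_ || any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing, one per frame")
  mask_candidates <- as.integer(mask_candidates)
  if (length(mask_candidates) &&
      (min(mask_candidates) < 1 || max(mask_candidates) > T_))
    stopf("mask_candidates out of range")
  structure(list(frames = frames, fps = fps, timestamps = timestamps,
                 mask_candidates = mask_candidates),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_series: %d frames of %d x %d @ %g fps (%d mask candidates)\n",
              d[3], d[1], d[2], x$fps, length(x$mask_candidates)))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3]

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a frame series as 16-bit multi-frame TIFF + JSON sidecar
#'
#' Intensities are linearly mapped to the 16-bit range; the mapping and all
#' acquisition metadata (fps, timestamps, mask candidates) go to a JSON
#' sidecar next to the TIFF, so a round-trip preserves values to one
#' 16-bit quantization step.
#'
#' @param series a [frame_series()].
#' @param path output TIFF path (`.tif`); sidecar gets the same stem + `.json`.
#' @param extra named list merged into the sidecar (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, extra = list()) {
  stopifnot(inherits(series, "frame_series"))
  vmin <- min(series$frames); vmax <- max(series$frames)
  scale <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(n_frames(series)), function(t)
    (series$frames[, , t] - vmin) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- c(list(fps = series$fps, timestamps = series$timestamps,
                 mask_candidates = series$mask_candidates,
                 vmin = vmin, vmax = vmax), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame series written by [write_series()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return A [frame_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing metadata sidecar: %s", sp)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("malformed TIFF stack: %s",
                                              conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stopf("empty TIFF stack: %s", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("nonuniform frame shapes in %s", path)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  scale <- if (meta$vmax > meta$vmin) meta$vmax - meta$vmin else 1
  frames <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages))
    frames[, , t] <- meta$vmin + pages[[t]] * scale
  frames <- pmax(frames, .Machine$double.xmin)
  frame_series(frames, fps = meta$fps, timestamps = meta$timestamps,
               mask_candidates = meta$mask_candidates)
}

# class -> 8-bit gray value map for label rasters
LABEL_VALUE_MAP <- c(background = 0L, large_vessel = 50L, small_vessel = 100L,
                     blush = 150L, vein = 200L)

#' Write / read a ground-truth label raster as single-frame 8-bit TIFF
#'
#' Class-to-value map: background 0, large_vessel 50, small_vessel 100,
#' blush 150, vein 200 (8-bit gray levels).
#'
#' @param labels integer label matrix (codes from [PHANTOM_CLASSES]).
#' @param path TIFF path.
#' @return `write_labels`: `path` invisibly; `read_labels`: label matrix.
#' @export
write_labels <- function(labels, path) {
  img <- matrix(0, nrow(labels), ncol(labels))
  for (cl in names(PHANTOM_CLASSES))
    img[labels == PHANTOM_CLASSES[[cl]]] <- LABEL_VALUE_MAP[[cl]] / 255
  tiff::writeTIFF(img, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- tiff::readTIFF(path)
  vals <- round(img * 255)
  labels <- matrix(NA_integer_, nrow(img), ncol(img))
  for (cl in names(LABEL_VALUE_MAP))
    labels[vals == LABEL_VALUE_MAP[[cl]]] <- PHANTOM_CLASSES[[cl]]
  if (any(is.na(labels))) stopf("unknown gray values in label raster")
  labels
}
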