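#' Construct a modality image (DSA or DVA)
#'
#' @param pixels H x W numeric raster of raw (unwindowed) values; vessels
#'   high.
#' @param modality `"DSA"` or `"DVA"`.
#' @param provenance list describing how the image was formed.
#' @return Object of class `modality_image`.
#' @export
modality_image <- function(pixels, modality = c("DSA", "DVA"),
                           provenance = list()) {
  modality <- match.arg(modality)
  if (modality == "DVA" && any(pixels < 0))
    stopf("DVA pixels must be >= 0 (standard deviations)")
  structure(list(pixels = pixels, modality = modality,
                 provenance = provenance, display_window = NULL,
                 windowed = FALSE),
            class = "modality_image")
}

#' @export
print.modality_image <- function(x, ...) {
  cat(sprintf("%s image %d x %d, range [%.4g, %.4g]%s\n", x$modality,
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (x$windowed) " (display-windowed)" else ""))
  invisible(x)
}

#' Select the mask (pre-contrast) frame for subtraction
#'
#' Uses the first metadata mask candidate when available; otherwise returns
#' the frame with the least total attenuation relative to the pixel-wise
#' temporal maximum intensity (the brightest, least opacified frame).
#'
#' @param series a [frame_series()] with >= 2 frames.
#' @return Frame index (1-based).
#' @export
select_mask_frame <- function(series) {
  stopifnot(inherits(series, "frame_series"))
  if (n_frames(series) < 2) stopf("need at least 2 frames")
  if (length(series$mask_candidates)) return(series$mask_candidates[1])
  T_ <- n_frames(series)
  refmax <- series$frames[, , 1]
  for (t in 2:T_) refmax <- pmax(refmax, series$frames[, , t])
  log_ref <- log(refmax)
  scores <- vapply(seq_len(T_), function(t)
    sum(log_ref - log(series$frames[, , t])), numeric(1))
  which.min(scores)
}

#' Compute a digital subtraction angiography (DSA) image
#'
#' Log-domain mask subtraction: `d_t(x) = ln I_mask(x) - ln I_t(x)`, positive
#' where contrast accumulates. The summary image is either the single frame
#' maximizing total positive opacification (`"peak_frame"`, the default) or
#' the pixel-wise maximum over frames (`"max_opacity_projection"`).
#'
#' @param series a motion-corrected [frame_series()].
#' @param mask mask frame index; `NULL` calls [select_mask_frame()].
#' @param summary summary image rule.
#' @param keep_series keep the full subtracted attenuation stack in the
#'   result (`$subtracted`)?
#' @return A [modality_image()]; provenance records the mask, the selected
#'   peak frame and the summary rule.
#' @export
compute_dsa <- function(series, mask = NULL,
                        summary = c("peak_frame", "max_opacity_projection"),
                        keep_series = FALSE) {
  stopifnot(inherits(series, "frame_series"))
  summary <- match.arg(summary)
  T_ <- n_frames(series)
  if (T_ < 2) stopf("mask frame cannot be the only frame")
  if (is.null(mask)) mask <- select_mask_frame(series)
  if (mask < 1 || mask > T_) stopf("mask index out of range")
  log_mask <- log(series$frames[, , mask])
  d <- log(series$frames)
  for (t in seq_len(T_)) d[, , t] <- log_mask - d[, , t]
  scores <- vapply(seq_len(T_), function(t) sum(pmax(d[, , t], 0)), numeric(1))
  peak <- which.max(scores)
  pixels <- if (summary == "peak_frame") d[, , peak] else {
    mx <- d[, , 1]
    for (t in 2:T_) mx <- pmax(mx, d[, , t])
    mx
  }
  img <- modality_image(pixels, "DSA",
                        provenance = list(mask = mask, summary = summary,
                                          peak_frame = peak,
                                          frames_used = seq_len(T_)))
  if (keep_series) img$subtracted <- d
  img
}

#' Compute a digital variance angiography (DVA) image
#'
#' Maps each pixel to the sample standard deviation (denominator N - 1) of
#' its log intensity — the x-ray attenuation up to a constant reference —
#' across the acquisition. No mask frame is involved; by default all frames,
#' including pre-contrast ones, contribute.
#'
#' @param series a motion-corrected [frame_series()].
#' @param frame_subset optional frame indices to restrict to (>= 2 frames).
#' @return A [modality_image()] with non-negative pixels.
#' @export
compute_dva <- function(series, frame_subset = NULL) {
  stopifnot(inherits(series, "frame_series"))
  frames <- series$frames
  if (!is.null(frame_subset)) {
    if (length(frame_subset) < 2) stopf("frame_subset must keep >= 2 frames")
    frames <- frames[, , frame_subset, drop = FALSE]
  }
  T_ <- dim(frames)[3]
  if (T_ < 2) stopf("DVA needs at least 2 frames")
  logI <- log(frames)
  m <- rowMeans(logI, dims = 2)
  ss <- rowSums((logI - as.vector(m))^2, dims = 2)
  pixels <- sqrt(pmax(ss, 0) / (T_ - 1))
  modality_image(pixels, "DVA",
                 provenance = list(frames_used =
                   if (is.null(frame_subset)) seq_len(n_frames(series))
                   else frame_subset))
}

#' Window a modality image for display
#'
#' Linear brightness/contrast adjustment: the `[low_pct, high_pct]` percentile
#' range of the raw pixels is rescaled to `[0, out_max]` and clipped. The
#' result is marked as display-windowed; quantitative CNR operations refuse
#' windowed images and always consume raw pixels.
#'
#' @param image a [modality_image()].
#' @param low_pct,high_pct percentile window, `0 <= low < high <= 100`.
#' @param out_max top of the display range (255 for 8-bit export).
#' @return The windowed [modality_image()].
#' @export
window_image <- function(image, low_pct = 1, high_pct = 99, out_max = 1) {
  stopifnot(inherits(image, "modality_image"))
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stopf("need 0 <= low_pct < high_pct <= 100")
  lo <- quantile7(image$pixels, low_pct / 100)
  hi <- quantile7(image$pixels, high_pct / 100)
  if (hi <= lo) {
    warning("degenerate window (constant image); returning unmodified")
    return(image)
  }
  out <- image
  out$pixels <- pmin(pmax((image$pixels - lo) / (hi - lo), 0), 1) * out_max
  out$display_window <- c(low = lo, high = hi)
  out$windowed <- TRUE
  out$provenance$window <- c(low_pct = low_pct, high_pct = high_pct,
                             out_max = out_max)
  out
}
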