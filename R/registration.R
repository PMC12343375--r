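#' Translate a raster by a (possibly sub-pixel) rigid shift
#'
#' Bilinear interpolation; `out(y, x) = m(y - dy, x - dx)`. Pixels sampling
#' outside the raster are edge-replicated when `fill` is `NULL`, otherwise
#' set to the constant `fill`.
#'
#' @param m numeric matrix.
#' @param dy,dx shift in rows / columns (px, positive moves content down /
#'   right).
#' @param fill constant for out-of-field pixels, or `NULL` to replicate the
#'   frame edge.
#' @return Translated matrix, same dimensions.
#' @export
translate_frame <- function(m, dy, dx, fill = NULL) {
  H <- nrow(m); W <- ncol(m)
  ys <- seq_len(H) - dy
  xs <- seq_len(W) - dx
  y0 <- floor(ys); fy <- ys - y0
  x0 <- floor(xs); fx <- xs - x0
  clampy <- function(i) pmin(pmax(i, 1), H)
  clampx <- function(i) pmin(pmax(i, 1), W)
  y0c <- clampy(y0); y1c <- clampy(y0 + 1)
  x0c <- clampx(x0); x1c <- clampx(x0 + 1)
  out <- m[y0c, x0c, drop = FALSE] * tcrossprod(1 - fy, 1 - fx) +
    m[y1c, x0c, drop = FALSE] * tcrossprod(fy, 1 - fx) +
    m[y0c, x1c, drop = FALSE] * tcrossprod(1 - fy, fx) +
    m[y1c, x1c, drop = FALSE] * tcrossprod(fy, fx)
  if (!is.null(fill)) {
    out[ys < 1 | ys > H, ] <- fill
    out[, xs < 1 | xs > W] <- fill
  }
  out
}

# Evaluate the inverse DFT of `data` on an upsampled local grid
# (matrix-multiply DFT): rows/cols (0:(size-1) - offset) / usf in pixel units.
upsampled_dft <- function(data, size, usf, offset) {
  H <- nrow(data); W <- ncol(data)
  kr <- exp(-2i * pi * outer(seq_len(size) - 1 - offset[1], fftfreq(H, usf)))
  kc <- exp(-2i * pi * outer(seq_len(size) - 1 - offset[2], fftfreq(W, usf)))
  kr %*% data %*% t(kc)
}

#' Estimate the rigid translation between two rasters
#'
#' Spectral cross-correlation: the integer peak of the FFT cross-correlation
#' surface, refined to sub-pixel precision by evaluating the correlation on a
#' locally upsampled DFT grid (default 10x). Both images are mean-subtracted
#' and Hann-tapered first: without the taper, the constant border bands left
#' by rigid motion correlate with each other and bias the peak toward zero.
#' Wrap-around ambiguity is broken toward the smaller shift magnitude.
#'
#' @param moving,ref numeric matrices of equal size.
#' @param upsample sub-pixel upsampling factor (1 = integer precision).
#' @return `c(dy, dx)`: the displacement of `moving` relative to `ref`,
#'   i.e. `moving(y, x) ~ ref(y - dy, x - dx)`.
#' @export
register_translation <- function(moving, ref, upsample = 10) {
  stopifnot(all(dim(moving) == dim(ref)))
  H <- nrow(ref); W <- ncol(ref)
  win <- tcrossprod(0.5 * (1 - cos(2 * pi * seq(0, H - 1) / (H - 1))),
                    0.5 * (1 - cos(2 * pi * seq(0, W - 1) / (W - 1))))
  f_mov <- stats::fft((moving - mean(moving)) * win)
  f_ref <- stats::fft((ref - mean(ref)) * win)
  cp <- f_mov * Conj(f_ref)
  cc <- Re(stats::fft(cp, inverse = TRUE)) / (H * W)
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  shift <- as.numeric(peak)
  if (shift[1] > H / 2) shift[1] <- shift[1] - H
  if (shift[2] > W / 2) shift[2] <- shift[2] - W
  if (upsample > 1) {
    size <- ceiling(upsample * 1.5)
    dftshift <- floor(size / 2)
    offset <- dftshift - shift * upsample
    cc_up <- Conj(upsampled_dft(Conj(cp), size, upsample, offset))
    p <- arrayInd(which.max(abs(cc_up)), dim(cc_up)) - 1L
    shift <- shift + (as.numeric(p) - dftshift) / upsample
  }
  shift
}

#' Estimate per-frame pixel-shift motion against a reference frame
#'
#' Registers the log-intensity of every frame to the reference frame by
#' spectral cross-correlation with sub-pixel refinement. The reference
#' defaults to the most structured frame (largest spatial SD of log
#' intensity), since featureless pre-contrast frames carry no registration
#' signal. Frames with (numerically) zero variance get shift (0, 0) and are
#' flagged.
#'
#' @param series a [frame_series()] with >= 2 frames.
#' @param reference reference frame index; `NULL` selects automatically.
#' @param upsample sub-pixel upsampling factor.
#' @return T x 2 matrix (columns dy, dx); attributes `"reference"` and
#'   `"flagged"` (logical, zero-variance frames).
#' @export
estimate_shifts <- function(series, reference = NULL, upsample = 10) {
  stopifnot(inherits(series, "frame_series"))
  T_ <- n_frames(series)
  if (T_ < 2) stopf("need at least 2 frames to estimate motion")
  logI <- log(series$frames)
  sds <- apply(logI, 3, stats::sd)
  if (is.null(reference)) reference <- which.max(sds)
  shifts <- matrix(0, T_, 2, dimnames = list(NULL, c("dy", "dx")))
  flagged <- sds < 1e-12
  if (flagged[reference])
    warning("reference frame has zero variance; all shifts set to (0,0)")
  else {
    ref <- logI[, , reference]
    for (t in seq_len(T_)) {
      if (t == reference || flagged[t]) next
      shifts[t, ] <- register_translation(logI[, , t], ref, upsample)
    }
  }
  if (any(flagged))
    warning(sprintf("%d zero-variance frame(s) assigned shift (0,0)",
                    sum(flagged)))
  attr(shifts, "reference") <- reference
  attr(shifts, "flagged") <- flagged
  shifts
}

#' Align a frame series by undoing estimated shifts
#'
#' Each frame is translated by the negative of its shift with sub-pixel
#' (bilinear) interpolation; border pixels replicate the frame edge, which
#' keeps intensities strictly positive.
#'
#' @param series a [frame_series()].
#' @param shifts T x 2 matrix as returned by [estimate_shifts()].
#' @return The aligned [frame_series()].
#' @export
align_series <- function(series, shifts) {
  stopifnot(inherits(series, "frame_series"))
  shifts <- as.matrix(shifts)
  d <- dim(series$frames)
  if (nrow(shifts) != d[3] || ncol(shifts) != 2)
    stopf("shifts must be a %d x 2 matrix", d[3])
  if (any(!is.finite(shifts))) stopf("shifts must be finite")
  if (any(abs(shifts[, 1]) >= d[1]) || any(abs(shifts[, 2]) >= d[2]))
    stopf("shift magnitude exceeds raster size")
  out <- series
  for (t in seq_len(d[3])) {
    if (any(shifts[t, ] != 0))
      out$frames[, , t] <- translate_frame(series$frames[, , t],
                                           -shifts[t, 1], -shifts[t, 2],
                                           fill = NULL)
  }
  out
}
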