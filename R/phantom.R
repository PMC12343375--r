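#' Structure class codes used in ground-truth label rasters
#'
#' Integer codes: background 0, large_vessel 1, small_vessel 2, blush 3,
#' vein 4.
#' @export
PHANTOM_CLASSES <- c(background = 0L, large_vessel = 1L, small_vessel = 2L,
                     blush = 3L, vein = 4L)

VASCULAR_CLASSES <- c("large_vessel", "small_vessel", "blush", "vein")

#' Configuration of a synthetic angiographic acquisition
#'
#' Describes one simulated acquisition: raster size, number of frames and
#' frame rate, the anatomical region (which sets the default patient-motion
#' regime), vessel geometry, bolus kinetics, detector noise, and the RNG seed.
#' Identical configuration + seed gives bit-identical phantoms.
#'
#' Bolus kinetics default to fractions of the series length (arrival at
#' ~20%, time-to-peak ~25%, venous delay ~30% of `n_frames`): in practice an
#' angiographic run is filmed until the venous phase completes, so acquisition
#' length tracks the lesion's transit time.
#'
#' @param height_px,width_px raster size in pixels (>= 64).
#' @param n_frames number of frames (>= 2).
#' @param fps frame rate, 2 or 4 frames/s.
#' @param region_profile one of `"upper_limb"`, `"lower_limb"`, `"head_neck"`,
#'   `"chest"`; selects the default motion regime (limbs: none/small jitter;
#'   head/neck: intermittent jitter; chest: respiratory sinusoid + jitter).
#' @param vessel_spec list overriding any of `n_large`, `large_width` (range,
#'   px), `n_small`, `small_width`, `blush_area` (px^2), `vein_width`.
#' @param bolus_spec list overriding any of `arrival` (frame), `time_to_peak`
#'   (frames), `shape` (gamma-variate exponent), `amplitude` (named per-class
#'   peak attenuation, dimensionless).
#' @param venous_delay frames between arterial and venous arrival.
#' @param tissue_spec list overriding `amplitude` and `scale_px` (parallel
#'   vectors: per-component SD of the static soft-tissue/bone attenuation
#'   field and its spatial correlation length in px; all-zero amplitude
#'   disables the field). The default combines a coarse soft-tissue
#'   component with fine bone detail. The static field is what makes
#'   patient motion visible: without it, translating a featureless
#'   background leaves no artifact — and sub-pixel shift estimation needs
#'   its gradient energy.
#' @param photon_flux expected background photon count per pixel per frame
#'   (I0); must be > 0.
#' @param read_noise_sd additive Gaussian detector noise SD (counts).
#' @param photon_noise logical; disable to make [add_noise()] a no-op when
#'   `read_noise_sd` is also 0.
#' @param motion_spec list overriding `pattern` (`"none"`, `"sinusoid"`,
#'   `"jitter"`, `"sinusoid+jitter"`), `amplitude` (px), `period` (frames),
#'   `prob` (per-frame probability that jitter occurs).
#' @param seed integer RNG seed for all stochastic stages.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height_px = 512, width_px = 512, n_frames = 15,
                           fps = 2,
                           region_profile = c("lower_limb", "upper_limb",
                                              "head_neck", "chest"),
                           vessel_spec = list(), bolus_spec = list(),
                           venous_delay = NULL, tissue_spec = list(),
                           photon_flux = 2000, read_noise_sd = 2,
                           photon_noise = TRUE,
                           motion_spec = list(), seed = 1L) {
  region_profile <- match.arg(region_profile)
  if (n_frames < 2) stopf("n_frames must be >= 2 (got %s)", n_frames)
  if (!fps %in% c(2, 4)) stopf("fps must be 2 or 4 (got %s)", fps)
  if (height_px < 64 || width_px < 64) stopf("raster must be at least 64x64")
  if (photon_flux <= 0) stopf("photon_flux must be > 0")
  if (read_noise_sd < 0) stopf("read_noise_sd must be >= 0")

  vs <- utils::modifyList(list(
    n_large = 2L, large_width = c(8, 20),
    n_small = 3L, small_width = c(3, 4),
    blush_area = 1500, vein_width = c(5, 9)
  ), vessel_spec)
  maxw <- max(vs$large_width, vs$small_width, vs$vein_width)
  if (maxw >= min(height_px, width_px) / 4)
    stopf("vessel widths must be < min(height, width)/4")

  bs <- utils::modifyList(list(
    arrival = max(2, round(0.2 * n_frames)),
    time_to_peak = max(2, round(0.25 * n_frames)),
    shape = 2,
    amplitude = c(large_vessel = 0.8, small_vessel = 0.45,
                  blush = 0.18, vein = 0.5)
  ), bolus_spec)
  if (bs$time_to_peak <= 0 || bs$shape <= 0)
    stopf("bolus time_to_peak and shape must be > 0")
  if (any(bs$amplitude < 0)) stopf("bolus amplitudes must be >= 0")
  if (is.null(venous_delay)) venous_delay <- max(2, round(0.3 * n_frames))

  ts <- utils::modifyList(list(amplitude = c(0.25, 0.2),
                               scale_px = c(30, 5)), tissue_spec)
  if (length(ts$amplitude) != length(ts$scale_px))
    stopf("tissue amplitude and scale_px must have equal length")
  if (any(ts$amplitude < 0) || any(ts$scale_px <= 0))
    stopf("tissue amplitudes must be >= 0 and scales > 0")

  default_motion <- switch(region_profile,
    upper_limb = list(pattern = "none", amplitude = 0, period = 8, prob = 1),
    lower_limb = list(pattern = "jitter", amplitude = 0.4, period = 8,
                      prob = 0.3),
    head_neck  = list(pattern = "jitter", amplitude = 1.5, period = 8,
                      prob = 0.5),
    chest      = list(pattern = "sinusoid+jitter", amplitude = 2.5,
                      period = 8, prob = 0.4)
  )
  ms <- utils::modifyList(default_motion, motion_spec)
  ms$pattern <- match.arg(ms$pattern,
                          c("none", "sinusoid", "jitter", "sinusoid+jitter"))
  if (ms$amplitude < 0) stopf("motion amplitude must be >= 0")
  if (ms$amplitude >= min(height_px, width_px) / 8)
    stopf("motion amplitude must be < min(height, width)/8")

  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    n_frames = as.integer(n_frames), fps = fps,
    region_profile = region_profile,
    vessel_spec = vs, bolus_spec = bs,
    venous_delay = venous_delay, tissue_spec = ts,
    photon_flux = photon_flux, read_noise_sd = read_noise_sd,
    photon_noise = isTRUE(photon_noise),
    motion_spec = ms, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Mark pixels within halfw of the segment p1--p2 that are still background.
rasterize_segment <- function(labels, yy, xx, p1, p2, halfw, class_id) {
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) return(labels)
  t <- ((yy - p1[1]) * v[1] + (xx - p1[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (yy - (p1[1] + t * v[1]))^2 + (xx - (p1[2] + t * v[2]))^2
  hit <- d2 <= halfw^2 & labels == 0L
  labels[hit] <- class_id
  labels
}

#' Generate a random vessel-tree label raster
#'
#' Draws large vessels, a draining vein, small vessels, and a tissue-blush
#' patch as mutually exclusive classes on a background raster. Structures are
#' placed in priority order (large, vein, small, blush); pixels already
#' claimed are never overwritten, so classes stay disjoint. Retries with a
#' perturbed layout until every configured class is present.
#'
#' @param config a [phantom_config()].
#' @return Integer H x W matrix with codes from [PHANTOM_CLASSES].
#' @export
generate_vessel_tree <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height_px; W <- config$width_px
  vs <- config$vessel_spec
  yy <- matrix(rep(seq_len(H), W), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)

  wanted <- c(
    large_vessel = vs$n_large > 0,
    vein = TRUE,
    small_vessel = vs$n_small > 0,
    blush = vs$blush_area > 0
  )

  for (attempt in 1:8) {
    labels <- with_seed(derive_seed(config$seed, "geometry", attempt), {
      lab <- matrix(0L, H, W)
      diag_len <- sqrt(H^2 + W^2)
      draw_line <- function(lab, width_range, class_id) {
        ctr <- c(stats::runif(1, 0.25 * H, 0.75 * H),
                 stats::runif(1, 0.25 * W, 0.75 * W))
        ang <- stats::runif(1, 0, pi)
        dir <- c(sin(ang), cos(ang))
        halfw <- stats::runif(1, width_range[1], width_range[2]) / 2
        rasterize_segment(lab, yy, xx, ctr - diag_len * dir,
                          ctr + diag_len * dir, halfw, class_id)
      }
      for (i in seq_len(vs$n_large))
        lab <- draw_line(lab, vs$large_width, PHANTOM_CLASSES[["large_vessel"]])
      lab <- draw_line(lab, vs$vein_width, PHANTOM_CLASSES[["vein"]])
      for (i in seq_len(vs$n_small))
        lab <- draw_line(lab, vs$small_width, PHANTOM_CLASSES[["small_vessel"]])
      if (vs$blush_area > 0) {
        ratio <- stats::runif(1, 0.6, 1.6)
        b <- sqrt(vs$blush_area / (pi * ratio)); a <- ratio * b
        ctr <- c(stats::runif(1, 0.3 * H, 0.7 * H),
                 stats::runif(1, 0.3 * W, 0.7 * W))
        th <- stats::runif(1, 0, pi)
        dy <- yy - ctr[1]; dx <- xx - ctr[2]
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        hit <- (u / a)^2 + (v / b)^2 <= 1 & lab == 0L
        lab[hit] <- PHANTOM_CLASSES[["blush"]]
      }
      lab
    })
    present <- vapply(names(wanted)[wanted], function(cl)
      any(labels == PHANTOM_CLASSES[[cl]]), logical(1))
    if (all(present)) return(labels)
  }
  stopf("could not fit all configured structure classes in a %dx%d raster",
        H, W)
}

# Static soft-tissue/bone attenuation: a sum of Gaussian-filtered white-noise
# components (one per amplitude/scale pair; by default a coarse soft-tissue
# component plus fine bone/trabecular detail), shifted to be non-negative.
# The fine component matters: sub-pixel shift estimation needs gradient
# energy, exactly as pixel-shift correction on clinical images relies on
# bone edges.
generate_tissue_field <- function(config) {
  ts <- config$tissue_spec
  H <- config$height_px; W <- config$width_px
  if (all(ts$amplitude == 0)) return(matrix(0, H, W))
  with_seed(derive_seed(config$seed, "tissue"), {
    field <- matrix(0, H, W)
    for (i in seq_along(ts$amplitude)) {
      if (ts$amplitude[i] == 0) next
      noise <- matrix(stats::rnorm(H * W), H, W)
      s <- ts$scale_px[i] / 4  # kernel SD; full structure scale ~ scale_px
      ky <- stats::dnorm(c(0:(H %/% 2), -((H - H %/% 2 - 1):1)), sd = s)
      kx <- stats::dnorm(c(0:(W %/% 2), -((W - W %/% 2 - 1):1)), sd = s)
      kern <- outer(ky, kx)
      sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                          inverse = TRUE)) / (H * W)
      field <- field + sm / stats::sd(sm) * ts$amplitude[i]
    }
    field - min(field)
  })
}

#' Gamma-variate bolus attenuation curve
#'
#' Standard parametric model of a contrast bolus: zero before `arrival`,
#' rising to exactly `amplitude` at `arrival + time_to_peak`, then decaying.
#' `a(t) = A * tau^shape * exp(shape * (1 - tau))` with
#' `tau = (t - arrival) / time_to_peak`.
#'
#' @param t frame index (vectorized; same units as `arrival`).
#' @param arrival bolus arrival frame.
#' @param time_to_peak frames from arrival to peak (> 0).
#' @param shape gamma-variate exponent (> 0).
#' @param amplitude peak attenuation (>= 0).
#' @return Attenuation value(s), dimensionless.
#' @export
gamma_variate_curve <- function(t, arrival, time_to_peak, shape, amplitude) {
  if (time_to_peak <= 0 || shape <= 0)
    stopf("time_to_peak and shape must be > 0")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  tau <- (t - arrival) / time_to_peak
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- amplitude * tau[pos]^shape * exp(shape * (1 - tau[pos]))
  out
}

#' Ground truth of a phantom acquisition
#'
#' Combines the label raster with per-class attenuation time-curves, the
#' (initially zero) per-frame rigid shifts, and the peak-opacification frame.
#'
#' @param config a [phantom_config()].
#' @param labels optional precomputed label raster.
#' @return Object of class `ground_truth` with elements `labels`,
#'   `attenuation_curves` (class x frame matrix), `static_attenuation`
#'   (H x W field of motionless anatomy), `true_shifts` (T x 2, columns dy,
#'   dx), `peak_frame`.
#' @export
phantom_ground_truth <- function(config, labels = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(labels)) labels <- generate_vessel_tree(config)
  bs <- config$bolus_spec
  t <- seq_len(config$n_frames)
  curves <- rbind(
    background = numeric(config$n_frames),
    large_vessel = gamma_variate_curve(t, bs$arrival, bs$time_to_peak,
                                       bs$shape, bs$amplitude[["large_vessel"]]),
    small_vessel = gamma_variate_curve(t, bs$arrival, bs$time_to_peak,
                                       bs$shape, bs$amplitude[["small_vessel"]]),
    blush = gamma_variate_curve(t, bs$arrival, bs$time_to_peak,
                                bs$shape, bs$amplitude[["blush"]]),
    vein = gamma_variate_curve(t, bs$arrival + config$venous_delay,
                               bs$time_to_peak, bs$shape,
                               bs$amplitude[["vein"]])
  )
  structure(list(
    labels = labels,
    attenuation_curves = curves,
    static_attenuation = generate_tissue_field(config),
    true_shifts = matrix(0, config$n_frames, 2,
                         dimnames = list(NULL, c("dy", "dx"))),
    peak_frame = which.max(curves["large_vessel", ])
  ), class = "ground_truth")
}

#' Render a noise-free frame series from ground truth
#'
#' Beer-Lambert detector model: expected intensity
#' `I_t(x) = I0 * exp(-a_t(x))`, where `a_t(x)` is the static anatomy field
#' plus the attenuation curve of the structure covering pixel x at frame t.
#' With the tissue field disabled, frames before bolus arrival equal I0
#' everywhere; the pre-arrival frames become the mask candidates.
#'
#' @param truth a [phantom_ground_truth()].
#' @param config the matching [phantom_config()].
#' @return A [frame_series()].
#' @export
render_series <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "phantom_config"))
  H <- config$height_px; W <- config$width_px; T_ <- config$n_frames
  if (ncol(truth$attenuation_curves) < T_)
    stopf("attenuation curves not defined for all %d frames", T_)
  frames <- array(0, dim = c(H, W, T_))
  class_idx <- lapply(VASCULAR_CLASSES, function(cl)
    which(truth$labels == PHANTOM_CLASSES[[cl]]))
  names(class_idx) <- VASCULAR_CLASSES
  static <- truth$static_attenuation
  if (is.null(static)) static <- matrix(0, H, W)
  for (t in seq_len(T_)) {
    amap <- static
    for (cl in VASCULAR_CLASSES) {
      a <- truth$attenuation_curves[cl, t]
      if (a != 0) amap[class_idx[[cl]]] <- amap[class_idx[[cl]]] + a
    }
    frames[, , t] <- config$photon_flux * exp(-amap)
  }
  if (any(frames <= 0)) stopf("rendered expected intensity <= 0")
  mask_candidates <- which(colSums(truth$attenuation_curves) == 0)
  frame_series(frames, fps = config$fps, mask_candidates = mask_candidates)
}

#' Add Poisson photon noise and Gaussian read noise
#'
#' Draws each pixel as `Poisson(I) + Normal(0, read_noise_sd)` and clamps at
#' 1 count so logarithms stay defined; the expected value equals the
#' noise-free intensity. With `photon_noise = FALSE` and `read_noise_sd = 0`
#' the series is returned unchanged.
#'
#' @param series a [frame_series()] of expected intensities.
#' @param config the [phantom_config()] (noise parameters, seed).
#' @param seed optional override of the derived noise seed.
#' @return A [frame_series()]; attribute `"n_clamped"` counts clamped pixels.
#' @export
add_noise <- function(series, config, seed = NULL) {
  stopifnot(inherits(series, "frame_series"), inherits(config, "phantom_config"))
  if (!config$photon_noise && config$read_noise_sd == 0) return(series)
  if (is.null(seed)) seed <- derive_seed(config$seed, "noise")
  frames <- series$frames
  n <- length(frames)
  noisy <- with_seed(seed, {
    out <- if (config$photon_noise)
      stats::rpois(n, lambda = as.vector(frames)) else as.vector(frames)
    if (config$read_noise_sd > 0)
      out <- out + stats::rnorm(n, 0, config$read_noise_sd)
    out
  })
  n_clamped <- sum(noisy < 1)
  noisy <- pmax(noisy, 1)
  out <- series
  out$frames <- array(noisy, dim = dim(frames))
  attr(out, "n_clamped") <- n_clamped
  out
}

# Per-frame rigid shifts for a motion pattern; frame 1 (the canonical mask
# frame) is always (0, 0).
motion_shifts <- function(config, seed = NULL) {
  ms <- config$motion_spec
  T_ <- config$n_frames
  shifts <- matrix(0, T_, 2, dimnames = list(NULL, c("dy", "dx")))
  if (ms$pattern == "none" || ms$amplitude == 0) return(shifts)
  t0 <- seq_len(T_) - 1
  if (ms$pattern %in% c("sinusoid", "sinusoid+jitter")) {
    shifts[, 1] <- ms$amplitude * sin(2 * pi * t0 / ms$period)
    shifts[, 2] <- 0.4 * ms$amplitude * sin(2 * pi * t0 / ms$period + pi / 3)
  }
  if (ms$pattern %in% c("jitter", "sinusoid+jitter")) {
    if (is.null(seed)) seed <- derive_seed(config$seed, "motion")
    amp <- if (ms$pattern == "jitter") ms$amplitude else 0.4 * ms$amplitude
    jit <- with_seed(seed, {
      on <- stats::runif(T_) < ms$prob
      cbind(stats::runif(T_, -amp, amp), stats::runif(T_, -amp, amp)) * on
    })
    shifts <- shifts + jit
  }
  shifts[1, ] <- 0
  shifts
}

#' Apply rigid patient motion to a frame series
#'
#' Translates each frame by the region profile's motion pattern (recorded to
#' sub-pixel precision in the ground truth). Out-of-field pixels are filled
#' with the background flux I0. The first frame — the canonical mask frame —
#' is never displaced.
#'
#' @param series a [frame_series()] (noise-free; noise is added after motion).
#' @param truth the matching [phantom_ground_truth()]; its `true_shifts` are
#'   replaced.
#' @param config the [phantom_config()].
#' @param seed optional override of the derived motion seed.
#' @return List with elements `series` (moved [frame_series()]) and `truth`
#'   (updated `true_shifts`).
#' @export
apply_motion <- function(series, truth, config, seed = NULL) {
  stopifnot(inherits(series, "frame_series"), inherits(truth, "ground_truth"))
  shifts <- motion_shifts(config, seed)
  out <- series
  if (any(shifts != 0)) {
    for (t in seq_len(config$n_frames)) {
      if (any(shifts[t, ] != 0))
        out$frames[, , t] <- translate_frame(series$frames[, , t],
                                             shifts[t, 1], shifts[t, 2],
                                             fill = config$photon_flux)
    }
  }
  truth$true_shifts <- shifts
  list(series = out, truth = truth)
}

#' Simulate one full acquisition
#'
#' Convenience composition: vessel tree, bolus rendering, patient motion,
#' detector noise.
#'
#' @param config a [phantom_config()].
#' @return List with `series` (the raw noisy [frame_series()]) and `truth`.
#' @export
simulate_acquisition <- function(config) {
  truth <- phantom_ground_truth(config)
  clean <- render_series(truth, config)
  moved <- apply_motion(clean, truth, config)
  list(series = add_noise(moved$series, config), truth = moved$truth)
}
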