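REGIONS <- c("upper_limb", "lower_limb", "head_neck", "chest")

#' Configuration of a full simulated comparison experiment
#'
#' Describes a complete desk-scale replica of a DVA-versus-DSA comparison:
#' how many acquisitions to simulate per anatomical region, the phantom
#' template, the ROI policy, the synthetic-rater policy, and a master seed
#' from which every downstream seed is derived (via [derive_seed()], so any
#' acquisition can be re-run in isolation).
#'
#' Acquisition frame counts are drawn per acquisition from a shifted
#' negative-binomial on 5..53 with mean 15 frames, and the frame rate from
#' {2, 4} fps, matching typical angiographic runs.
#'
#' @param region_counts named integer vector of acquisitions per region;
#'   the default mirrors a 132-acquisition series (14/56/23/39).
#' @param height_px,width_px phantom raster size for the experiment.
#' @param n_pairs ROI pairs per acquisition.
#' @param motion_correction apply pixel-shift motion correction?
#' @param rater_m,rater_gain,rater_noise_sd synthetic-rater policy for the
#'   concordance table.
#' @param seed master seed.
#' @param scale convenience multiplier applied to `region_counts`
#'   (`ceiling(counts * scale)`), for scaled-down runs.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(region_counts = c(upper_limb = 14,
                                                lower_limb = 56,
                                                head_neck = 23,
                                                chest = 39),
                              height_px = 256, width_px = 256,
                              n_pairs = 25, motion_correction = TRUE,
                              rater_m = 5, rater_gain = 1,
                              rater_noise_sd = 1.5,
                              seed = 1L, scale = 1) {
  region_counts <- ceiling(region_counts * scale)
  if (any(region_counts < 1)) stopf("all region counts must be >= 1")
  if (!all(names(region_counts) %in% REGIONS))
    stopf("region names must be among: %s", paste(REGIONS, collapse = ", "))
  structure(list(region_counts = region_counts,
                 height_px = height_px, width_px = width_px,
                 n_pairs = n_pairs,
                 motion_correction = isTRUE(motion_correction),
                 rater_m = rater_m, rater_gain = rater_gain,
                 rater_noise_sd = rater_noise_sd,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Acquisition length: 5..53 frames, mean ~15 (shifted negative binomial).
sample_n_frames <- function(seed) {
  with_seed(seed, min(5L + stats::rnbinom(1, size = 3, mu = 10), 53L))
}

sample_fps <- function(seed) with_seed(seed, sample(c(2, 4), 1))

#' Simulate, image and measure one acquisition
#'
#' One pass of the measurement chain: phantom generation, patient motion,
#' detector noise, optional pixel-shift correction, DSA and DVA formation,
#' automatic ROI placement (carried from ground-truth coordinates onto the
#' aligned images via the reference frame's true shift), and per-pair CNR on
#' both modality images.
#'
#' @param config a [phantom_config()].
#' @param n_pairs ROI pairs to place.
#' @param motion_correction apply pixel-shift correction?
#' @param acq_id acquisition identifier carried into the output rows.
#' @return Data frame: one row per ROI pair with CNR of both modalities and
#'   their ratio.
#' @export
measure_acquisition <- function(config, n_pairs = 25,
                                motion_correction = TRUE, acq_id = 1L) {
  sim <- simulate_acquisition(config)
  series <- sim$series
  roi_shift <- c(0, 0)
  if (motion_correction && config$motion_spec$pattern != "none") {
    shifts <- suppressWarnings(estimate_shifts(series))
    series <- align_series(series, shifts)
    # aligned content sits at the reference frame's displaced position
    roi_shift <- sim$truth$true_shifts[attr(shifts, "reference"), ]
  }
  dsa <- compute_dsa(series)
  dva <- compute_dva(series)
  pairs <- suppressWarnings(
    auto_place_rois(sim$truth, n_pairs,
                    seed = derive_seed(config$seed, "roi")))
  if (any(roi_shift != 0))
    pairs <- align_rois(pairs, roi_shift, dim(dsa$pixels))
  rows <- lapply(pairs, function(p) {
    rec <- tryCatch({
      pc <- compute_ratio(compute_cnr(dsa, p), compute_cnr(dva, p))
      data.frame(acq_id = acq_id, region = config$region_profile,
                 pair_id = p$id, class = p$structure_class,
                 n_frames = config$n_frames, fps = config$fps,
                 cnr_dsa = pc$cnr_dsa, cnr_dva = pc$cnr_dva,
                 ratio = pc$ratio, flagged = pc$flagged)
    }, error = function(e) NULL)
    rec
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Run the full simulated DVA-versus-DSA experiment
#'
#' Generates region-specific phantom acquisitions, forms both modality
#' images, measures paired CNR, and assembles a report: per-region and
#' overall CNR summaries (median, IQR, Wilcoxon signed-rank p on the paired
#' CNR differences), the CNR ratio summary, and a synthetic-rater
#' concordance (Kendall's W) table per structure class. Deterministic under
#' the master seed.
#'
#' @param config an [experiment_config()].
#' @return Object of class `experiment_report`: `per_pair` (data frame),
#'   `summary` (per-region + overall), `wilcoxon` (per-region + overall),
#'   `rater_w`, `acq_meta`, `config`, `version`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  per_pair <- list()
  acq_meta <- list()
  acq_id <- 0L
  for (region in names(config$region_counts)) {
    for (i in seq_len(config$region_counts[[region]])) {
      acq_id <- acq_id + 1L
      acq_seed <- derive_seed(config$seed, region, i)
      nf <- sample_n_frames(derive_seed(acq_seed, "n_frames"))
      fps <- sample_fps(derive_seed(acq_seed, "fps"))
      pc <- phantom_config(height_px = config$height_px,
                           width_px = config$width_px,
                           n_frames = nf, fps = fps,
                           region_profile = region, seed = acq_seed)
      rows <- tryCatch(
        measure_acquisition(pc, config$n_pairs,
                            config$motion_correction, acq_id),
        error = function(e) stopf("acquisition %d (%s #%d) failed: %s",
                                  acq_id, region, i, conditionMessage(e)))
      per_pair[[acq_id]] <- rows
      acq_meta[[acq_id]] <- data.frame(acq_id = acq_id, region = region,
                                       n_frames = nf, fps = fps,
                                       n_pairs = nrow(rows))
    }
  }
  per_pair <- do.call(rbind, per_pair)
  acq_meta <- do.call(rbind, acq_meta)

  overall <- summarize_cnr(per_pair)
  by_region <- summarize_cnr(per_pair, "region")
  summary_tab <- rbind(overall, by_region)

  wtest <- function(r) {
    res <- wilcoxon_signed_rank(r$cnr_dva - r$cnr_dsa)
    data.frame(n = res$n, W = res$statistic, p = res$p_value)
  }
  wil <- rbind(cbind(group = "overall", wtest(per_pair)),
               do.call(rbind, lapply(split(per_pair, per_pair$region),
                                     function(r)
                                       cbind(group = r$region[1], wtest(r)))))
  rownames(wil) <- NULL

  # synthetic raters: per class, one item per acquisition having that class;
  # the true quality difference is the standardized log median CNR ratio
  rater_rows <- lapply(VASCULAR_CLASSES, function(cl) {
    sub <- per_pair[per_pair$class == cl & !per_pair$flagged &
                      !is.na(per_pair$ratio) & per_pair$ratio > 0, ]
    if (nrow(sub) == 0) return(NULL)
    med <- vapply(split(sub$ratio, sub$acq_id), stats::median, numeric(1))
    if (length(med) < 3) return(NULL)
    dq <- as.numeric(scale(log(med)))
    ratings <- likert_rater_sim(dq, m = config$rater_m,
                                gain = config$rater_gain,
                                noise_sd = config$rater_noise_sd,
                                seed = derive_seed(config$seed, "raters", cl))
    res <- kendalls_w(ratings)
    data.frame(class = cl, k_items = res$n, W = res$statistic,
               p = res$p_value, band = res$aux$band)
  })
  rater_w <- do.call(rbind, rater_rows[!vapply(rater_rows, is.null,
                                               logical(1))])
  rownames(rater_w) <- NULL

  structure(list(per_pair = per_pair, summary = summary_tab,
                 wilcoxon = wil, rater_w = rater_w, acq_meta = acq_meta,
                 config = config,
                 version = as.character(utils::packageVersion("varangio"))),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Simulated DVA vs DSA experiment: %d acquisitions, %d ROI pairs\n",
              nrow(x$acq_meta), nrow(x$per_pair)))
  cat("\nCNR summary (median [IQR]):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s n=%4d  DSA %6.2f [%.2f-%.2f]  DVA %6.2f [%.2f-%.2f]  ratio %5.2f [%.2f-%.2f]\n",
                s$group[i], s$n[i],
                s$cnr_dsa_median[i], s$cnr_dsa_q25[i], s$cnr_dsa_q75[i],
                s$cnr_dva_median[i], s$cnr_dva_q25[i], s$cnr_dva_q75[i],
                s$ratio_median[i], s$ratio_q25[i], s$ratio_q75[i]))
  cat("\nWilcoxon signed-rank (CNR_DVA - CNR_DSA):\n")
  for (i in seq_len(nrow(x$wilcoxon)))
    cat(sprintf("  %-11s n=%4d  p %s\n", x$wilcoxon$group[i],
                x$wilcoxon$n[i], format.pval(x$wilcoxon$p[i], digits = 3)))
  if (!is.null(x$rater_w) && nrow(x$rater_w)) {
    cat("\nSynthetic-rater concordance (Kendall's W):\n")
    for (i in seq_len(nrow(x$rater_w)))
      cat(sprintf("  %-13s W = %.3f (%s), p = %s\n", x$rater_w$class[i],
                  x$rater_w$W[i], x$rater_w$band[i],
                  format.pval(x$rater_w$p[i], digits = 3)))
  }
  invisible(x)
}

#' Box-plot figures for an experiment report
#'
#' CNR by region and modality, and CNR ratio by region, as ggplot2 box
#' plots (one facet per non-empty region), optionally written as PNG files.
#'
#' @param report an [run_experiment()] report.
#' @param dir output directory for PNG files, or `NULL` to skip writing.
#' @return Named list of ggplot objects (`cnr`, `ratio`), invisibly when
#'   writing files.
#' @export
make_figures <- function(report, dir = NULL) {
  stopifnot(inherits(report, "experiment_report"))
  pp <- report$per_pair
  if (nrow(pp) == 0) stopf("empty report")
  long <- rbind(data.frame(region = pp$region, modality = "DSA",
                           cnr = pp$cnr_dsa),
                data.frame(region = pp$region, modality = "DVA",
                           cnr = pp$cnr_dva))
  fig_cnr <- ggplot2::ggplot(long, ggplot2::aes(x = modality, y = cnr, fill = modality)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(y = "CNR", x = NULL,
                  title = "Paired CNR by region and modality") +
    ggplot2::theme_bw() + ggplot2::theme(legend.position = "none")
  rat <- pp[!pp$flagged & !is.na(pp$ratio), ]
  fig_ratio <- ggplot2::ggplot(rat, ggplot2::aes(x = region, y = ratio)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = expression(CNR[DVA] / CNR[DSA]), x = NULL,
                  title = "CNR ratio by region") +
    ggplot2::theme_bw()
  figs <- list(cnr = fig_cnr, ratio = fig_ratio)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(figs))
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), figs[[nm]],
                      width = 7, height = 5, dpi = 120)
    return(invisible(figs))
  }
  figs
}

#' Run the package's property-check battery
#'
#' One command executing the cross-module correctness properties against
#' built-in oracles: the DVA naive-loop equivalence, the closed-form step
#' limit (with denominator mutation sensitivity), the rendering inverse, CNR
#' against a brute-force loop, Wilcoxon against full sign enumeration,
#' Kendall's W worked examples, and rigid-shift recovery.
#'
#' @param seed RNG seed for the randomized checks.
#' @return Data frame with columns `check`, `pass`, `detail`; attribute
#'   `"ok"` is TRUE when every check passed.
#' @export
validate_suite <- function(seed = 1L) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name,
                                                 pass = pass, detail = detail)
  }

  # DVA equals a naive per-pixel two-pass SD loop
  err <- with_seed(derive_seed(seed, "dva"), {
    worst <- 0
    for (i in 1:20) {
      fr <- array(exp(stats::rnorm(5 * 4 * 4)), c(4, 4, 5))
      s <- frame_series(fr, fps = 2)
      got <- compute_dva(s)$pixels
      want <- matrix(0, 4, 4)
      for (y in 1:4) for (x in 1:4) want[y, x] <- stats::sd(log(fr[y, x, ]))
      worst <- max(worst, max(abs(got - want) / pmax(abs(want), 1e-300)))
    }
    worst
  })
  add("dva_oracle_equivalence", err <= 1e-10, sprintf("rel err %.3g", err))

  # closed-form step limit + denominator mutation sensitivity
  att <- c(rep(1, 5), rep(0, 10))
  fr <- array(rep(1000 * exp(-att), each = 9), c(3, 3, 15))
  v <- compute_dva(frame_series(fr, fps = 2))$pixels[1, 1]
  expected <- sqrt(50 / 210)
  mutated <- sqrt(50 / 210 * (14 / 15))  # what a denominator-N DVA would give
  add("dva_step_closed_form",
      abs(v - expected) <= 1e-9 && abs(v - mutated) > 1e-3,
      sprintf("value %.6f", v))

  # rendering inverse
  cfg <- phantom_config(128, 128, n_frames = 10, seed = derive_seed(seed, "r"))
  truth <- phantom_ground_truth(cfg)
  series <- render_series(truth, cfg)
  t_pk <- truth$peak_frame
  a_rec <- -log(series$frames[, , t_pk] / cfg$photon_flux)
  lv <- truth$labels == PHANTOM_CLASSES[["large_vessel"]]
  a_want <- truth$static_attenuation[lv] +
    truth$attenuation_curves["large_vessel", t_pk]
  add("rendering_inverse", max(abs(a_rec[lv] - a_want)) < 1e-12)

  # CNR brute force
  ok <- with_seed(derive_seed(seed, "cnr"), {
    img <- modality_image(matrix(stats::rnorm(400), 20), "DSA")
    p <- roi_pair(roi(c(8, 8), 1.5), roi(c(14, 14), 1.5), "large_vessel")
    rec <- compute_cnr(img, p)
    v <- img$pixels[roi_pixels(p$vascular, c(20, 20))]
    b <- img$pixels[roi_pixels(p$background, c(20, 20))]
    mb <- sum(b) / length(b)
    sb <- sqrt(sum((b - mb)^2) / (length(b) - 1))
    abs(rec$cnr - (sum(v) / length(v) - mb) / sb) < 1e-12
  })
  add("cnr_brute_force", ok)

  # Wilcoxon vs full 2^n enumeration
  ok <- with_seed(derive_seed(seed, "wil"), {
    all_ok <- TRUE
    for (i in 1:5) {
      d <- stats::rnorm(8)
      got <- wilcoxon_signed_rank(d)$p_value
      r <- rank(abs(d)); n <- length(d)
      ws <- vapply(0:(2^n - 1), function(mask)
        sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]), numeric(1))
      W <- sum(r[d > 0])
      p_ref <- min(1, 2 * min(mean(ws >= W), mean(ws <= W)))
      if (abs(got - p_ref) > 1e-12) all_ok <- FALSE
    }
    all_ok
  })
  add("wilcoxon_exact_enumeration", ok)

  # Kendall's W worked examples
  w1 <- kendalls_w(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))$statistic
  w2 <- kendalls_w(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$statistic
  add("kendalls_w_examples", abs(w1 - 1 / 9) < 1e-12 && abs(w2 - 1) < 1e-12)

  # rigid-shift recovery
  ok <- with_seed(derive_seed(seed, "reg"), {
    base <- matrix(stats::rnorm(128 * 128), 128)
    sm <- stats::fft(stats::fft(base) *
                       stats::fft(outer(stats::dnorm(-63:64 / 4),
                                        stats::dnorm(-63:64 / 4))),
                     inverse = TRUE)
    sm <- Re(sm) / length(sm)
    mv <- translate_frame(sm, 2.3, -1.7)
    est <- register_translation(mv, sm)
    max(abs(est - c(2.3, -1.7))) <= 0.25
  })
  add("shift_recovery", ok)

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}
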