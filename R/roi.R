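#' Circular region of interest
#'
#' A circle on the raster; its pixel set is every pixel whose (integer)
#' center lies within `radius` of the ROI center.
#'
#' @param center numeric `c(row, col)` (1-based pixel coordinates).
#' @param radius radius in px (>= 1).
#' @return Object of class `roi`.
#' @export
roi <- function(center, radius) {
  if (radius < 1) stopf("ROI radius must be >= 1 px")
  structure(list(center = as.numeric(center), radius = radius), class = "roi")
}

#' Pixel set of an ROI
#'
#' @param r an [roi()].
#' @param dim raster dimensions `c(H, W)`.
#' @return Integer matrix with columns `row`, `col`; errors if any pixel
#'   falls outside the raster or the set has < 3 pixels.
#' @export
roi_pixels <- function(r, dim) {
  cy <- r$center[1]; cx <- r$center[2]
  rows <- seq(floor(cy - r$radius), ceiling(cy + r$radius))
  cols <- seq(floor(cx - r$radius), ceiling(cx + r$radius))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - cy)^2 + (grid$col - cx)^2 <= r$radius^2
  px <- as.matrix(grid[keep, , drop = FALSE])
  if (nrow(px) < 3) stopf("ROI pixel set has fewer than 3 pixels")
  if (min(px) < 1 || max(px[, 1]) > dim[1] || max(px[, 2]) > dim[2])
    stopf("ROI extends outside the raster")
  px
}

#' Vascular / background ROI pair
#'
#' @param vascular,background [roi()]s; their pixel sets must be disjoint.
#' @param structure_class one of `"large_vessel"`, `"small_vessel"`,
#'   `"blush"`, `"vein"`.
#' @param region_profile anatomical region label (optional).
#' @param id pair identifier.
#' @param dim raster dimensions used to validate disjointness.
#' @return Object of class `roi_pair`.
#' @export
roi_pair <- function(vascular, background, structure_class,
                     region_profile = NA_character_, id = 1L,
                     dim = NULL) {
  structure_class <- match.arg(structure_class, VASCULAR_CLASSES)
  if (!is.null(dim)) {
    pv <- roi_pixels(vascular, dim); pb <- roi_pixels(background, dim)
    key <- function(p) paste(p[, 1], p[, 2])
    if (length(intersect(key(pv), key(pb))))
      stopf("vascular and background pixel sets overlap (pair %s)", id)
  }
  structure(list(vascular = vascular, background = background,
                 structure_class = structure_class,
                 region_profile = region_profile, id = id),
            class = "roi_pair")
}

# disc offsets around an integer center for a given radius
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

#' Automatically place ROI pairs using ground-truth labels
#'
#' Emulates manual ROI selection: vascular ROIs lie entirely on pixels of
#' their structure class, background ROIs entirely on background, the
#' background center sits within `[d_min, d_max]` of the vascular center
#' ("adjacent"), and pairs never overlap each other. Classes are assigned
#' round-robin over the classes present. When geometry cannot fit all
#' requested pairs, the shortfall is reported explicitly via the
#' `"shortfall"` attribute and a warning — never silently.
#'
#' @param truth a [phantom_ground_truth()].
#' @param n_pairs number of pairs requested.
#' @param radius named per-class ROI radius (px); background ROI uses the
#'   same radius as its vascular partner.
#' @param d_min,d_max adjacency band for the background center (default
#'   `2 * radius` / `8 * radius`).
#' @param seed RNG seed (placement is deterministic given the seed).
#' @param classes structure classes to sample; default all present in the
#'   labels.
#' @param margin keep-out border (px) so that later small ROI re-alignments
#'   cannot leave the raster.
#' @return List of [roi_pair()]s; attribute `"shortfall"` is a data frame of
#'   per-class requested/placed counts when placement fell short.
#' @export
auto_place_rois <- function(truth, n_pairs = 25,
                            radius = c(large_vessel = 4, small_vessel = 1.5,
                                       blush = 4, vein = 3),
                            d_min = NULL, d_max = NULL, seed = 1L,
                            classes = NULL, margin = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  if (n_pairs == 0) return(list())
  labels <- truth$labels
  H <- nrow(labels); W <- ncol(labels)
  present <- VASCULAR_CLASSES[vapply(VASCULAR_CLASSES, function(cl)
    any(labels == PHANTOM_CLASSES[[cl]]), logical(1))]
  if (is.null(classes)) classes <- present
  requested <- classes[seq_len(n_pairs) %% length(classes) + 1]

  used <- matrix(FALSE, H, W)
  class_pixels <- lapply(classes, function(cl)
    which(labels == PHANTOM_CLASSES[[cl]], arr.ind = TRUE))
  names(class_pixels) <- classes

  place <- function(cl, pair_id) {
    rad <- if (cl %in% names(radius)) radius[[cl]] else radius[[1]]
    dmin <- if (is.null(d_min)) 2 * rad else d_min
    dmax <- if (is.null(d_max)) 8 * rad else d_max
    offs <- disc_offsets(rad)
    cand <- class_pixels[[cl]]
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    target <- PHANTOM_CLASSES[[cl]]
    bg <- PHANTOM_CLASSES[["background"]]
    ok_disc <- function(cy, cx, want) {
      ry <- cy + offs$dy; rx <- cx + offs$dx
      if (min(ry) < 1 + margin || max(ry) > H - margin ||
          min(rx) < 1 + margin || max(rx) > W - margin) return(NULL)
      idx <- cbind(ry, rx)
      if (any(labels[idx] != want) || any(used[idx])) return(NULL)
      idx
    }
    for (try in 1:200) {
      p <- cand[sample.int(nrow(cand), 1), ]
      vpx <- ok_disc(p[1], p[2], target)
      if (is.null(vpx)) next
      for (btry in 1:40) {
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- stats::runif(1, dmin, dmax)
        bc <- round(c(p[1] + dist * sin(ang), p[2] + dist * cos(ang)))
        bpx <- ok_disc(bc[1], bc[2], bg)
        if (is.null(bpx)) next
        used[rbind(vpx, bpx)] <<- TRUE
        return(roi_pair(roi(as.numeric(p), rad), roi(as.numeric(bc), rad),
                        cl, id = pair_id))
      }
    }
    NULL
  }

  pairs <- list()
  placed_by_class <- stats::setNames(integer(length(classes)), classes)
  with_seed(seed, {
    for (i in seq_len(n_pairs)) {
      pr <- place(requested[i], length(pairs) + 1L)
      if (!is.null(pr)) {
        pairs[[length(pairs) + 1L]] <- pr
        placed_by_class[pr$structure_class] <-
          placed_by_class[pr$structure_class] + 1L
      }
    }
  })
  if (length(pairs) < n_pairs) {
    req_by_class <- table(factor(requested, levels = classes))
    shortfall <- data.frame(class = classes,
                            requested = as.integer(req_by_class[classes]),
                            placed = as.integer(placed_by_class[classes]))
    attr(pairs, "shortfall") <- shortfall
    warning(sprintf("placed %d of %d requested ROI pairs",
                    length(pairs), n_pairs))
  }
  pairs
}

#' Translate ROI pairs by a rigid shift
#'
#' Used to carry the ROI set of one modality image onto the other when a
#' residual pixel-shift displacement separates them. Bounds are re-validated;
#' an ROI pushed outside the raster raises an error naming the pair.
#'
#' @param pairs list of [roi_pair()]s.
#' @param shift `c(dy, dx)` in px.
#' @param dim raster dimensions `c(H, W)` for re-validation.
#' @return The translated list of pairs.
#' @export
align_rois <- function(pairs, shift, dim) {
  if (any(!is.finite(shift))) stopf("shift must be finite")
  lapply(pairs, function(p) {
    p$vascular$center <- p$vascular$center + shift
    p$background$center <- p$background$center + shift
    for (part in c("vascular", "background")) {
      ok <- tryCatch({roi_pixels(p[[part]], dim); TRUE},
                     error = function(e) FALSE)
      if (!ok) stopf("pair %s: %s ROI pushed outside the raster", p$id, part)
    }
    p
  })
}

#' Contrast-to-noise ratio of one ROI pair on one modality image
#'
#' `CNR = (Mean_v - Mean_b) / SD_b`: the arithmetic means of the vascular and
#' background pixel values and the sample SD (denominator N - 1) of the
#' background pixels. Sign is preserved. Raw (unwindowed) pixels only.
#'
#' @param image a [modality_image()] (not display-windowed).
#' @param pair an [roi_pair()].
#' @return Object of class `cnr_record` with fields `mean_v`, `mean_b`,
#'   `sd_b`, `cnr`, `modality`, `pair_id`.
#' @export
compute_cnr <- function(image, pair) {
  stopifnot(inherits(image, "modality_image"), inherits(pair, "roi_pair"))
  if (image$windowed)
    stopf("CNR must be computed on raw pixels, not a display-windowed image")
  d <- dim(image$pixels)
  v <- image$pixels[roi_pixels(pair$vascular, d)]
  b <- image$pixels[roi_pixels(pair$background, d)]
  if (length(b) < 2) stopf("background ROI needs >= 2 pixels")
  sd_b <- stats::sd(b)
  if (sd_b == 0) stopf("degenerate background (SD = 0): CNR undefined")
  structure(list(mean_v = mean(v), mean_b = mean(b), sd_b = sd_b,
                 cnr = (mean(v) - mean(b)) / sd_b,
                 modality = image$modality, pair_id = pair$id),
            class = "cnr_record")
}

#' Pair the DSA and DVA CNR of one ROI pair
#'
#' @param dsa,dva [compute_cnr()] records for the same pair id, one per
#'   modality.
#' @return Object of class `paired_cnr` with `cnr_dsa`, `cnr_dva`, `ratio`
#'   (`CNR_DVA / CNR_DSA`) and a `flagged` marker when `cnr_dsa <= 0` (ratio
#'   `NA` when exactly 0; flagged records are reported, never silently
#'   dropped).
#' @export
compute_ratio <- function(dsa, dva) {
  stopifnot(inherits(dsa, "cnr_record"), inherits(dva, "cnr_record"))
  if (!identical(dsa$pair_id, dva$pair_id)) stopf("mismatched pair ids")
  if (dsa$modality != "DSA" || dva$modality != "DVA")
    stopf("arguments must be a DSA record and a DVA record")
  flagged <- dsa$cnr <= 0
  ratio <- if (dsa$cnr == 0) NA_real_ else dva$cnr / dsa$cnr
  structure(list(pair_id = dsa$pair_id, cnr_dsa = dsa$cnr, cnr_dva = dva$cnr,
                 ratio = ratio, flagged = flagged),
            class = "paired_cnr")
}

#' Summarize paired CNR records
#'
#' Per group: n, median and IQR (25th-75th percentile, linear interpolation)
#' of DSA CNR, DVA CNR and their ratio. Flagged ratios (non-positive DSA CNR)
#' are excluded from the ratio statistics and counted in `n_ratio_excluded`.
#'
#' @param records data frame with columns `cnr_dsa`, `cnr_dva`, `ratio`,
#'   `flagged`, plus any grouping columns.
#' @param group_by character vector of grouping column names, or `NULL` for
#'   one overall row.
#' @return Data frame of group summaries.
#' @export
summarize_cnr <- function(records, group_by = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  groups <- if (is.null(group_by)) list(overall = records)
  else split(records, records[group_by], drop = TRUE)
  if (length(groups) == 0) {
    warning("no non-empty groups")
    return(data.frame())
  }
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    rat <- r$ratio[!r$flagged & !is.na(r$ratio)]
    q <- function(x, p) if (length(x)) quantile7(x, p) else NA_real_
    data.frame(group = g, n = nrow(r),
               cnr_dsa_median = q(r$cnr_dsa, 0.5),
               cnr_dsa_q25 = q(r$cnr_dsa, 0.25), cnr_dsa_q75 = q(r$cnr_dsa, 0.75),
               cnr_dva_median = q(r$cnr_dva, 0.5),
               cnr_dva_q25 = q(r$cnr_dva, 0.25), cnr_dva_q75 = q(r$cnr_dva, 0.75),
               ratio_median = q(rat, 0.5),
               ratio_q25 = q(rat, 0.25), ratio_q75 = q(rat, 0.75),
               n_ratio_excluded = sum(r$flagged | is.na(r$ratio)))
  })
  do.call(rbind, rows)
}
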