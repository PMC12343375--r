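test_that("mask frame selection honors metadata and finds the pre-contrast frame", {
  cfg <- tiny_config()
  s <- add_noise(render_series(phantom_ground_truth(cfg), cfg), cfg)
  expect_equal(select_mask_frame(s), s$mask_candidates[1])

  # without metadata: returns some frame before bolus arrival
  s2 <- s; s2$mask_candidates <- integer(0)
  expect_lt(select_mask_frame(s2), cfg$bolus_spec$arrival + 1)

  # 2-frame series, contrast only in frame 2 -> frame 1
  fr <- array(1000, c(8, 8, 2)); fr[3:5, 3:5, 2] <- 400
  expect_equal(select_mask_frame(frame_series(fr, fps = 2)), 1L)
})

test_that("DVA equals the sample SD of attenuation, with closed-form checks", {
  # temporally constant -> all zeros
  s <- frame_series(array(123.4, c(4, 4, 6)), fps = 2)
  expect_true(all(compute_dva(s)$pixels == 0))

  # N = 2, attenuation 0 then 1 -> 1/sqrt(2)
  fr <- array(0, c(3, 3, 2))
  fr[, , 1] <- 1000; fr[, , 2] <- 1000 * exp(-1)
  expect_equal(compute_dva(frame_series(fr, fps = 2))$pixels[1, 1],
               1 / sqrt(2), tolerance = 1e-12)

  # step signal, amplitude 1 in 5 of 15 frames -> sqrt(50/210)
  att <- c(rep(1, 5), rep(0, 10))
  fr <- array(rep(1000 * exp(-att), each = 4), c(2, 2, 15))
  v <- compute_dva(frame_series(fr, fps = 2))$pixels[1, 1]
  expect_equal(v, sqrt(50 / 210), tolerance = 1e-9)
  # a denominator-N implementation would land elsewhere
  expect_gt(abs(v - sqrt(50 / 210 * 14 / 15)), 1e-3)

  expect_error(compute_dva(frame_series(fr, fps = 2), frame_subset = 3),
               "2 frames")
})

test_that("DVA matches the naive per-pixel loop oracle on random stacks", {
  set.seed(11)
  for (i in 1:20) {
    fr <- array(exp(stats::rnorm(5 * 4 * 4)), c(4, 4, 5))
    got <- compute_dva(frame_series(fr, fps = 2))$pixels
    want <- naive_dva(fr)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-300)), 1e-10)
  }
})

test_that("DSA is log-domain mask subtraction with the stated summaries", {
  # identical frames -> all-zero summary
  s <- frame_series(array(500, c(4, 4, 3)), fps = 2)
  expect_true(all(compute_dsa(s, mask = 1)$pixels == 0))

  # half transmission -> ln 2
  fr <- array(1000, c(4, 4, 3)); fr[2, 2, 3] <- 500
  d <- compute_dsa(frame_series(fr, fps = 2), mask = 1, keep_series = TRUE)
  expect_equal(d$subtracted[2, 2, 3], log(2), tolerance = 1e-12)
  expect_equal(d$provenance$peak_frame, 3L)

  # noise-free phantom: selected peak frame equals the ground-truth peak
  cfg <- tiny_config(photon_noise = FALSE, read_noise_sd = 0)
  truth <- phantom_ground_truth(cfg)
  clean <- render_series(truth, cfg)
  dsa <- compute_dsa(clean, mask = 1)
  expect_equal(dsa$provenance$peak_frame, truth$peak_frame)

  # max-opacity projection dominates any single frame pixel-wise
  mip <- compute_dsa(clean, mask = 1, summary = "max_opacity_projection")
  expect_true(all(mip$pixels >= dsa$pixels - 1e-12))

  expect_error(compute_dsa(frame_series(array(1, c(2, 2, 1)), fps = 2)),
               "only frame")
})

test_that("both engines are invariant to a global intensity gain", {
  cfg <- tiny_config(region_profile = "head_neck")
  s <- add_noise(render_series(phantom_ground_truth(cfg), cfg), cfg)
  s2 <- s; s2$frames <- s$frames * 3.7   # constant shift of all log-intensities
  expect_equal(compute_dva(s2)$pixels, compute_dva(s)$pixels,
               tolerance = 1e-12)
  expect_equal(compute_dsa(s2, mask = 1)$pixels,
               compute_dsa(s, mask = 1)$pixels, tolerance = 1e-12)
})

test_that("display windowing is linear, recorded, and kept out of CNR", {
  img <- modality_image(matrix(c(0, 1), 4, 4), "DSA")
  w <- window_image(img, 0, 100, out_max = 255)
  expect_setequal(unique(as.vector(w$pixels)), c(0, 255))
  expect_true(w$windowed)

  const <- modality_image(matrix(5, 4, 4), "DSA")
  expect_warning(wc <- window_image(const), "degenerate")
  expect_identical(wc$pixels, const$pixels)

  p <- roi_pair(roi(c(2, 2), 1.5), roi(c(2, 6), 1.5), "large_vessel")
  img2 <- modality_image(matrix(stats::rnorm(64), 8, 8), "DSA")
  expect_error(compute_cnr(window_image(img2), p), "raw pixels")
  expect_error(window_image(img2, 50, 20), "low_pct")
})

test_that("subpixel registration recovers known translations of a smooth image", {
  sm <- smooth_test_image(128, seed = 3)
  for (s in list(c(2, 0), c(-3, 1), c(2.3, -1.7), c(0.5, 2.5))) {
    mv <- translate_frame(sm, s[1], s[2], fill = 0)
    expect_lt(max(abs(register_translation(mv, sm) - s)), 0.25)
  }
  # reference against itself is exactly zero
  expect_equal(register_translation(sm, sm), c(0, 0))
})

test_that("estimate_shifts finds no motion where there is none, flags flat frames", {
  # static scene + noise: shifts within 0.1 px
  cfg <- tiny_config(motion_spec = list(pattern = "none"))
  s <- add_noise(render_series(phantom_ground_truth(cfg), cfg), cfg)
  static <- s
  for (t in 1:10) static$frames[, , t] <- s$frames[, , 8] + 0.01 * t
  sh0 <- estimate_shifts(static)
  expect_true(all(abs(sh0) <= 0.1))

  # evolving bolus, still no motion: content change may cost a fraction of
  # a pixel but stays within the registration tolerance
  sh <- estimate_shifts(s)
  expect_true(all(abs(sh) <= 0.25))
  expect_equal(unname(sh[attr(sh, "reference"), ]), c(0, 0))

  # zero-variance frames are flagged and assigned (0,0)
  fr <- array(1000, c(16, 16, 3))
  fr[4:8, 4:8, 2] <- 500
  expect_warning(sh2 <- estimate_shifts(frame_series(fr, fps = 2)),
                 "zero-variance")
  expect_true(all(sh2[c(1, 3), ] == 0))
  expect_true(attr(sh2, "flagged")[1])
})

test_that("align_series undoes shifts to interpolation tolerance", {
  cfg <- tiny_config(motion_spec = list(pattern = "none"))
  s <- render_series(phantom_ground_truth(cfg), cfg)
  # zero shifts -> identity
  z <- matrix(0, 10, 2)
  expect_identical(align_series(s, z)$frames, s$frames)

  # shift then unshift a smooth frame: interior error within 1% of range
  sm <- 1000 * exp(smooth_test_image(128, seed = 6, scale = 10) / 8)
  smser <- frame_series(array(sm, c(128, 128, 2)), fps = 2)
  sh <- matrix(0, 2, 2); sh[2, ] <- c(1.3, -2.6)
  moved <- smser
  moved$frames[, , 2] <- translate_frame(sm, 1.3, -2.6)
  back <- align_series(moved, sh)
  dyn <- diff(range(sm))
  interior <- back$frames[10:119, 10:119, 2] - sm[10:119, 10:119]
  expect_lt(max(abs(interior)), 0.01 * dyn)

  # integer shift of a delta spike is relocated exactly
  fr <- array(1, c(32, 32, 2)); fr[16, 16, 2] <- 100
  sp <- frame_series(fr, fps = 2)
  al <- align_series(sp, rbind(c(0, 0), c(3, -4)))
  expect_equal(which(al$frames[, , 2] == 100, arr.ind = TRUE)[1, ],
               c(row = 13, col = 20))

  expect_error(align_series(s, matrix(NA, 10, 2)), "finite")
  expect_error(align_series(s, matrix(200, 10, 2)), "raster")
})

test_that("estimated shifts track true phantom motion within 0.25 px", {
  cfg <- phantom_config(192, 192, n_frames = 12, seed = 5,
                        region_profile = "chest",
                        motion_spec = list(pattern = "sinusoid",
                                           amplitude = 2.5, period = 6))
  sim <- simulate_acquisition(cfg)
  sh <- estimate_shifts(sim$series)
  rel_true <- sweep(sim$truth$true_shifts, 2,
                    sim$truth$true_shifts[attr(sh, "reference"), ])
  expect_lt(max(abs(sh - rel_true)), 0.25)
})
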