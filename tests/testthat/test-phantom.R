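test_that("gamma-variate curve is zero pre-arrival, peaks at amplitude, unimodal", {
  expect_equal(gamma_variate_curve(0:2, arrival = 3, time_to_peak = 4,
                                   shape = 2, amplitude = 0.8),
               c(0, 0, 0))
  expect_equal(gamma_variate_curve(7, arrival = 3, time_to_peak = 4,
                                   shape = 2, amplitude = 0.8), 0.8)
  # argmax over an evaluated grid sits at arrival + time_to_peak, and the
  # curve decays monotonically afterwards
  v <- gamma_variate_curve(0:20, arrival = 3, time_to_peak = 4,
                           shape = 2, amplitude = 1)
  expect_equal(which.max(v), 8L)  # t = 7 on the 0-based grid
  expect_true(all(diff(v[8:21]) < 0))
  expect_error(gamma_variate_curve(1, 0, time_to_peak = -1, shape = 2,
                                   amplitude = 1), "time_to_peak")
  expect_error(gamma_variate_curve(1, 0, time_to_peak = 2, shape = 0,
                                   amplitude = 1), "shape")
})

test_that("vessel tree contains every configured class, deterministically", {
  cfg <- tiny_config()
  labels <- generate_vessel_tree(cfg)
  present <- sort(unique(as.vector(labels)))
  expect_equal(present, unname(PHANTOM_CLASSES))  # all 5 classes
  expect_identical(labels, generate_vessel_tree(cfg))

  no_small <- tiny_config(vessel_spec = list(n_small = 0L))
  expect_false(any(generate_vessel_tree(no_small) ==
                     PHANTOM_CLASSES[["small_vessel"]]))
})

test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(n_frames = 1), "n_frames")
  expect_error(phantom_config(fps = 3), "fps")
  expect_error(phantom_config(height_px = 32), "64x64")
  expect_error(tiny_config(vessel_spec = list(large_width = c(40, 60))),
               "widths")
  expect_error(tiny_config(motion_spec = list(pattern = "sinusoid",
                                              amplitude = 30)),
               "amplitude")
  expect_error(phantom_config(photon_flux = 0), "photon_flux")
})

test_that("rendering follows the Beer-Lambert model exactly (noise-free)", {
  # a_t(x) = 0 everywhere -> all pixels exactly I0
  cfg <- tiny_config(tissue_spec = list(amplitude = 0, scale_px = 1),
                     bolus_spec = list(amplitude = c(large_vessel = 0,
                                                     small_vessel = 0,
                                                     blush = 0, vein = 0)),
                     photon_flux = 1000)
  truth <- phantom_ground_truth(cfg)
  s <- render_series(truth, cfg)
  expect_true(all(s$frames == 1000))
  expect_equal(s$mask_candidates, 1:10)

  # a = ln 2 on large vessels -> intensity exactly I0/2 at peak
  cfg2 <- tiny_config(tissue_spec = list(amplitude = 0, scale_px = 1),
                      bolus_spec = list(amplitude = c(large_vessel = log(2),
                                                      small_vessel = 0,
                                                      blush = 0, vein = 0)),
                      photon_flux = 1000)
  truth2 <- phantom_ground_truth(cfg2)
  s2 <- render_series(truth2, cfg2)
  lv <- truth2$labels == PHANTOM_CLASSES[["large_vessel"]]
  expect_equal(unique(s2$frames[, , truth2$peak_frame][lv]), 500)

  # rendering inverse: -ln(I/I0) recovers the summed attenuation per pixel
  cfg3 <- tiny_config()
  truth3 <- phantom_ground_truth(cfg3)
  s3 <- render_series(truth3, cfg3)
  t_pk <- truth3$peak_frame
  a_rec <- -log(s3$frames[, , t_pk] / cfg3$photon_flux)
  lv3 <- truth3$labels == PHANTOM_CLASSES[["large_vessel"]]
  a_want <- truth3$static_attenuation[lv3] +
    truth3$attenuation_curves["large_vessel", t_pk]
  expect_lt(max(abs(a_rec[lv3] - a_want)), 1e-12)
})

test_that("ground-truth curves are zero before arrival and vein lags artery", {
  cfg <- tiny_config()
  truth <- phantom_ground_truth(cfg)
  arr <- cfg$bolus_spec$arrival
  pre <- seq_len(arr)
  expect_true(all(truth$attenuation_curves[, pre] == 0))
  vein_peak <- which.max(truth$attenuation_curves["vein", ])
  expect_equal(vein_peak - truth$peak_frame, cfg$venous_delay)
})

test_that("detector noise is unbiased, deterministic, and clamps at 1 count", {
  cfg <- tiny_config(photon_flux = 1e6, read_noise_sd = 0,
                     tissue_spec = list(amplitude = 0, scale_px = 1),
                     bolus_spec = list(amplitude = c(large_vessel = 0,
                                                     small_vessel = 0,
                                                     blush = 0, vein = 0)),
                     n_frames = 16)
  clean <- render_series(phantom_ground_truth(cfg), cfg)
  # stack a few renders to get ~2e5 independent draws at lambda = 1e6
  noisy <- add_noise(clean, cfg)
  m <- mean(noisy$frames)
  se <- sqrt(1e6 / length(noisy$frames))
  expect_lt(abs(m - 1e6), 3 * se)

  # same seed -> identical; noise disabled -> identity
  expect_identical(add_noise(clean, cfg)$frames, noisy$frames)
  off <- tiny_config(photon_noise = FALSE, read_noise_sd = 0)
  clean2 <- render_series(phantom_ground_truth(off), off)
  expect_identical(add_noise(clean2, off), clean2)

  # tiny flux forces clamping; positivity survives
  lowcfg <- tiny_config(photon_flux = 1.5, read_noise_sd = 2)
  low <- add_noise(render_series(phantom_ground_truth(lowcfg), lowcfg), lowcfg)
  expect_gt(attr(low, "n_clamped"), 0)
  expect_true(all(low$frames >= 1))
})

test_that("motion is recorded truthfully and moves content as stated", {
  cfg <- tiny_config(motion_spec = list(pattern = "none"))
  truth <- phantom_ground_truth(cfg)
  s <- render_series(truth, cfg)
  mv <- apply_motion(s, truth, cfg)
  expect_true(all(mv$truth$true_shifts == 0))
  expect_identical(mv$series$frames, s$frames)

  # sinusoid: max recorded |dy| equals the amplitude (period hits the crest)
  cfg2 <- tiny_config(n_frames = 17,
                      motion_spec = list(pattern = "sinusoid", amplitude = 3,
                                         period = 8))
  truth2 <- phantom_ground_truth(cfg2)
  mv2 <- apply_motion(render_series(truth2, cfg2), truth2, cfg2)
  expect_equal(max(abs(mv2$truth$true_shifts[, "dy"])), 3)
  # the canonical mask frame is never displaced
  expect_equal(unname(mv2$truth$true_shifts[1, ]), c(0, 0))

  # a delta spike translated by (2, 0) moves its centroid 2 rows down
  img <- matrix(0, 32, 32); img[16, 16] <- 1
  out <- translate_frame(img, 2, 0, fill = 0)
  expect_equal(which(out == max(out), arr.ind = TRUE)[1, ],
               c(row = 18, col = 16))
})

test_that("acquisition metadata stays inside the study envelope", {
  nf <- vapply(1:300, function(i)
    varangio:::sample_n_frames(derive_seed(7, i)), numeric(1))
  expect_true(all(nf >= 5 & nf <= 53))
  expect_lt(abs(mean(nf) - 15), 1)
  fps <- vapply(1:50, function(i)
    varangio:::sample_fps(derive_seed(7, "f", i)), numeric(1))
  expect_true(all(fps %in% c(2, 4)))
})

test_that("the full generator is a pure function of (config, seed)", {
  cfg <- tiny_config(region_profile = "chest")
  a <- simulate_acquisition(cfg)
  b <- simulate_acquisition(cfg)
  expect_identical(a$series$frames, b$series$frames)
  expect_identical(a$truth$true_shifts, b$truth$true_shifts)
  cfg2 <- tiny_config(region_profile = "chest", seed = 43L)
  expect_false(identical(simulate_acquisition(cfg2)$series$frames,
                         a$series$frames))
})
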