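test_that("simulated IRF is a unit-area unimodal pulse of the right width", {
  irf <- simulate_irf(200, 500, n_bins = 256, bin_width_ps = 48.8)
  expect_equal(sum(irf), 1)
  expect_true(all(irf >= 0))
  peak <- which.max(irf)
  expect_true(all(diff(irf[seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(irf[peak:length(irf)]) <= 1e-12))
  # empirical FWHM within one bin of the nominal 200 ps
  half <- max(irf) / 2
  above <- range(which(irf >= half))
  fwhm_meas <- (diff(above) + 1) * 48.8
  expect_lt(abs(fwhm_meas - 200), 48.8 + 1e-9)
  # vanishing width collapses to a single bin at the center
  delta <- simulate_irf(1e-9, 500)
  expect_equal(sum(delta > 0), 1)
  expect_equal(which(delta > 0), floor(500 / 48.8) + 1)
  expect_error(simulate_irf(-5, 500), class = "flim_param_error")
  expect_error(simulate_irf(200, 12000), class = "flim_param_error")
})

test_that("decay simulation conserves the photon budget and is seed-deterministic", {
  irf <- simulate_irf(200, 1000)
  p <- decay_params(450, 4000)
  expect_equal(simulate_decay(p, irf, 0, seed = 1), rep(0L, 256))
  n <- 5e4
  tot <- vapply(1:20, function(s) sum(simulate_decay(p, irf, n, seed = s)), 0)
  expect_true(all(abs(tot - n) < 4 * sqrt(n)))
  expect_identical(simulate_decay(p, irf, 1e4, seed = 7),
                   simulate_decay(p, irf, 1e4, seed = 7))
  expect_error(decay_params(-100, 4000), class = "flim_param_error")
  expect_error(decay_params(450, 100), class = "flim_param_error")
})

test_that("a single-exponential tail fit recovers the simulated lifetime", {
  irf <- simulate_irf(150, 300)
  y <- simulate_decay(decay_params(2000, 2000), irf, 1e6, wrap = FALSE, seed = 3)
  # independent check: weighted log-linear regression on the bare tail
  idx <- seq(which.max(y) + 10, 256)
  t_ps <- (idx - 1) * 48.8
  ok <- y[idx] > 0
  fitlm <- stats::lm(log(y[idx][ok]) ~ t_ps[ok], weights = y[idx][ok])
  tau_lm <- -1 / coef(fitlm)[2]
  expect_lt(abs(tau_lm - 2000) / 2000, 0.02)
})

test_that("sample simulation places the requested cells and honours budgets", {
  spec0 <- normal_skin_spec(density_mm2 = 1e-9)
  s0 <- simulate_sample(spec0, n_cells = 0, render = "image", seed = 1,
                        image_size = 48)
  expect_equal(n_rois(s0$rois), 0)
  expect_true(sum(intensity_image(s0$stack)) > 0) # background only

  s20 <- simulate_sample(bcc_spec(), n_cells = 20, render = "rois", seed = 2)
  expect_equal(n_rois(s20$rois), 20)
  expect_equal(sort(unique(as.vector(s20$rois$labels[s20$rois$labels > 0]))), 1:20)

  # fixed per-cell budget, no background: ROI-integrated counts within
  # Poisson bounds of the budget
  spec_fix <- normal_skin_spec(yield_sdlog = 1e-9, patient_cv = 0,
                               background_photons_px = 0, dark_rate = 0)
  spec_fix$channels$yield <- rep(5e4, 4)
  s <- simulate_sample(spec_fix, n_cells = 5, render = "image", seed = 4,
                       image_size = 96)
  for (id in 1:5) {
    d <- integrate_roi_decay(s$stack, s$rois, "green", roi_id = id)
    expect_lt(abs(d$photon_count - 5e4), 3 * sqrt(5e4))
  }

  # unplaceable density errors out explicitly
  expect_error(simulate_sample(bcc_spec(), n_cells = 400, image_size = 32,
                               render = "rois", seed = 1),
               class = "flim_density_error")
})

test_that("cohorts have the requested structure and reproduce under a seed", {
  coh <- simulate_cohort(5, 5, 50, seed = 9)
  expect_length(coh, 10)
  expect_equal(sum(vapply(coh, function(s) n_rois(s$rois), 1L)), 500)
  cls <- vapply(coh, function(s) s$class_label, "")
  expect_equal(sum(cls == "normal"), 5)

  coh2 <- simulate_cohort(5, 5, 50, seed = 9)
  expect_identical(coh[[1]]$roi_decays$counts, coh2[[1]]$roi_decays$counts)
  expect_identical(coh[[3]]$truth_params, coh2[[3]]$truth_params)
})

test_that("generator lifetime distributions sit at their class anchors", {
  # patient random effects off: this test isolates the anchor calibration
  # (the cohort-level tests exercise the random-effect structure)
  coh <- simulate_cohort(6, 6, 40, seed = 21,
                         spec_normal = normal_skin_spec(patient_cv = 0),
                         spec_bcc = bcc_spec(patient_cv = 0))
  tp <- dplyr::bind_rows(lapply(coh, function(s)
    dplyr::mutate(s$truth_params, class_label = s$class_label)))
  tm <- tp$frac1 * tp$tau1 + (1 - tp$frac1) * tp$tau2
  med <- tapply(tm, list(tp$class_label, tp$channel), median)
  # truth-parameter medians near the class targets (ps)
  expect_lt(abs(med["bcc", "blue"] - 2419) / 2419, 0.05)
  expect_lt(abs(med["normal", "blue"] - 1797) / 1797, 0.05)
  expect_lt(abs(med["bcc", "green"] - 2624) / 2624, 0.05)
  expect_lt(abs(med["normal", "red"] - 1036) / 1036, 0.05)
  # per-class blue-channel separation ~ 35%
  pd <- percent_difference(med["bcc", "blue"], med["normal", "blue"])
  expect_lt(abs(pd - 34.6), 5)
})
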