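tb_irf <- simulate_irf(200, 1000)

test_that("mono-exponential reconvolution is self-consistent and masks empty pixels", {
  mu <- decay_model_curve(decay_params(2000, 2000), tb_irf, 1e6)
  f <- fit_monoexp_pixel(round(mu), tb_irf)
  expect_lt(abs(f$tau - 2000), 3)
  z <- fit_monoexp_pixel(rep(0L, 256), tb_irf)
  expect_true(z$masked)
  expect_true(is.na(z$tau))
})

test_that("mono-exponential fits are unbiased over Poisson replicates", {
  set.seed(42)
  p <- decay_params(1500, 1500)
  taus <- vapply(1:100, function(i) {
    y <- simulate_decay(p, tb_irf, 5000)
    fit_monoexp_pixel(y, tb_irf)$tau
  }, 0)
  expect_lt(abs(mean(taus) - 1500) / 1500, 0.03)
  expect_gt(sd(taus), 0) # empirical dispersion is reported, not degenerate
})

test_that("bi-exponential fit recovers the green-channel peak lifetimes", {
  y <- simulate_decay(decay_params(450, 4000), tb_irf, 1e5, seed = 11)
  # the synthetic data carry no instrumental shift; fitting one only opens
  # the shift/tau1 degeneracy, so the self-consistency check runs without it
  f <- fit_biexp(y, tb_irf, fit_shift = FALSE)
  expect_lt(abs(f$tau1 - 450) / 450, 0.05)
  expect_lt(abs(f$tau2 - 4000) / 4000, 0.05)
  expect_gt(f$chi2_reduced, 0.8)
  expect_lt(f$chi2_reduced, 1.2)
  expect_true(f$converged)
  expect_lte(f$tau1, f$tau2)
})

test_that("degenerate single-exponential input gives tau_mean at the truth", {
  y <- simulate_decay(decay_params(2000, 2000), tb_irf, 1e5, seed = 5)
  f <- fit_biexp(y, tb_irf)
  expect_lt(abs(f$tau_mean - 2000) / 2000, 0.02)
})

test_that("fit result is invariant to swapping the initial lifetimes", {
  y <- as.numeric(simulate_decay(decay_params(450, 4000), tb_irf, 1e5, seed = 2))
  w <- 1 / pmax(y, 1)
  core <- function(init) flimcyte:::fit_biexp_cpp(y, tb_irf, 48.8, TRUE, w,
                                                  FALSE, 3, 50, 8000, init, 0, 400L)
  a <- core(c(450, 4000))
  b <- core(c(4000, 450))
  expect_lt(abs(a$tau1 - b$tau1) / a$tau1, 0.01)
  expect_lt(abs(a$tau2 - b$tau2) / a$tau2, 0.01)
  expect_lte(a$tau1, a$tau2)
  expect_lte(b$tau1, b$tau2)
})

test_that("fits are refused below the photon floor with explicit status", {
  y <- simulate_decay(decay_params(450, 4000), tb_irf, 500, seed = 1)
  f <- fit_biexp(y, tb_irf, min_photons = 1000)
  expect_equal(f$status, "insufficient_photons")
  expect_true(is.na(f$tau1))
})

test_that("tau_mean follows the amplitude-weighted convention", {
  expect_equal(tau_mean(list(tau1 = 1000, tau2 = 3000, a1 = 1, a2 = 0)), 1000)
  expect_equal(tau_mean(list(tau1 = 1000, tau2 = 3000, a1 = 1, a2 = 1)), 2000)
  expect_equal(tau_mean(list(tau1 = 450, tau2 = 4000, a1 = 0.7, a2 = 0.3)), 1515)
  expect_error(tau_mean(list(tau1 = 1, tau2 = 2, a1 = 0, a2 = 0)),
               class = "flim_param_error")
  # intensity-weighted alternative
  expect_equal(tau_mean(list(tau1 = 1000, tau2 = 3000, a1 = 1, a2 = 1),
                        type = "intensity"), (1e6 + 9e6) / 4000)
})

test_that("ROI integration is exact photon conservation", {
  s <- simulate_sample(normal_skin_spec(), n_cells = 4, image_size = 48,
                       render = "image", seed = 3)
  a <- s$stack$channels$green
  # single pixel
  m1 <- matrix(FALSE, 48, 48); m1[10, 20] <- TRUE
  expect_equal(integrate_roi_decay(s$stack, m1, "green")$counts, a[10, 20, ])
  # two disjoint pixels: element-wise sum
  m2 <- m1; m2[30, 5] <- TRUE
  expect_equal(integrate_roi_decay(s$stack, m2, "green")$counts,
               a[10, 20, ] + a[30, 5, ])
  # full image equals the (x, y) marginal
  mall <- matrix(TRUE, 48, 48)
  expect_equal(integrate_roi_decay(s$stack, mall, "green")$counts,
               as.integer(apply(a, 3, sum)))
  expect_error(integrate_roi_decay(s$stack, matrix(FALSE, 48, 48), "green"),
               class = "flim_roi_error")
  expect_error(integrate_roi_decay(s$stack, matrix(TRUE, 12, 12), "green"),
               class = "flim_roi_error")
})

test_that("FLIM images mask dim pixels and recover regional lifetimes", {
  # two-region phantom: left 1000 ps, right 3000 ps, ~600 photons/px
  nx <- 24; nbins <- 256
  mu1 <- decay_model_curve(decay_params(1000, 1000), tb_irf, 600)
  mu2 <- decay_model_curve(decay_params(3000, 3000), tb_irf, 600)
  set.seed(8)
  ch <- array(0L, c(nx, nx, nbins))
  for (x in 1:nx) for (y in 1:nx) {
    ch[x, y, ] <- rpois(nbins, if (x <= nx / 2) mu1 else mu2)
  }
  stk <- flim_stack(list(blue = ch, green = ch, yellow = ch, red = ch))
  img <- make_flim_image(stk, "green", tb_irf, min_pixel_photons = 100)
  left <- median(img$tau[1:(nx / 2), ])
  right <- median(img$tau[(nx / 2 + 1):nx, ])
  expect_lt(abs(left - 1000) / 1000, 0.05)
  expect_lt(abs(right - 3000) / 3000, 0.05)
  # infinite threshold -> fully masked
  img2 <- make_flim_image(stk, "green", tb_irf, min_pixel_photons = Inf)
  expect_false(any(img2$mask))
  expect_true(all(is.na(img2$tau)))
})

test_that("photon filters implement both exclusion rules with an exact log", {
  mk <- function(pid, roi, counts) tibble::tibble(
    patient_id = pid, sample_id = pid, roi_id = roi,
    channel = c("blue", "green", "yellow", "red"), photon_count = counts)
  fits <- dplyr::bind_rows(
    mk("P1", 1, c(1200, 1500, 999, 2000)),
    mk("P1", 2, c(1000, 1000, 1000, 1000)), # boundary: kept everywhere
    mk("P2", 1, c(999, 998, 500, 100)),     # excluded everywhere
    mk("P3", 1, c(5000, 6000, 7000, 8000)))
  filt <- apply_photon_filters(fits, min_photons = 1000)
  cs <- filt$channel_set
  expect_setequal(cs$channel[cs$patient_id == "P1" & cs$roi_id == 1],
                  c("blue", "green", "red"))
  ds_keys <- unique(paste(filt$discriminant_set$patient_id,
                          filt$discriminant_set$roi_id))
  expect_setequal(ds_keys, c("P1 2", "P3 1"))
  expect_equal(filt$excluded_patients, "P2")
  # log equals a brute-force application of the two rules
  brute_ch <- sum(fits$photon_count < 1000)
  key <- paste(fits$patient_id, fits$roi_id)
  bad_roi <- unique(key[fits$photon_count < 1000])
  brute_disc <- sum(key %in% bad_roi & fits$photon_count >= 1000)
  expect_equal(nrow(filt$exclusion_log), brute_ch + brute_disc)
})

test_that("lifetime recovery improves with photon count", {
  set.seed(33)
  p <- decay_params(450, 4000)
  med_err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    errs <- vapply(1:25, function(i) {
      f <- fit_biexp(simulate_decay(p, tb_irf, n), tb_irf, fit_shift = FALSE)
      max(abs(f$tau1 - 450) / 450, abs(f$tau2 - 4000) / 4000)
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[2], 0.10)
})

test_that("the fitter agrees with an independent reconvolution fit (minpack.lm)", {
  skip_if_not_installed("minpack.lm")
  y <- simulate_decay(decay_params(450, 4000, a1 = 1, a2 = 1), tb_irf, 5e4,
                      seed = 19)
  ours <- fit_biexp(y, tb_irf, fit_shift = FALSE)
  # independent route: FFT circular convolution + Levenberg-Marquardt on all
  # five parameters at once, under the same fixed Pearson weights
  n <- length(y)
  w <- 1 / pmax(ours$fitted, 1e-3)
  conv_fft <- function(tau) {
    e <- exp(-(0:(n - 1)) * 48.8 / tau)
    per <- e / (1 - exp(-n * 48.8 / tau)) # periodic wrap
    Re(stats::fft(stats::fft(tb_irf) * stats::fft(per), inverse = TRUE)) / n
  }
  resid_fn <- function(p) {
    m <- exp(p[1]) * conv_fft(exp(p[3])) + exp(p[2]) * conv_fft(exp(p[4])) + exp(p[5])
    (y - m) * sqrt(w)
  }
  ref <- minpack.lm::nls.lm(par = c(log(50), log(50), log(500), log(3500), log(0.01)),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  taus <- sort(exp(ref$par[3:4]))
  # the reference must not find a better optimum of the shared objective
  expect_lte(sum(resid_fn(c(log(ours$a1), log(ours$a2), log(ours$tau1),
                            log(ours$tau2), log(max(ours$background, 1e-8))))^2),
             sum(ref$fvec^2) * 1.001)
  expect_lt(abs(ours$tau1 - taus[1]) / taus[1], 0.03)
  expect_lt(abs(ours$tau2 - taus[2]) / taus[2], 0.03)
})
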