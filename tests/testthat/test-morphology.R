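test_that("Gabriel graph matches its defining condition on simple cases", {
  g2 <- gabriel_graph(cbind(c(0, 3), c(0, 0)))
  expect_equal(nrow(g2$edges), 1)
  # collinear points: the midpoint blocks the long edge
  g3 <- gabriel_graph(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(nrow(g3$edges), 2)
  expect_false(any(g3$edges$from == 1 & g3$edges$to == 3))
  expect_error(gabriel_graph(matrix(numeric(), 0, 2)), class = "flim_param_error")
})

test_that("Gabriel graph equals the brute-force oracle on random point sets", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    pts <- matrix(runif(2 * n, 0, 100), n)
    g <- gabriel_graph(pts)
    o <- oracle_gabriel_edges(pts)
    got <- sort(paste(g$edges$from, g$edges$to))
    want <- sort(paste(o[, 1], o[, 2]))
    expect_identical(got, want)
  }
})

test_that("equivalent ellipses recover axis ratios and orientations", {
  disc <- make_disc_mask(41, 12)
  expect_lt(abs(flattening_factor(disc) - 1), 0.02)

  rect <- make_rect_mask(61, 40, 10)
  e <- equivalent_ellipse(rect)
  expect_lt(abs(e$orientation_deg %% 180), 1)
  expect_lt(abs(e$minor_axis / e$major_axis - 0.25), 0.02)

  rect30 <- make_rect_mask(81, 40, 10, angle_deg = 30)
  e30 <- equivalent_ellipse(rect30)
  expect_lt(abs(e30$orientation_deg - 30), 1)

  # 2:1 ellipse: flattening 0.5, rotation invariant within raster tolerance
  mke <- function(n, a, b, ang = 0) {
    c0 <- (n + 1) / 2; th <- ang * pi / 180
    g <- expand.grid(x = 1:n, y = 1:n)
    u <- ((g$x - c0) * cos(th) + (g$y - c0) * sin(th)) / a
    v <- (-(g$x - c0) * sin(th) + (g$y - c0) * cos(th)) / b
    m <- matrix(FALSE, n, n); m[cbind(g$x, g$y)] <- u^2 + v^2 <= 1; m
  }
  f0 <- flattening_factor(mke(81, 30, 15))
  expect_lt(abs(f0 - 0.5), 0.02)
  for (ang in c(30, 77))
    expect_lt(abs(flattening_factor(mke(81, 30, 15, ang)) - f0) / f0, 0.02)

  # cross-check axis length against EBImage moments on the same mask
  fm <- EBImage::computeFeatures.moment(matrix(as.integer(rect), nrow(rect)))
  expect_equal(e$major_axis, unname(fm[1, "m.majoraxis"]), tolerance = 1e-6)
})

test_that("axial orientation SD treats angles mod 180 and matches closed form", {
  expect_equal(axial_sd(c(37, 37, 37)), 0)
  expect_equal(axial_sd(c(0, 180)), 0)
  ang <- c(10, 20, 30)
  phi <- 2 * ang * pi / 180
  rbar <- sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
  expect_equal(axial_sd(ang), sqrt(2 * (1 - rbar)) / 2 * 180 / pi)
  expect_equal(axial_sd(ang, method = "naive"), sd(ang))
  expect_equal(axial_sd(5), 0) # single angle
})

test_that("confluency follows the hull geometry of ROI unions", {
  # two 10x10 squares separated by a 10-px gap inside a 30x10 strip
  lab <- matrix(0L, 40, 20)
  lab[3:12, 5:14] <- 1L
  lab[23:32, 5:14] <- 2L
  rs <- roi_set(lab, source = "manual")
  mo <- compute_morphology(rs)
  expect_equal(mo$confluency, rep(200 / 300, 2), tolerance = 1e-9)

  # a single convex ROI is its own hull
  lone <- matrix(0L, 20, 20); lone[5:14, 5:14] <- 1L
  expect_equal(compute_morphology(roi_set(lone, "manual"))$confluency, 1)

  # touching tiles approach full confluency
  tile <- matrix(0L, 30, 12)
  tile[1:10, 2:11] <- 1L; tile[11:20, 2:11] <- 2L; tile[21:30, 2:11] <- 3L
  expect_gt(min(compute_morphology(roi_set(tile, "manual"))$confluency), 0.98)
})

test_that("morphology features are translation invariant", {
  lab <- matrix(0L, 60, 60)
  lab[5:14, 8:13] <- 1L; lab[25:31, 30:38] <- 2L; lab[40:49, 10:17] <- 3L
  shifted <- matrix(0L, 60, 60)
  shifted[11:20, 15:20] <- 1L; shifted[31:37, 37:45] <- 2L; shifted[46:55, 17:24] <- 3L
  a <- compute_morphology(roi_set(lab, "manual"))
  b <- compute_morphology(roi_set(shifted, "manual"))
  expect_equal(a$flattening_factor, b$flattening_factor, tolerance = 1e-9)
  expect_equal(a$orientation_sd, b$orientation_sd, tolerance = 1e-9)
  expect_equal(a$confluency, b$confluency, tolerance = 1e-9)
})

test_that("spectral contributions are exact fractions", {
  expect_equal(unname(spectral_contribution(c(0, 500, 0, 0))), c(0, 1, 0, 0))
  expect_equal(unname(spectral_contribution(rep(7, 4))), rep(0.25, 4))
  expect_equal(unname(spectral_contribution(c(1000, 2000, 3000, 4000))),
               c(0.1, 0.2, 0.3, 0.4))
  expect_error(spectral_contribution(rep(0, 4)), class = "flim_param_error")
})

test_that("feature assembly yields one record per surviving ROI, morphology NA for auto", {
  coh <- simulate_cohort(2, 2, 8, seed = 15)
  fits <- fit_rois(coh)
  filt <- apply_photon_filters(fits, min_photons = 1000)
  rec <- assemble_features(filt, coh)
  n_surv <- nrow(dplyr::distinct(filt$discriminant_set, patient_id, roi_id))
  expect_equal(nrow(rec), n_surv)
  expect_true(all(!is.na(rec$flattening_factor)))
  sums <- rowSums(as.matrix(rec[, paste0("spectral_", c("blue", "green",
                                                        "yellow", "red"))]))
  expect_equal(sums, rep(1, nrow(rec)), tolerance = 1e-9)

  # auto-source ROIs carry no morphology
  auto <- coh[[1]]$rois
  auto$source <- "auto"
  rec2 <- assemble_features(filt$discriminant_set %>%
                              dplyr::filter(patient_id == coh[[1]]$patient_id),
                            list(auto))
  expect_true(all(is.na(rec2$flattening_factor)))
  expect_true(all(!is.na(rec2$tau_mean_green)))
})
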