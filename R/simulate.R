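#' Multispectral FLIM photon-count stack
#'
#' The raw unit of analysis: per-channel 3-D photon-count histograms
#' (x, y, time) on a common TCSPC time base, with acquisition metadata.
#'
#' @param channels Named list of exactly 4 integer arrays `[x, y, t]`, names
#'   `blue`, `green`, `yellow`, `red`.
#' @param bin_width_ps TCSPC bin width, ps.
#' @param channel_bands Named list of detection bands (nm); defaults to
#'   360–425 / 425–515 / 515–620 / 620–655 nm.
#' @param metadata List: `patient_id`, `sample_id`, `diagnosis`
#'   (`normal`/`bcc`/`unknown`), `depth_um`, `context`
#'   (`in_vivo`/`ex_vivo`/`synthetic`).
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(channels, bin_width_ps = 48.8,
                       channel_bands = .flim_bands, metadata = list()) {
  if (!is.list(channels) || length(channels) != 4)
    abort("a FLIM stack must have exactly 4 spectral channels", class = "flim_format_error")
  if (is.null(names(channels))) names(channels) <- .flim_channels
  stopifnot(setequal(names(channels), .flim_channels))
  channels <- channels[.flim_channels]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3) || length(unique(dims)) != 1)
    abort("channel arrays must share [x, y, t] dimensions", class = "flim_format_error")
  for (ch in .flim_channels) {
    a <- channels[[ch]]
    if (any(a < 0) || any(a != round(a)))
      abort("photon counts must be non-negative integers", class = "flim_format_error")
    storage.mode(channels[[ch]]) <- "integer"
  }
  md <- utils::modifyList(list(patient_id = NA_character_, sample_id = NA_character_,
                               diagnosis = "unknown", depth_um = NA_real_,
                               context = "synthetic"), metadata)
  structure(list(channels = channels, bin_width_ps = bin_width_ps,
                 channel_bands = channel_bands, metadata = md),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<flim_stack: 4 channels, %dx%d px, %d bins @ %.1f ps, %s>\n",
              d[1], d[2], d[3], x$bin_width_ps, x$metadata$context))
  invisible(x)
}

stack_dims <- function(stack) dim(stack$channels[[1]])

#' Simulate an instrument response function
#'
#' A Gaussian pulse integrated over TCSPC bins and normalized to unit area,
#' standing in for the daily nanorod-measured instrument response.
#'
#' @param fwhm_ps Full width at half maximum, ps (> 0).
#' @param center_ps Pulse center, ps from the start of the window.
#' @param n_bins,bin_width_ps Time base.
#' @return Numeric unit-area histogram of length `n_bins`.
#' @examples
#' irf <- simulate_irf(200, 1000)
#' sum(irf) # 1
#' @export
simulate_irf <- function(fwhm_ps = 200, center_ps = 1000,
                         n_bins = 256, bin_width_ps = 48.8) {
  if (!is.numeric(fwhm_ps) || fwhm_ps <= 0)
    abort("`fwhm_ps` must be > 0", class = "flim_param_error")
  if (bin_width_ps <= 0) abort("`bin_width_ps` must be > 0", class = "flim_param_error")
  if (center_ps + 3 * fwhm_ps >= n_bins * bin_width_ps)
    abort("IRF must lie well inside the time window", class = "flim_param_error")
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  edges <- seq(0, n_bins) * bin_width_ps
  h <- diff(pnorm(edges, mean = center_ps, sd = sigma))
  if (sum(h) <= 0) { # degenerate-width fallback: all mass in the center bin
    h <- numeric(n_bins)
    h[min(n_bins, floor(center_ps / bin_width_ps) + 1)] <- 1
  }
  h / sum(h)
}

#' Per-channel IRF set
#'
#' @param channels Named list of 4 non-negative histograms (one per spectral
#'   channel) on a common time base.
#' @param bin_width_ps Bin width, ps.
#' @return An object of class `irf_set`.
#' @export
irf_set <- function(channels, bin_width_ps = 48.8) {
  if (is.null(names(channels))) names(channels) <- .flim_channels
  stopifnot(setequal(names(channels), .flim_channels))
  channels <- channels[.flim_channels]
  n <- unique(lengths(channels))
  if (length(n) != 1) abort("IRF channels must share one time base", class = "flim_format_error")
  if (any(unlist(channels) < 0)) abort("IRF histograms must be non-negative", class = "flim_format_error")
  structure(list(channels = channels, bin_width_ps = bin_width_ps), class = "irf_set")
}

#' Default synthetic IRF set (200 ps FWHM Gaussian in every channel)
#' @param tb A [time_base()].
#' @param fwhm_ps,center_ps Pulse shape parameters, ps.
#' @return An `irf_set`.
#' @export
default_irfset <- function(tb = time_base(), fwhm_ps = 200, center_ps = 1000) {
  h <- simulate_irf(fwhm_ps, center_ps, tb$n_bins, tb$bin_width_ps)
  irf_set(stats::setNames(rep(list(h), 4), .flim_channels), tb$bin_width_ps)
}

#' Expected (noise-free) reconvolved decay curve
#'
#' The forward model: IRF convolved with a periodic bi-exponential decay
#' (optionally including the wrap-around tail of incomplete decays across
#' the repetition window), scaled to `n_photons` expected decay counts plus
#' the constant background.
#'
#' @param params A [decay_params()].
#' @param irf Unit-area IRF histogram.
#' @param n_photons Expected total decay photons.
#' @param bin_width_ps Bin width, ps.
#' @param wrap Include the periodic pre-excitation tail (default TRUE).
#' @return Numeric vector of expected counts per bin.
#' @export
decay_model_curve <- function(params, irf, n_photons, bin_width_ps = 48.8,
                              wrap = TRUE) {
  stopifnot(inherits(params, "decay_params"))
  b1 <- conv_irf_exp_cpp(irf, params$tau1, bin_width_ps, wrap)
  b2 <- conv_irf_exp_cpp(irf, params$tau2, bin_width_ps, wrap)
  shape <- params$a1 * b1 + params$a2 * b2
  shape <- shape / sum(shape)
  n_photons * shape + params$background_rate
}

#' Simulate a TCSPC photon-count histogram
#'
#' Poisson-sampled counts from the reconvolved bi-exponential forward model.
#'
#' @inheritParams decay_model_curve
#' @param seed Optional RNG seed.
#' @return Integer histogram; expected total ≈ `n_photons` (+ background).
#' @examples
#' irf <- simulate_irf(200, 1000)
#' y <- simulate_decay(decay_params(450, 4000), irf, 1e4, seed = 1)
#' @export
simulate_decay <- function(params, irf, n_photons, bin_width_ps = 48.8,
                           wrap = TRUE, seed = NULL) {
  if (n_photons < 0) abort("`n_photons` must be >= 0", class = "flim_param_error")
  if (!is.null(seed)) set.seed(seed)
  mu <- decay_model_curve(params, irf, n_photons, bin_width_ps, wrap)
  rpois(length(mu), mu)
}

# --- cell placement ---------------------------------------------------------

# Pixel set (0-based arr indices) of an ellipse; centres inside the ellipse.
ellipse_pixels <- function(x0, y0, a, b, angle_deg, nx, ny, grow = 0) {
  a <- a + grow; b <- b + grow
  th <- angle_deg * pi / 180
  ext <- ceiling(sqrt((a * cos(th))^2 + (b * sin(th))^2))
  eyt <- ceiling(sqrt((a * sin(th))^2 + (b * cos(th))^2))
  xs <- max(0, floor(x0 - ext)):min(nx - 1, ceiling(x0 + ext))
  ys <- max(0, floor(y0 - eyt)):min(ny - 1, ceiling(y0 + eyt))
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - x0; dy <- g$y - y0
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  g[u * u + v * v <= 1, , drop = FALSE]
}

place_cells <- function(n_cells, nx, ny, px_um, spec, base_angle,
                        max_attempts = 200 * max(1, n_cells)) {
  labels <- matrix(0L, nx, ny)
  geom <- vector("list", n_cells)
  placed <- 0L
  attempts <- 0L
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      abort(sprintf("could not place %d non-overlapping cells (density too high)", n_cells),
            class = "flim_density_error")
    d_px <- rlnorm(1, log(spec$diameter_um), spec$diameter_sdlog) / px_um
    q <- min(1, max(0.2, rnorm(1, spec$flattening_mean, spec$flattening_sd)))
    a <- d_px / 2 / sqrt(q); b <- d_px / 2 * sqrt(q)
    ang <- (base_angle + rnorm(1, 0, spec$orientation_sd_deg)) %% 180
    ext <- max(a, b)
    x0 <- runif(1, ext, nx - 1 - ext); y0 <- runif(1, ext, ny - 1 - ext)
    px <- ellipse_pixels(x0, y0, a, b, ang, nx, ny)
    if (nrow(px) < 3) next
    # 1-px clearance so neighbouring cells stay spatially distinct
    pxg <- ellipse_pixels(x0, y0, a, b, ang, nx, ny, grow = 1)
    if (any(labels[cbind(pxg$x + 1, pxg$y + 1)] > 0L)) next
    placed <- placed + 1L
    labels[cbind(px$x + 1, px$y + 1)] <- placed
    geom[[placed]] <- c(placed, x0, y0, a, b, ang, nrow(px))
  }
  gm <- do.call(rbind, geom)
  list(labels = labels,
       geometry = tibble(roi_id = as.integer(gm[, 1]), x0 = gm[, 2],
                         y0 = gm[, 3], major_px = gm[, 4], minor_px = gm[, 5],
                         angle_deg = gm[, 6], area_px = as.integer(gm[, 7])))
}

draw_cell_params <- function(spec, n_cells, patient_factor) {
  ch <- spec$channels
  if (n_cells == 0) {
    return(tibble(roi_id = integer(), channel = character(), tau1 = double(),
                  tau2 = double(), frac1 = double(), yield = double()))
  }
  m <- n_cells * 4L
  t1 <- rep(ch$tau1, n_cells) * patient_factor * exp(rnorm(m, 0, spec$tau_cv))
  t2 <- rep(ch$tau2, n_cells) * patient_factor * exp(rnorm(m, 0, spec$tau_cv))
  t2 <- pmax(t2, t1) # truncation keeps tau2 >= tau1
  f1 <- plogis(qlogis(pmin(pmax(rep(ch$frac1, n_cells), 1e-3), 1 - 1e-3)) +
                 rnorm(m, 0, spec$frac_sd))
  yl <- rlnorm(m, log(pmax(rep(ch$yield, n_cells), 1e-9)), spec$yield_sdlog)
  tibble(roi_id = rep(seq_len(n_cells), each = 4L),
         channel = rep(ch$channel, n_cells),
         tau1 = t1, tau2 = t2, frac1 = f1, yield = yl)
}

cell_shape_curve <- function(spec, channel, tau1, tau2, frac1, irf, bin_width_ps, wrap) {
  b1 <- conv_irf_exp_cpp(irf, tau1, bin_width_ps, wrap)
  b2 <- conv_irf_exp_cpp(irf, tau2, bin_width_ps, wrap)
  shape <- frac1 * b1 + (1 - frac1) * b2 # amplitudes act on the exponentials
  if (spec$melanin_frac > 0 && channel %in% c("yellow", "red")) {
    bm <- conv_irf_exp_cpp(irf, spec$melanin_tau, bin_width_ps, wrap)
    shape <- (1 - spec$melanin_frac) * shape / sum(shape) +
      spec$melanin_frac * bm / sum(bm)
  }
  shape / sum(shape)
}

#' Simulate one multispectral FLIM sample
#'
#' Places non-overlapping elliptical cells with the population's size,
#' elongation and orientation structure, draws per-cell per-channel decay
#' parameters, and renders either a full per-pixel photon-count stack
#' (`render = "image"`) or per-ROI integrated decay histograms
#' (`render = "rois"`; distributionally identical to summing per-pixel
#' draws, used for cohort-scale studies). Ground-truth ROIs and parameters
#' are returned alongside.
#'
#' @param spec A [cell_population_spec()].
#' @param n_cells Number of cells; default from `spec$density_mm2` and the
#'   field size.
#' @param image_size Image side, px.
#' @param field_size_um Field of view side, µm.
#' @param irfs An [irf_set()]; default [default_irfset()].
#' @param tb A [time_base()].
#' @param patient_id,depth_um Metadata.
#' @param patient_factor Multiplicative patient lifetime effect; drawn from
#'   the spec's random-effect distribution when `NULL`.
#' @param render `"image"` or `"rois"`.
#' @param wrap Include periodic decay wrap-around.
#' @param seed Optional RNG seed.
#' @return An object of class `flim_sample`: `stack` (or NULL), `rois`
#'   (truth `roi_set`), `geometry`, `truth_params`, `roi_decays` (tibble or
#'   NULL), `patient_id`, `class_label`, `irfs`, `tb`.
#' @export
simulate_sample <- function(spec, n_cells = NULL, image_size = 128,
                            field_size_um = 175, irfs = NULL,
                            tb = time_base(), patient_id = "P01",
                            depth_um = 60, patient_factor = NULL,
                            render = c("image", "rois"), wrap = TRUE,
                            seed = NULL) {
  render <- match.arg(render)
  stopifnot(inherits(spec, "cell_population_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(irfs)) irfs <- default_irfset(tb)
  nx <- image_size; ny <- image_size
  px_um <- field_size_um / image_size
  if (is.null(n_cells))
    n_cells <- round(spec$density_mm2 * (field_size_um / 1000)^2)
  if (is.null(patient_factor)) patient_factor <- exp(rnorm(1, 0, spec$patient_cv))
  base_angle <- runif(1, 0, 180)

  if (n_cells > 0) {
    pl <- place_cells(n_cells, nx, ny, px_um, spec, base_angle)
  } else {
    pl <- list(labels = matrix(0L, nx, ny), geometry = tibble(
      roi_id = integer(), x0 = double(), y0 = double(), major_px = double(),
      minor_px = double(), angle_deg = double(), area_px = integer()))
  }
  rois <- roi_set(pl$labels, source = "truth")
  params <- draw_cell_params(spec, n_cells, patient_factor)

  nbins <- tb$n_bins; bw <- tb$bin_width_ps
  bg_shape <- conv_irf_exp_cpp(irfs$channels[[1]], spec$background_tau, bw, wrap)
  bg_shape <- bg_shape / sum(bg_shape)

  stack <- NULL; roi_decays <- NULL
  if (render == "image") {
    chans <- vector("list", 4); names(chans) <- .flim_channels
    for (ch in .flim_channels) {
      bg_bin <- spec$background_photons_px * bg_shape + spec$dark_rate
      mu <- matrix(rep(bg_bin, each = nx * ny), nx * ny, nbins)
      if (n_cells > 0) {
        pch <- params[params$channel == ch, ]
        for (i in seq_len(n_cells)) {
          shape <- cell_shape_curve(spec, ch, pch$tau1[i], pch$tau2[i],
                                    pch$frac1[i], irfs$channels[[ch]], bw, wrap)
          lin <- which(as.vector(pl$labels) == i)
          mu[lin, ] <- mu[lin, ] + outer(rep(pch$yield[i] / length(lin), length(lin)), shape)
        }
      }
      cnt <- rpois(length(mu), mu)
      chans[[ch]] <- array(as.integer(cnt), c(nx, ny, nbins))
    }
    stack <- flim_stack(chans, bw, metadata = list(
      patient_id = patient_id, sample_id = patient_id,
      diagnosis = spec$class_label, depth_um = depth_um, context = "synthetic"))
  } else {
    nrw <- n_cells * 4L
    counts_l <- vector("list", nrw)
    photons_v <- numeric(nrw)
    areas <- setNames(rois$table$area, rois$table$roi_id)
    k <- 0L
    for (i in seq_len(n_cells)) {
      npix <- areas[[as.character(i)]]
      pch <- params[params$roi_id == i, ]
      for (ch in .flim_channels) {
        p <- pch[pch$channel == ch, ]
        shape <- cell_shape_curve(spec, ch, p$tau1, p$tau2, p$frac1,
                                  irfs$channels[[ch]], bw, wrap)
        mu <- p$yield * shape +
          npix * (spec$background_photons_px * bg_shape + spec$dark_rate)
        cnt <- rpois(nbins, mu)
        k <- k + 1L
        counts_l[[k]] <- as.integer(cnt)
        photons_v[k] <- sum(cnt)
      }
    }
    roi_decays <- tibble(roi_id = rep(seq_len(n_cells), each = 4L),
                         channel = rep(.flim_channels, max(n_cells, 0L)),
                         counts = counts_l, photons = photons_v)
    if (n_cells == 0)
      roi_decays <- tibble(roi_id = integer(), channel = character(),
                           counts = list(), photons = double())
  }
  structure(list(stack = stack, rois = rois, geometry = pl$geometry,
                 truth_params = params, roi_decays = roi_decays,
                 patient_id = patient_id, class_label = spec$class_label,
                 depth_um = depth_um, patient_factor = patient_factor,
                 irfs = irfs, tb = tb, wrap = wrap),
            class = "flim_sample")
}

#' @export
print.flim_sample <- function(x, ...) {
  cat(sprintf("<flim_sample %s: %s, %d cells, %s>\n", x$patient_id,
              x$class_label, n_rois(x$rois),
              if (is.null(x$stack)) "roi-rendered" else "image-rendered"))
  invisible(x)
}

#' Simulate a two-class patient cohort
#'
#' One sample per patient; per-patient multiplicative lifetime random
#' effects correlate ROIs within a patient. Reproducible under a fixed seed.
#'
#' @param n_normal_patients,n_bcc_patients Patients per class (≥ 1).
#' @param cells_per_patient Cells per patient sample.
#' @param spec_normal,spec_bcc Class [cell_population_spec()]s.
#' @param seed Optional RNG seed.
#' @param render `"rois"` (default; per-ROI histograms) or `"image"`.
#' @inheritParams simulate_sample
#' @return An object of class `flim_cohort` (list of `flim_sample`).
#' @examples
#' coh <- simulate_cohort(2, 2, cells_per_patient = 5, seed = 1)
#' @export
simulate_cohort <- function(n_normal_patients, n_bcc_patients,
                            cells_per_patient,
                            spec_normal = normal_skin_spec(),
                            spec_bcc = bcc_spec(), seed = NULL,
                            render = c("rois", "image"), image_size = 128,
                            field_size_um = 175, tb = time_base(),
                            irfs = NULL, wrap = TRUE) {
  render <- match.arg(render)
  if (n_normal_patients < 1 || n_bcc_patients < 1 || cells_per_patient < 1)
    abort("patient and cell counts must be >= 1", class = "flim_param_error")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(irfs)) irfs <- default_irfset(tb)
  ids <- c(sprintf("N%02d", seq_len(n_normal_patients)),
           sprintf("B%02d", seq_len(n_bcc_patients)))
  specs <- c(rep(list(spec_normal), n_normal_patients),
             rep(list(spec_bcc), n_bcc_patients))
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    samples[[i]] <- simulate_sample(
      specs[[i]], n_cells = cells_per_patient, image_size = image_size,
      field_size_um = field_size_um, irfs = irfs, tb = tb,
      patient_id = ids[i], render = render, wrap = wrap)
  }
  structure(samples, class = "flim_cohort", names = ids)
}

#' @export
print.flim_cohort <- function(x, ...) {
  cls <- vapply(x, function(s) s$class_label, "")
  cat(sprintf("<flim_cohort: %d patients (%d normal / %d bcc), %d truth ROIs>\n",
              length(x), sum(cls == "normal"), sum(cls == "bcc"),
              sum(vapply(x, function(s) n_rois(s$rois), 1L))))
  invisible(x)
}
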