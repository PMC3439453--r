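#' Bi-exponential decay model parameters
#'
#' Parameters of the two-component fluorescence decay
#' \eqn{a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}} plus a constant background
#' rate, the forward model convolved with the instrument response in both
#' simulation and fitting.
#'
#' @param tau1,tau2 Short and long lifetime components, picoseconds
#'   (`tau1 > 0`, `tau2 >= tau1`).
#' @param a1,a2 Non-negative amplitude weights, `a1 + a2 > 0`.
#' @param background_rate Constant background, counts/bin.
#' @return An object of class `decay_params`.
#' @examples
#' decay_params(450, 4000, a1 = 1, a2 = 1)
#' @export
decay_params <- function(tau1, tau2, a1 = 1, a2 = 1, background_rate = 0) {
  if (!is.numeric(tau1) || tau1 <= 0) abort("`tau1` must be > 0", class = "flim_param_error")
  if (!is.numeric(tau2) || tau2 < tau1) abort("`tau2` must be >= tau1", class = "flim_param_error")
  if (a1 < 0 || a2 < 0 || a1 + a2 <= 0) abort("amplitudes must be >= 0 with a1 + a2 > 0", class = "flim_param_error")
  if (background_rate < 0) abort("`background_rate` must be >= 0", class = "flim_param_error")
  structure(list(tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2,
                 background_rate = background_rate),
            class = "decay_params")
}

#' Cell population specification for the synthetic cohort generator
#'
#' Describes one diagnostic class: per-spectral-channel lifetime
#' distributions, photon yields, cell geometry and spatial arrangement.
#' Lifetime anchors default to values consistent with the class-separated
#' medians and histogram peaks reported for basal cell carcinoma versus
#' normal keratinocytes; dispersions are generator choices (see the methods
#' vignette).
#'
#' @param class_label `"normal"` or `"bcc"`.
#' @param channels Tibble with columns `channel`, `tau1`, `tau2` (ps),
#'   `frac1` (amplitude fraction of the short component, `a1/(a1+a2)`), and
#'   `yield` (expected photons per cell).
#' @param tau_cv Cell-level lognormal coefficient of variation applied to
#'   both lifetimes.
#' @param frac_sd Cell-level jitter of `frac1` on the logit scale.
#' @param patient_cv Lognormal SD of the per-patient multiplicative lifetime
#'   random effect.
#' @param yield_sdlog Lognormal SD of per-cell photon yields.
#' @param diameter_um,diameter_sdlog Median equivalent cell diameter (µm)
#'   and its lognormal SD.
#' @param density_mm2 Cell density, cells per mm².
#' @param flattening_mean,flattening_sd Mean and SD of the cell flattening
#'   factor (minor/major axis ratio), truncated to (0.2, 1].
#' @param orientation_sd_deg SD (degrees) of cell major-axis angles about a
#'   per-sample base orientation; small values give locally coherent,
#'   elongated-cell alignment.
#' @param background_photons_px Expected background photons per pixel
#'   (lifetime `background_tau` decay) per channel.
#' @param background_tau Background decay lifetime, ps.
#' @param dark_rate Dark counts per bin per pixel.
#' @param melanin_frac Fraction of yellow/red-channel signal given a
#'   melanin-like short lifetime (`melanin_tau`); 0 disables.
#' @param melanin_tau Lifetime of the melanin-like contaminant, ps.
#' @return An object of class `cell_population_spec`.
#' @seealso [normal_skin_spec()], [bcc_spec()]
#' @export
cell_population_spec <- function(class_label,
                                 channels,
                                 tau_cv = 0.12,
                                 frac_sd = 0.25,
                                 patient_cv = 0.08,
                                 yield_sdlog = 0.45,
                                 diameter_um = 12,
                                 diameter_sdlog = 0.18,
                                 density_mm2 = 400,
                                 flattening_mean = 0.75,
                                 flattening_sd = 0.10,
                                 orientation_sd_deg = 60,
                                 background_photons_px = 2,
                                 background_tau = 1500,
                                 dark_rate = 0.002,
                                 melanin_frac = 0,
                                 melanin_tau = 150) {
  class_label <- match.arg(class_label, c("normal", "bcc"))
  channels <- as_tibble(channels)
  stopifnot(all(c("channel", "tau1", "tau2", "frac1", "yield") %in% names(channels)),
            setequal(channels$channel, .flim_channels))
  if (any(channels$tau1 <= 0) || any(channels$tau2 < channels$tau1))
    abort("channel lifetimes must satisfy 0 < tau1 <= tau2", class = "flim_param_error")
  if (any(channels$yield < 0)) abort("photon yields must be >= 0", class = "flim_param_error")
  if (density_mm2 <= 0) abort("`density_mm2` must be > 0", class = "flim_param_error")
  structure(list(
    class_label = class_label, channels = channels,
    tau_cv = tau_cv, frac_sd = frac_sd, patient_cv = patient_cv,
    yield_sdlog = yield_sdlog, diameter_um = diameter_um,
    diameter_sdlog = diameter_sdlog, density_mm2 = density_mm2,
    flattening_mean = flattening_mean, flattening_sd = flattening_sd,
    orientation_sd_deg = orientation_sd_deg,
    background_photons_px = background_photons_px,
    background_tau = background_tau, dark_rate = dark_rate,
    melanin_frac = melanin_frac, melanin_tau = melanin_tau
  ), class = "cell_population_spec")
}

# frac1 anchors solve f*tau1 + (1-f)*tau2 = target median tau_mean per channel
.spec_channels <- function(tau1, tau2, target_mean, yield) {
  tibble(channel = .flim_channels, tau1 = tau1, tau2 = tau2,
         frac1 = (tau2 - target_mean) / (tau2 - tau1), yield = yield)
}

#' Default normal-skin population
#'
#' Per-channel lifetime anchors chosen so the amplitude-weighted mean
#' lifetimes equal the reported normal-skin medians
#' (1797/2189/1380/1036 ps in blue/green/yellow/red); mildly flattened cells
#' with incoherent orientations.
#'
#' @param ... Overrides passed to [cell_population_spec()].
#' @return A `cell_population_spec`.
#' @export
normal_skin_spec <- function(...) {
  ch <- .spec_channels(
    tau1 = c(300, 350, 300, 250),
    tau2 = c(3000, 3300, 2400, 2200),
    target_mean = c(1797, 2189, 1380, 1036),
    yield = c(3000, 8000, 5000, 2000)
  )
  defaults <- list(class_label = "normal", channels = ch,
                   flattening_mean = 0.75, orientation_sd_deg = 60)
  do.call(cell_population_spec, utils::modifyList(defaults, list(...)))
}

#' Default basal cell carcinoma population
#'
#' Lifetime anchors at the reported BCC histogram peaks where printed
#' (green τ1 = 450 ps, τ2 = 4000 ps; yellow τ2 = 3000 ps), with amplitude
#' fractions solving the reported BCC median mean lifetimes
#' (2419/2624/1908/1448 ps); elongated cells with locally coherent
#' orientations.
#'
#' @param ... Overrides passed to [cell_population_spec()].
#' @return A `cell_population_spec`.
#' @export
bcc_spec <- function(...) {
  ch <- .spec_channels(
    tau1 = c(400, 450, 400, 500),
    tau2 = c(3800, 4000, 3000, 2600),
    target_mean = c(2419, 2624, 1908, 1448),
    yield = c(3500, 7000, 5000, 3500)
  )
  defaults <- list(class_label = "bcc", channels = ch,
                   flattening_mean = 0.55, flattening_sd = 0.12,
                   orientation_sd_deg = 12)
  do.call(cell_population_spec, utils::modifyList(defaults, list(...)))
}
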