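#' Photon-count exclusion rules
#'
#' Applies the two analysis filters: (i) per-channel — ROI decay curves with
#' fewer than `min_photons` photons in a spectral channel are excluded from
#' that channel's analysis set; (ii) discriminant — ROIs with fewer than
#' `min_photons` photons in *any* spectral channel are excluded from the
#' discriminant analysis. Patients left with no discriminant-eligible ROIs
#' are flagged excluded. The boundary is inclusive: a count of exactly
#' `min_photons` is retained.
#'
#' @param fits Per-ROI × channel fit table from [fit_rois()] (needs
#'   `patient_id`, `sample_id`, `roi_id`, `channel`, `photon_count`).
#' @param min_photons Threshold, photons (default 1000).
#' @return An object of class `photon_filter`: `channel_set` (fits passing
#'   the per-channel rule), `discriminant_set` (fits of ROIs passing in all
#'   4 channels), `exclusion_log` (one row per excluded ROI-channel pair
#'   with the rule that removed it), `excluded_patients` (character vector)
#'   and `min_photons`.
#' @examples
#' # an ROI with counts (1200, 1500, 999, 2000) stays in the blue/green/red
#' # channel sets but drops out of the discriminant set
#' @export
apply_photon_filters <- function(fits, min_photons = 1000) {
  need <- c("patient_id", "sample_id", "roi_id", "channel", "photon_count")
  stopifnot(all(need %in% names(fits)))
  fits <- mutate(fits, .key = paste(.data$patient_id, .data$sample_id, .data$roi_id))
  ch_ok <- fits$photon_count >= min_photons
  channel_set <- fits[ch_ok, , drop = FALSE]

  roi_all_ok <- fits %>%
    group_by(.data$.key) %>%
    summarise(all_ok = sum(.data$photon_count >= min_photons) == 4L,
              .groups = "drop")
  disc_keys <- roi_all_ok$.key[roi_all_ok$all_ok]
  discriminant_set <- fits[fits$.key %in% disc_keys, , drop = FALSE]

  log_ch <- fits[!ch_ok, c(need)] %>% mutate(rule = "channel_min_photons")
  log_disc <- fits[!(fits$.key %in% disc_keys) & ch_ok, c(need)] %>%
    mutate(rule = "discriminant_all_channels")
  exclusion_log <- bind_rows(log_ch, log_disc) %>%
    arrange(.data$patient_id, .data$roi_id, .data$channel)

  patients <- unique(fits$patient_id)
  excluded_patients <- setdiff(patients, unique(discriminant_set$patient_id))

  structure(list(
    channel_set = select(channel_set, -".key"),
    discriminant_set = select(discriminant_set, -".key"),
    exclusion_log = exclusion_log,
    excluded_patients = excluded_patients,
    min_photons = min_photons
  ), class = "photon_filter")
}

#' @export
print.photon_filter <- function(x, ...) {
  cat(sprintf(paste0(
    "<photon_filter (>= %d photons): %d ROI-channel fits kept, %d in the\n",
    " discriminant set; %d exclusions logged; %d patient(s) excluded>\n"),
    x$min_photons, nrow(x$channel_set), nrow(x$discriminant_set),
    nrow(x$exclusion_log), length(x$excluded_patients)))
  invisible(x)
}
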