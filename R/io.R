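# On-disk formats: per-channel multi-page TIFF (pages = time bins) with a
# JSON sidecar for the time base and metadata; ROI masks as 16-bit label
# TIFF; IRFs and feature tables as CSV. All writers are deterministic.

.tiff_write_pages <- function(pages, path) {
  if (any(unlist(pages) > 65535))
    abort("counts exceed 16-bit TIFF range", class = "flim_format_error")
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                  bits.per.sample = 16L, compression = "none")
}

.tiff_read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    v <- m * 65535
    if (max(abs(v - round(v))) > 1e-6)
      abort("non-integer TIFF payload", class = "flim_format_error")
    matrix(as.integer(round(v)), nrow(m), ncol(m))
  })
}

#' Write / read a FLIM stack
#'
#' A stack directory holds one multi-page TIFF per spectral channel
#' (`blue.tif` … `red.tif`, pages = time bins) and a `metadata.json`
#' sidecar (time base, channel bands, acquisition metadata, coordinate
#' convention: pixel-centred, 0-based, row-major). The round trip is
#' lossless.
#'
#' @param stack A [flim_stack()].
#' @param path Directory to create/read.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   [flim_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- stack_dims(stack)
  for (ch in .flim_channels) {
    a <- stack$channels[[ch]]
    pages <- lapply(seq_len(d[3]), function(t) a[, , t])
    .tiff_write_pages(pages, file.path(path, paste0(ch, ".tif")))
  }
  meta <- list(format = "flimcyte-stack", version = 1L,
               n_bins = d[3], bin_width_ps = stack$bin_width_ps,
               image_size = d[1:2],
               channels = .flim_channels,
               channel_bands_nm = stack$channel_bands,
               coordinates = "pixel-centred, 0-based, row-major (y,x)",
               metadata = stack$metadata)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  mpath <- file.path(path, "metadata.json")
  if (!file.exists(mpath))
    abort("missing metadata.json sidecar", class = "flim_format_error")
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(meta$bin_width_ps))
    abort("sidecar lacks the time base (bin_width_ps)", class = "flim_format_error")
  files <- file.path(path, paste0(.flim_channels, ".tif"))
  if (!all(file.exists(files)))
    abort("a FLIM stack needs exactly 4 channel TIFFs (blue/green/yellow/red)",
          class = "flim_format_error")
  chans <- lapply(files, function(f) {
    pages <- .tiff_read_pages(f)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  })
  names(chans) <- .flim_channels
  bands <- meta$channel_bands_nm
  if (is.null(bands)) bands <- .flim_bands
  flim_stack(chans, bin_width_ps = meta$bin_width_ps, channel_bands = bands,
             metadata = as.list(meta$metadata))
}

#' Write / read an ROI label mask
#'
#' 16-bit label TIFF (0 = background). On reading, every label is checked
#' for 8-connectivity: a label whose pixels fall into several disjoint
#' components is split into one ROI per component, with a warning.
#'
#' @param roiset A [roi_set()].
#' @param path TIFF file path.
#' @param source Source tag assigned on read.
#' @return `write_roiset` returns `path` invisibly; `read_roiset` the
#'   [roi_set()].
#' @export
write_roiset <- function(roiset, path) {
  stopifnot(inherits(roiset, "roi_set"))
  .tiff_write_pages(list(roiset$labels), path)
  invisible(path)
}

#' @rdname write_roiset
#' @export
read_roiset <- function(path, source = "manual") {
  lab <- .tiff_read_pages(path)[[1]]
  ids <- sort(unique(lab[lab > 0L]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  split_any <- FALSE
  for (id in ids) {
    comp <- label_components_cpp(lab == id, 8L)
    k <- max(comp)
    if (k > 1) split_any <- TRUE
    for (c in seq_len(k)) {
      nxt <- nxt + 1L
      out[comp == c] <- nxt
    }
  }
  if (split_any)
    warn("label image contained disconnected labels; split into components")
  roi_set(out, source = source)
}

#' Write / read an IRF set as CSV
#'
#' Columns `bin`, `blue`, `green`, `yellow`, `red`; the bin width is kept in
#' a `# bin_width_ps:` comment line.
#'
#' @param irfs An [irf_set()].
#' @param path CSV path.
#' @return `write_irfset` returns `path` invisibly; `read_irfset` the
#'   [irf_set()].
#' @export
write_irfset <- function(irfs, path) {
  stopifnot(inherits(irfs, "irf_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_ps: %.10g", irfs$bin_width_ps), con)
  df <- data.frame(bin = seq_along(irfs$channels[[1]]) - 1L,
                   irfs$channels, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_irfset
#' @export
read_irfset <- function(path) {
  first <- readLines(path, n = 1)
  bw <- as.numeric(sub("^# bin_width_ps:\\s*", "", first))
  if (is.na(bw)) abort("IRF CSV lacks bin_width_ps comment", class = "flim_format_error")
  df <- utils::read.csv(path, comment.char = "#")
  irf_set(as.list(df[.flim_channels]), bin_width_ps = bw)
}

.feature_units <- function(cols) {
  unit <- function(cl) {
    if (grepl("^(tau1_|tau2_|tau_mean_)", cl)) "ps"
    else if (grepl("^photons_", cl) || cl == "photon_count") "counts"
    else if (cl == "orientation_sd" || cl == "orientation_deg") "degrees"
    else if (cl == "depth_um") "micrometres"
    else if (grepl("^(frac1_|spectral_)", cl) ||
             cl %in% c("flattening_factor", "confluency", "fraction_bcc")) "fraction"
    else if (grepl("^chi2_", cl)) "unitless (reduced chi-square)"
    else "unitless or identifier"
  }
  vapply(cols, unit, "")
}

#' Write / read the per-cell feature table
#'
#' CSV with a commented header documenting each column's unit. Missing
#' values (e.g. ROI-channel pairs removed by the photon filter, or
#' morphology of auto-segmented ROIs) are written as explicit `NA`, never
#' zeros. Duplicate `(patient_id, sample_id, roi_id)` keys are an error.
#'
#' @param records Feature tibble.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the tibble.
#' @export
write_feature_table <- function(records, path) {
  keys <- c("patient_id", "sample_id", "roi_id")
  if (all(keys %in% names(records)) &&
      anyDuplicated(records[keys]) > 0)
    abort("duplicate (patient, sample, roi) keys", class = "flim_format_error")
  con <- file(path, "w")
  on.exit(close(con))
  units <- .feature_units(names(records))
  writeLines(c("# flimcyte feature table",
               sprintf("# %s: %s", names(records), units)), con)
  utils::write.table(records, con, sep = ",", row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Per patient: truth ROI label TIFF, truth parameter CSV, and (when
#' rendered) the FLIM stack; plus a cohort `manifest.json`.
#'
#' @param cohort A `flim_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "flim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(s) {
    pdir <- file.path(dir, s$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    write_roiset(s$rois, file.path(pdir, "truth_rois.tif"))
    utils::write.csv(s$truth_params, file.path(pdir, "truth_params.csv"),
                     row.names = FALSE)
    if (!is.null(s$stack)) write_stack(s$stack, file.path(pdir, "stack"))
    list(patient_id = s$patient_id, class_label = s$class_label,
         n_cells = n_rois(s$rois), rendered = !is.null(s$stack))
  })
  jsonlite::write_json(list(format = "flimcyte-cohort", version = 1L,
                            patients = entries),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
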