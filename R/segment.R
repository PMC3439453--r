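#' Parameters of the size-tuned non-linear top-hat detector
#'
#' @param r_inner Close-vicinity disc radius, px (tune to half the expected
#'   cell diameter).
#' @param r_outer Distant-vicinity outer radius, px (default `2 * r_inner`).
#' @param inner_stat,outer_stat Rank-order statistics as quantile
#'   probabilities or the names `"median"`/`"q25"`/`"q75"`; defaults
#'   median (inner) and upper quartile (outer).
#' @param threshold Intensity threshold applied to the enhanced image.
#' @param opening_radius Disc radius of the morphological opening, px.
#' @param min_area Size sieve: regions smaller than this (px²) are removed.
#' @return An object of class `tophat_params`.
#' @export
tophat_params <- function(r_inner, r_outer = 2 * r_inner,
                          inner_stat = "median", outer_stat = "q75",
                          threshold = 0, opening_radius = 1, min_area = 0) {
  if (!(r_inner > 0 && r_inner < r_outer))
    abort("need 0 < r_inner < r_outer", class = "flim_param_error")
  if (min_area < 0) abort("`min_area` must be >= 0", class = "flim_param_error")
  as_prob <- function(s) {
    if (is.numeric(s)) return(s)
    switch(s, median = 0.5, q25 = 0.25, q75 = 0.75,
           abort("unknown rank statistic", class = "flim_param_error"))
  }
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 inner_prob = as_prob(inner_stat),
                 outer_prob = as_prob(outer_stat),
                 threshold = threshold, opening_radius = opening_radius,
                 min_area = min_area),
            class = "tophat_params")
}

disc_offsets <- function(r_min, r_max) {
  r <- ceiling(r_max)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 <= r_max^2 & d2 > r_min^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Size-tuned non-linear top-hat transform
#'
#' Enhances a pixel when its close vicinity (disc of radius `r_inner`) is
#' bright while its distant vicinity (annulus `r_inner`–`r_outer`) is dim:
#' `enhanced = max(0, inner_stat(disc) - outer_stat(annulus))`, with
#' rank-order statistics (median / upper quartile by default) making the
#' operator non-linear and robust to outlier pixels.
#'
#' @param img Numeric intensity matrix.
#' @param params A [tophat_params()].
#' @return Non-negative enhanced image, same dimensions.
#' @export
tophat_transform <- function(img, params) {
  stopifnot(inherits(params, "tophat_params"), is.matrix(img))
  if (2 * params$r_outer >= min(dim(img)))
    abort("r_outer exceeds half the image size", class = "flim_param_error")
  inner <- rank_filter_cpp(img, disc_offsets(-1, params$r_inner),
                           params$inner_prob)
  outer <- rank_filter_cpp(img, disc_offsets(params$r_inner, params$r_outer),
                           params$outer_prob)
  pmax(inner - outer, 0)
}

#' Total-intensity image of a stack
#'
#' Per-pixel photon totals summed over all spectral channels and time bins;
#' the input image for automatic segmentation.
#'
#' @param stack A [flim_stack()].
#' @return Numeric matrix.
#' @export
intensity_image <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  Reduce(`+`, lapply(stack$channels, function(a) rowSums(a, dims = 2)))
}

#' Automatic cell detection
#'
#' The fixed pipeline: top-hat transform → threshold → morphological
#' opening (disc) → 8-connected components → area sieve. The same
#' parameters are meant to be applied uniformly across all images of a run.
#'
#' @param x A [flim_stack()] (its [intensity_image()] is segmented) or a
#'   numeric intensity matrix.
#' @param params A [tophat_params()].
#' @return A [roi_set()] with `source = "auto"`.
#' @export
segment_auto <- function(x, params) {
  img <- if (inherits(x, "flim_stack")) intensity_image(x) else x
  enh <- tophat_transform(img, params)
  mask <- enh >= params$threshold & enh > 0
  if (params$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * floor(params$opening_radius) + 1, "disc")
    mask <- EBImage::opening(matrix(as.numeric(mask), nrow(mask)), brush) > 0.5
  }
  lab <- label_components_cpp(mask, 8L)
  if (params$min_area > 0 && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < params$min_area)
    lab[lab %in% drop] <- 0L
  }
  roi_set(relabel_rois(lab), source = "auto")
}

roi_pixel_sets <- function(rs) {
  lab <- rs$labels
  idx <- which(lab > 0L)
  split(idx, lab[idx])
}

#' Match detected against ground-truth ROIs
#'
#' Greedy one-to-one matching by decreasing intersection-over-union (IoU),
#' accepting pairs with IoU above the threshold.
#'
#' @param detected,truth `roi_set`s on the same image frame.
#' @param iou_threshold Minimum IoU for a match.
#' @return List: `matches` (tibble `detected_id`, `truth_id`, `iou`),
#'   `precision`, `recall`, `n_detected`, `n_truth`, `missed_truth`,
#'   `unmatched_detected`.
#' @export
match_rois <- function(detected, truth, iou_threshold = 0.2) {
  stopifnot(all(dim(detected$labels) == dim(truth$labels)))
  dp <- roi_pixel_sets(detected); tp <- roi_pixel_sets(truth)
  pairs <- list()
  for (di in names(dp)) for (ti in names(tp)) {
    inter <- length(intersect(dp[[di]], tp[[ti]]))
    if (inter == 0) next
    iou <- inter / (length(dp[[di]]) + length(tp[[ti]]) - inter)
    if (iou >= iou_threshold)
      pairs[[length(pairs) + 1]] <- tibble(detected_id = as.integer(di),
                                           truth_id = as.integer(ti), iou = iou)
  }
  pairs <- if (length(pairs)) bind_rows(pairs) %>% arrange(desc(.data$iou)) else
    tibble(detected_id = integer(), truth_id = integer(), iou = double())
  used_d <- integer(); used_t <- integer()
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$detected_id[i] %in% used_d || pairs$truth_id[i] %in% used_t) next
    keep[i] <- TRUE
    used_d <- c(used_d, pairs$detected_id[i])
    used_t <- c(used_t, pairs$truth_id[i])
  }
  m <- pairs[keep, , drop = FALSE]
  nd <- n_rois(detected); nt <- n_rois(truth)
  list(matches = m,
       precision = if (nd > 0) nrow(m) / nd else NA_real_,
       recall = if (nt > 0) nrow(m) / nt else NA_real_,
       n_detected = nd, n_truth = nt,
       missed_truth = setdiff(truth$table$roi_id, m$truth_id),
       unmatched_detected = setdiff(detected$table$roi_id, m$detected_id))
}

#' Size-tuned default detector parameters
#'
#' Convenience constructor tying the top-hat radii to the expected cell
#' diameter: `r_inner` is half the diameter (the disc then sits inside a
#' centred cell) and `r_outer = 2.5 * r_inner` (the annulus clears the
#' cell body and its immediate neighbours). The threshold is in intensity
#' units of the summed-channel image and defaults to a value suited to the
#' synthetic generator's photon budget; tune it per instrument.
#'
#' @param cell_diameter_px Expected cell diameter, px.
#' @param threshold,min_area,opening_radius See [tophat_params()].
#' @return A [tophat_params()].
#' @export
default_tophat_params <- function(cell_diameter_px = 9, threshold = 10,
                                  min_area = 12, opening_radius = 1) {
  ri <- max(2, round(cell_diameter_px / 2))
  tophat_params(r_inner = ri, r_outer = 2.5 * ri, threshold = threshold,
                min_area = min_area, opening_radius = opening_radius)
}
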