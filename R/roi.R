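#' Region-of-interest set
#'
#' A labeled cell mask: an integer label image (0 = background, k = cell k)
#' with a per-ROI geometry table (area in px², centroid in 0-based pixel
#' coordinates).
#'
#' @param labels Integer matrix of region labels.
#' @param source One of `"manual"`, `"auto"`, `"truth"`.
#' @return An object of class `roi_set` with elements `labels`, `table`
#'   (a tibble: `roi_id`, `area`, `centroid_x`, `centroid_y`) and `source`.
#' @export
roi_set <- function(labels, source = c("manual", "auto", "truth")) {
  source <- match.arg(source)
  if (!is.matrix(labels)) abort("`labels` must be a matrix", class = "flim_format_error")
  if (any(labels != round(labels)) || any(labels < 0))
    abort("label image must contain non-negative integers", class = "flim_format_error")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  tab <- if (length(ids) == 0) {
    tibble(roi_id = integer(), area = integer(),
           centroid_x = double(), centroid_y = double())
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    # 0-based pixel-centre coordinates; rows = x, cols = y
    xs <- tapply(idx[, 1] - 1, lab, mean)
    ys <- tapply(idx[, 2] - 1, lab, mean)
    ar <- tapply(lab, lab, length)
    tibble(roi_id = as.integer(names(ar)), area = as.integer(ar),
           centroid_x = as.numeric(xs), centroid_y = as.numeric(ys))
  }
  structure(list(labels = labels, table = tab, source = source),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d regions, %dx%d px, source=%s>\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels), x$source))
  invisible(x)
}

#' Number of regions in a `roi_set`
#' @param x A `roi_set`.
#' @return Integer count of labeled regions.
#' @export
n_rois <- function(x) nrow(x$table)

roi_mask <- function(roiset, roi_id) roiset$labels == roi_id

# Relabel as consecutive 1..k keeping spatial order of first occurrence.
relabel_rois <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  out <- labels
  out[] <- match(labels, ids, nomatch = 0L) # background -> 0 via nomatch? see below
  out[labels == 0L] <- 0L
  storage.mode(out) <- "integer"
  out
}
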