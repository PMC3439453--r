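#' Gabriel neighbour graph of cell centroids
#'
#' Two centroids are joined iff no third centroid lies strictly inside the
#' circle having their segment as diameter (equivalently, iff
#' \eqn{d^2(p,k) + d^2(q,k) \ge d^2(p,q)} for every other point k);
#' boundary ties keep the edge. Duplicate points are collapsed.
#'
#' @param x A `roi_set`, a 2-column matrix, or a data frame with
#'   `centroid_x`/`centroid_y` (or `x`/`y`) columns; an optional `roi_id`
#'   column names the nodes.
#' @return An object of class `gabriel_graph`: `nodes` (tibble `roi_id`,
#'   `x`, `y`) and `edges` (tibble `from`, `to`, each edge once with
#'   `from < to`).
#' @examples
#' g <- gabriel_graph(cbind(c(0, 1, 2), c(0, 0, 0)))
#' g$edges # (1,2) and (2,3); the midpoint blocks (1,3)
#' @export
gabriel_graph <- function(x) {
  if (inherits(x, "roi_set")) {
    tab <- x$table
    nodes <- tibble(roi_id = tab$roi_id, x = tab$centroid_x, y = tab$centroid_y)
  } else if (is.matrix(x)) {
    xm <- x
    nodes <- tibble(roi_id = seq_len(nrow(xm)), x = xm[, 1], y = xm[, 2])
  } else {
    x <- as_tibble(x)
    if (!"centroid_x" %in% names(x) && "x" %in% names(x))
      x <- rename(x, centroid_x = "x", centroid_y = "y")
    cx <- x$centroid_x; cy <- x$centroid_y
    nodes <- tibble(roi_id = if ("roi_id" %in% names(x)) x$roi_id else seq_len(nrow(x)),
                    x = cx, y = cy)
  }
  if (nrow(nodes) == 0) abort("need at least one centroid", class = "flim_param_error")
  nodes <- distinct(nodes, .data$x, .data$y, .keep_all = TRUE)
  n <- nrow(nodes)
  edges <- tibble(from = integer(), to = integer())
  if (n >= 2) {
    p <- as.matrix(nodes[, c("x", "y")])
    d2 <- as.matrix(stats::dist(p))^2
    res <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      others <- setdiff(seq_len(n), c(i, j))
      if (length(others) == 0 || all(d2[i, others] + d2[j, others] >= d2[i, j] - 1e-12)) {
        res[[length(res) + 1]] <- c(nodes$roi_id[i], nodes$roi_id[j])
      }
    }
    if (length(res)) {
      m <- do.call(rbind, res)
      edges <- tibble(from = as.integer(m[, 1]), to = as.integer(m[, 2]))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "gabriel_graph")
}

#' @export
print.gabriel_graph <- function(x, ...) {
  cat(sprintf("<gabriel_graph: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

gabriel_neighbours <- function(graph, roi_id) {
  e <- graph$edges
  c(e$to[e$from == roi_id], e$from[e$to == roi_id])
}

#' Equivalent ellipse of a region mask
#'
#' Second-central-moment ellipse of the pixel coordinates: axis lengths are
#' `4 * sqrt(eigenvalue)` (the convention under which a solid ellipse
#' recovers its own axes) and the orientation is the major-axis angle in
#' degrees, axial in `[0, 180)`. Degenerate (collinear-pixel) regions get a
#' 1 px minor-axis floor with a warning.
#'
#' @param mask Logical matrix (TRUE inside the region), area ≥ 3 px.
#' @return List: `major_axis`, `minor_axis` (px), `orientation_deg`.
#' @export
equivalent_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE) - 1
  if (nrow(idx) < 3) abort("region must have at least 3 pixels", class = "flim_roi_error")
  cx <- colMeans(idx)
  cc <- sweep(idx, 2, cx)
  cov <- crossprod(cc) / nrow(idx)
  e <- eigen(cov, symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  if (minor < 1) {
    warn("degenerate region: minor axis floored at 1 px")
    minor <- 1
    major <- max(major, minor)
  }
  v <- e$vectors[, 1]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(major_axis = major, minor_axis = minor, orientation_deg = ang)
}

#' Flattening factor of a region
#'
#' Ratio of minor to major axis length of the equivalent ellipse, in (0, 1]
#' (1 = circular, small = elongated). Rotation invariant.
#'
#' @param x A logical mask or the result of [equivalent_ellipse()].
#' @return Unitless ratio.
#' @export
flattening_factor <- function(x) {
  if (is.matrix(x)) x <- equivalent_ellipse(x)
  min(1, x$minor_axis / x$major_axis)
}

#' Axial circular standard deviation of orientation angles
#'
#' Angles are axial (θ and θ+180° identical); they are doubled, the mean
#' resultant length \eqn{\bar R} computed, and the angular deviation
#' \eqn{\sqrt{2(1-\bar R)}/2} returned in degrees (0° for perfectly aligned
#' axes, at most ~40.5°). `method = "naive"` returns the ordinary linear SD
#' for sensitivity checks.
#'
#' @param angles_deg Orientation angles in degrees.
#' @param method `"axial"` (default) or `"naive"`.
#' @return SD in degrees.
#' @export
axial_sd <- function(angles_deg, method = c("axial", "naive")) {
  method <- match.arg(method)
  if (length(angles_deg) <= 1) return(0)
  if (method == "naive") return(sd(angles_deg))
  phi <- 2 * angles_deg * pi / 180
  rbar <- sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
  sqrt(2 * (1 - rbar)) / 2 * 180 / pi
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Convex hull area of the pixel *extents* (each pixel contributes its 4
# corners), so a filled w x h rectangle has hull area w*h.
pixel_hull_area <- function(idx0) {
  corners <- rbind(cbind(idx0[, 1] - 0.5, idx0[, 2] - 0.5),
                   cbind(idx0[, 1] + 0.5, idx0[, 2] - 0.5),
                   cbind(idx0[, 1] - 0.5, idx0[, 2] + 0.5),
                   cbind(idx0[, 1] + 0.5, idx0[, 2] + 0.5))
  h <- grDevices::chull(corners)
  polygon_area(corners[h, , drop = FALSE])
}

#' Morphology features of every ROI
#'
#' Computes, per ROI: the flattening factor; the orientation SD (axial
#' circular SD of the major-axis angles of the cell and its Gabriel
#' neighbours; 0 with a message for isolated nodes); and the cell
#' confluency (combined area of the ROI and its Gabriel-adjacent ROIs
#' divided by the convex-hull area of their union — a packing measure,
#' near 1 for dense tilings; an isolated ROI uses its own hull).
#'
#' @param roiset A [roi_set()].
#' @param graph Optional precomputed [gabriel_graph()] of the ROI centroids.
#' @param sd_method Passed to [axial_sd()].
#' @return Tibble: `roi_id`, `major_axis_px`, `minor_axis_px`,
#'   `orientation_deg`, `flattening_factor`, `orientation_sd`, `confluency`.
#' @export
compute_morphology <- function(roiset, graph = NULL,
                               sd_method = c("axial", "naive")) {
  sd_method <- match.arg(sd_method)
  ids <- roiset$table$roi_id
  if (length(ids) == 0) {
    return(tibble(roi_id = integer(), major_axis_px = double(),
                  minor_axis_px = double(), orientation_deg = double(),
                  flattening_factor = double(), orientation_sd = double(),
                  confluency = double()))
  }
  if (is.null(graph)) graph <- gabriel_graph(roiset)
  ell <- lapply(ids, function(id) equivalent_ellipse(roi_mask(roiset, id)))
  ang <- setNames(vapply(ell, `[[`, 0, "orientation_deg"), ids)
  lab <- roiset$labels
  pix <- lapply(ids, function(id) which(lab == id, arr.ind = TRUE) - 1)
  names(pix) <- ids
  areas <- setNames(roiset$table$area, ids)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    nb <- gabriel_neighbours(graph, id)
    osd <- axial_sd(ang[as.character(c(id, nb))], method = sd_method)
    grp <- as.character(c(id, nb))
    hull <- pixel_hull_area(do.call(rbind, pix[grp]))
    tibble(roi_id = id,
           major_axis_px = ell[[i]]$major_axis,
           minor_axis_px = ell[[i]]$minor_axis,
           orientation_deg = ell[[i]]$orientation_deg,
           flattening_factor = flattening_factor(ell[[i]]),
           orientation_sd = osd,
           confluency = min(1, sum(areas[grp]) / hull))
  })
  bind_rows(rows)
}

#' Per-channel spectral contribution
#'
#' Fraction of an ROI's total detected photons falling in each of the four
#' spectral bands; sums to 1.
#'
#' @param counts Numeric vector of 4 per-channel photon counts (named or in
#'   blue/green/yellow/red order).
#' @return Named numeric vector of 4 fractions.
#' @examples
#' spectral_contribution(c(1000, 2000, 3000, 4000))
#' @export
spectral_contribution <- function(counts) {
  stopifnot(length(counts) == 4)
  if (sum(counts) <= 0) abort("total photon count must be > 0", class = "flim_param_error")
  if (is.null(names(counts))) names(counts) <- .flim_channels
  counts / sum(counts)
}

#' Assemble the per-cell feature table
#'
#' Joins the filtered spectroscopic fits (wide, one column block per
#' spectral channel), the spectral contributions, and — for manual/truth
#' ROIs — the Gabriel-graph morphology features into one record per
#' surviving ROI. For automatically segmented ROIs the morphology fields
#' are set missing (automatic detection does not give a clean cell
#' outline).
#'
#' @param filtered A `photon_filter` from [apply_photon_filters()] (its
#'   discriminant set is used) or a fit tibble.
#' @param samples A `flim_cohort`, a single `flim_sample`, or a named list
#'   of `roi_set`s keyed by `sample_id` (for morphology).
#' @param sd_method Passed to [compute_morphology()].
#' @return Tibble with identifiers (`patient_id`, `sample_id`, `roi_id`,
#'   `class_label`, `depth_um`), per-channel `tau1_*`, `tau2_*`,
#'   `tau_mean_*`, `frac1_*`, `chi2_*`, `photons_*`, `spectral_*`, and
#'   `flattening_factor`, `orientation_sd`, `confluency` (NA for auto ROIs).
#' @export
assemble_features <- function(filtered, samples = NULL,
                              sd_method = c("axial", "naive")) {
  sd_method <- match.arg(sd_method)
  fits <- if (inherits(filtered, "photon_filter")) filtered$discriminant_set else filtered
  if (nrow(fits) == 0) {
    return(tibble(patient_id = character(), sample_id = character(),
                  roi_id = integer(), class_label = character()))
  }
  wide <- fits %>%
    select(all_of(c("patient_id", "sample_id", "roi_id", "channel",
                    "class_label", "depth_um", "tau1", "tau2", "tau_mean",
                    "amplitude_fraction", "chi2_reduced", "photon_count"))) %>%
    rename(frac1 = "amplitude_fraction", chi2 = "chi2_reduced",
           photons = "photon_count") %>%
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("tau1", "tau2", "tau_mean", "frac1",
                                       "chi2", "photons"))
  ph <- as.matrix(wide[, paste0("photons_", .flim_channels)])
  spec <- ph / rowSums(ph)
  colnames(spec) <- paste0("spectral_", .flim_channels)
  wide <- bind_cols(wide, as_tibble(spec))

  morph <- NULL
  if (!is.null(samples)) {
    if (inherits(samples, "flim_sample")) samples <- list(samples)
    roisets <- lapply(samples, function(s) if (inherits(s, "roi_set")) s else s$rois)
    if (is.null(names(roisets)) || any(names(roisets) == ""))
      names(roisets) <- vapply(samples, function(s)
        if (inherits(s, "roi_set")) NA_character_ else s$patient_id, "")
    mm <- lapply(seq_along(roisets), function(j) {
      sid <- names(roisets)[j]
      rs <- roisets[[j]]
      if (is.na(sid) || rs$source == "auto") return(NULL)
      compute_morphology(rs, sd_method = sd_method) %>%
        mutate(sample_id = sid, .before = 1) %>%
        select(all_of(c("sample_id", "roi_id", "flattening_factor",
                        "orientation_sd", "confluency")))
    })
    morph <- bind_rows(mm)
  }
  if (!is.null(morph) && nrow(morph) > 0) {
    wide <- left_join(wide, morph, by = c("sample_id", "roi_id"))
  } else {
    wide$flattening_factor <- NA_real_
    wide$orientation_sd <- NA_real_
    wide$confluency <- NA_real_
  }
  wide
}
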