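#' Percent difference from a reference value
#'
#' `100 * (value - reference) / reference`, reported to one decimal — the
#' convention of the per-channel "% difference from normal" lifetime
#' comparisons.
#'
#' @param value,reference Numeric (reference must be nonzero).
#' @return Percent difference, rounded to 1 decimal.
#' @examples
#' percent_difference(2419, 1797) # 34.6
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) abort("reference must be nonzero", class = "flim_param_error")
  round(100 * (value - reference) / reference, 1)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration over all group assignments (midranks for ties) when
#' the combined sample size is at most `exact_max`; otherwise the normal
#' approximation with tie correction and continuity correction
#' (`stats::wilcox.test`).
#'
#' @param group_a,group_b Numeric samples (non-empty).
#' @param exact_max Combined-size limit for exact enumeration (default 12).
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(group_a, group_b, exact_max = 12) {
  if (length(group_a) == 0 || length(group_b) == 0)
    abort("both groups must be non-empty", class = "flim_param_error")
  n1 <- length(group_a); n <- n1 + length(group_b)
  if (n <= exact_max) {
    r <- rank(c(group_a, group_b))
    t_obs <- sum(r[seq_len(n1)])
    idx <- combn(n, n1)
    t_all <- colSums(matrix(r[idx], nrow = n1))
    dev <- abs(t_all - mean(t_all))
    return(mean(dev >= abs(t_obs - mean(t_all)) - 1e-9))
  }
  suppressWarnings(
    wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)$p.value)
}

#' Cohen's d effect size (magnitude)
#'
#' `|mean_a - mean_b| / s_pooled`, the pooled SD using (n-1) weights.
#'
#' @param group_a,group_b Numeric samples of size >= 2 each.
#' @return Unsigned effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) abort("each group needs >= 2 values", class = "flim_param_error")
  sp <- sqrt(((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2))
  abs(mean(group_a) - mean(group_b)) / sp
}

#' Mann–Whitney AUC by pair counting
#'
#' `P(a > b) + 0.5 * P(a == b)` over all pairs; the orientation is fixed as
#' the probability that a value from `group_a` (BCC) exceeds one from
#' `group_b` (normal), so AUC > 0.5 means `group_a` tends larger.
#'
#' @param group_a,group_b Numeric samples (non-empty).
#' @return AUC in `[0, 1]`.
#' @examples
#' mannwhitney_auc(c(1, 3), c(2, 4)) # 0.25
#' @export
mannwhitney_auc <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    abort("both groups must be non-empty", class = "flim_param_error")
  cmp <- outer(group_a, group_b, `>`) + 0.5 * outer(group_a, group_b, `==`)
  mean(cmp)
}

#' Group comparison report over all features
#'
#' The descriptive/inferential summary table: for every numeric feature,
#' class medians with inter-quartile ranges, the percent difference of the
#' BCC median from the normal median, the two-sided Wilcoxon rank-sum
#' p-value (computed on per-patient medians by default, or on ROI-level
#' values), the unsigned Cohen's d and the Mann–Whitney AUC (both
#' ROI-level, oriented BCC vs normal), ranked by descending AUC.
#'
#' @param records Feature table with `class_label` (and `patient_id` for
#'   the patient-median grouping).
#' @param parameters Feature columns; default all per-channel and
#'   morphology features present.
#' @param grouping Unit for the rank-sum test: `"patient_median"` (default)
#'   or `"roi_level"`.
#' @return Tibble of class `flim_group_comparison`, one row per feature:
#'   `parameter`, `median_bcc`, `iqr_lo_bcc`, `iqr_hi_bcc`, `median_normal`,
#'   `iqr_lo_normal`, `iqr_hi_normal`, `percent_difference`, `wilcoxon_p`,
#'   `cohens_d`, `auc`, `n_bcc`, `n_normal`, `degenerate` (TRUE when a
#'   group has a single observation and the IQR collapses).
#' @export
group_summaries <- function(records, parameters = NULL,
                            grouping = c("patient_median", "roi_level")) {
  grouping <- match.arg(grouping)
  if (is.null(parameters)) {
    parameters <- intersect(
      c(grep("^(tau1_|tau2_|tau_mean_|frac1_|spectral_)", names(records), value = TRUE),
        "flattening_factor", "orientation_sd", "confluency"),
      names(records))
  }
  rows <- lapply(parameters, function(p) {
    v <- records[[p]]
    ok <- !is.na(v)
    b <- v[ok & records$class_label == "bcc"]
    n <- v[ok & records$class_label == "normal"]
    if (length(b) == 0 || length(n) == 0) return(NULL)
    if (grouping == "patient_median") {
      pm <- records[ok, ] %>%
        group_by(.data$patient_id, .data$class_label) %>%
        summarise(m = median(.data[[p]]), .groups = "drop")
      wp <- wilcoxon_ranksum(pm$m[pm$class_label == "bcc"],
                             pm$m[pm$class_label == "normal"])
    } else {
      wp <- wilcoxon_ranksum(b, n)
    }
    qb <- quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    qn <- quantile(n, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(parameter = p,
           median_bcc = qb[2], iqr_lo_bcc = qb[1], iqr_hi_bcc = qb[3],
           median_normal = qn[2], iqr_lo_normal = qn[1], iqr_hi_normal = qn[3],
           percent_difference = if (qn[2] != 0) percent_difference(qb[2], qn[2]) else NA_real_,
           wilcoxon_p = wp,
           cohens_d = if (length(b) >= 2 && length(n) >= 2) cohens_d(b, n) else NA_real_,
           auc = mannwhitney_auc(b, n),
           n_bcc = length(b), n_normal = length(n),
           degenerate = length(b) < 2 || length(n) < 2)
  })
  out <- bind_rows(rows) %>% arrange(desc(.data$auc))
  class(out) <- c("flim_group_comparison", class(out))
  out
}

#' Freedman–Diaconis histogram of a feature by class
#'
#' Bin counts for plotting class-separated feature distributions; the bin
#' width is the Freedman–Diaconis choice over the pooled data.
#'
#' @param records Feature table with `class_label`.
#' @param parameter Feature column name.
#' @param binwidth Optional fixed bin width.
#' @return Tibble: `class_label`, `mid`, `count`, `density`.
#' @export
feature_histogram <- function(records, parameter, binwidth = NULL) {
  v <- records[[parameter]]
  ok <- !is.na(v)
  v <- v[ok]; cls <- records$class_label[ok]
  if (is.null(binwidth)) {
    bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    binwidth <- if (bw > 0) bw else diff(range(v)) / 30
  }
  breaks <- seq(floor(min(v) / binwidth) * binwidth, max(v) + binwidth, by = binwidth)
  out <- lapply(unique(cls), function(cl) {
    h <- hist(v[cls == cl], breaks = breaks, plot = FALSE)
    tibble(class_label = cl, mid = h$mids, count = h$counts,
           density = h$density)
  })
  bind_rows(out)
}
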