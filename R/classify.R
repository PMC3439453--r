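#' Default diagnostic feature set
#'
#' All spectroscopic per-channel features (`tau1_*`, `tau2_*`, `tau_mean_*`,
#' `frac1_*`, `spectral_*` with one spectral fraction dropped — the four sum
#' to 1 and would be collinear) plus the three morphology features when they
#' are present without missing values (they are absent for automatically
#' segmented ROIs).
#'
#' @param records Feature table from [assemble_features()].
#' @return Character vector of column names.
#' @export
default_feature_set <- function(records) {
  spectro <- grep("^(tau1_|tau2_|tau_mean_|frac1_|spectral_)", names(records),
                  value = TRUE)
  spectro <- setdiff(spectro, "spectral_red")
  morph <- c("flattening_factor", "orientation_sd", "confluency")
  morph <- morph[morph %in% names(records)]
  if (length(morph) && anyNA(records[morph])) morph <- character()
  c(spectro, morph)
}

#' Fit the PCA + LDA diagnostic model
#'
#' Features are z-scored, projected onto the first `n_components` principal
#' components (sign-fixed: the largest-magnitude loading of each component
#' is positive, for determinism), and a linear discriminant is trained on
#' the component scores. ROI training labels inherit the patient diagnosis;
#' the label noise from normal keratinocytes inside carcinoma images is an
#' accepted property of the design.
#'
#' @param records Feature table with a `class_label` column (`normal`/`bcc`)
#'   and no missing values in the selected features.
#' @param features Feature columns; default [default_feature_set()].
#' @param n_components Number of principal components retained (default 4).
#' @return An object of class `flim_classifier`.
#' @export
fit_model <- function(records, features = NULL, n_components = 4) {
  if (is.null(features)) features <- default_feature_set(records)
  stopifnot(length(features) >= 2, "class_label" %in% names(records))
  if (length(unique(records$class_label)) < 2)
    abort("both classes must be present in training data", class = "flim_param_error")
  if ("patient_id" %in% names(records)) {
    per_class <- table(distinct(records, .data$patient_id, .data$class_label)$class_label)
    if (any(per_class < 2))
      abort("need at least 2 patients per class", class = "flim_param_error")
  }
  X <- as.matrix(records[, features])
  if (anyNA(X)) abort("missing values in selected features", class = "flim_param_error")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  qr_x <- qr(scale(X, ctr, pmax(scl, 1e-12))) # LINPACK: rank with pivoting
  # rank is bounded by n-1 after centering; only flag genuine collinearity
  if (any(scl <= 1e-12) || qr_x$rank < min(ncol(X), nrow(X) - 1L)) {
    bad <- unique(c(features[scl <= 1e-12],
                    features[qr_x$pivot[seq.int(qr_x$rank + 1, length.out = ncol(X) - qr_x$rank)]]))
    abort(paste0("collinear or constant features: ", paste(bad, collapse = ", ")),
          class = "flim_collinear_error")
  }
  Z <- scale(X, ctr, scl)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- Z %*% rot
  ld <- MASS::lda(scores, grouping = factor(records$class_label,
                                            levels = c("normal", "bcc")))
  structure(list(features = features, center = ctr, scale = scl,
                 rotation = rot, lda = ld, n_components = k,
                 training_ids = if ("patient_id" %in% names(records))
                   unique(records$patient_id) else NULL),
            class = "flim_classifier")
}

#' @export
print.flim_classifier <- function(x, ...) {
  cat(sprintf("<flim_classifier: %d features -> %d PCs -> LDA>\n",
              length(x$features), x$n_components))
  invisible(x)
}

#' Predict with a fitted diagnostic model
#'
#' @param object A `flim_classifier`.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble: `.pred_class` (`normal`/`bcc`), `.pred_score`
#'   (discriminant score; positive leans bcc), `.pred_posterior_bcc`.
#' @export
predict.flim_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  Z <- scale(X, object$center, object$scale)
  scores <- Z %*% object$rotation
  pr <- stats::predict(object$lda, as.data.frame(scores))
  pm <- object$lda$means %*% object$lda$scaling
  dir <- if (pm["bcc", 1] >= pm["normal", 1]) 1 else -1
  tibble(.pred_class = as.character(pr$class),
         .pred_score = as.numeric(pr$x) * dir,
         .pred_posterior_bcc = as.numeric(pr$posterior[, "bcc"]))
}

#' Leave-one-out classification of every ROI
#'
#' Each held-out unit is classified by a model fitted without it. The
#' default unit is the single ROI, matching the procedure of classifying
#' each cell by a model trained on all others; `"patient"` holds all of a
#' patient's ROIs out together, which removes within-patient leakage but —
#' under per-patient random effects — anti-classifies null data (removing a
#' patient shifts its own class's training mean away from it), so it is
#' offered as an option, not the default.
#'
#' ROI-level LOO refits are computed exactly by rank-one downdating of the
#' feature sufficient statistics (mean, scale, covariance, class moments)
#' followed by the same standardize → PCA(k) → LDA chain, and agree with
#' brute-force refits.
#'
#' @param records Feature table from [assemble_features()].
#' @param loo_unit `"roi"` (default) or `"patient"`.
#' @param features,n_components Passed to [fit_model()].
#' @return `records` with `.pred_class` and `.pred_posterior_bcc` columns.
#' @export
loo_classify <- function(records, loo_unit = c("roi", "patient"),
                         features = NULL, n_components = 4) {
  loo_unit <- match.arg(loo_unit)
  if (is.null(features)) features <- default_feature_set(records)
  if (length(unique(records$patient_id)) < 3)
    abort("leave-one-out needs at least 3 patients", class = "flim_param_error")
  records$.pred_class <- NA_character_
  records$.pred_posterior_bcc <- NA_real_
  if (loo_unit == "patient") {
    for (u in unique(records$patient_id)) {
      hold <- records$patient_id == u
      mdl <- fit_model(records[!hold, , drop = FALSE], features = features,
                       n_components = n_components)
      p <- predict(mdl, records[hold, , drop = FALSE])
      records$.pred_class[hold] <- p$.pred_class
      records$.pred_posterior_bcc[hold] <- p$.pred_posterior_bcc
    }
    return(records)
  }
  pr <- loo_roi_fast(as.matrix(records[, features]),
                     records$class_label, n_components)
  records$.pred_class <- pr$class
  records$.pred_posterior_bcc <- pr$posterior_bcc
  records
}

# Exact ROI-level LOO of the standardize -> PCA(k) -> LDA chain via rank-one
# downdates of sufficient statistics; equivalent to refitting without row i.
loo_roi_fast <- function(X, labels, n_components) {
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X)) abort("missing values in selected features", class = "flim_param_error")
  cls <- c("normal", "bcc")
  yb <- labels == "bcc"
  Sx <- colSums(X)
  Q <- crossprod(X)
  Sc <- rbind(normal = colSums(X[!yb, , drop = FALSE]),
              bcc = colSums(X[yb, , drop = FALSE]))
  Qc <- list(normal = crossprod(X[!yb, , drop = FALSE]),
             bcc = crossprod(X[yb, , drop = FALSE]))
  nc <- c(normal = sum(!yb), bcc = sum(yb))
  out_class <- character(n)
  out_post <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    ci <- if (yb[i]) "bcc" else "normal"
    n1 <- n - 1L
    S1 <- Sx - xi
    m <- S1 / n1
    Q1 <- Q - tcrossprod(xi)
    C <- (Q1 - n1 * tcrossprod(m)) / (n1 - 1)
    sdv <- sqrt(pmax(diag(C), 0))
    if (any(sdv <= 1e-12))
      abort("collinear or constant features in LOO training set",
            class = "flim_collinear_error")
    Dv <- 1 / sdv
    R <- C * tcrossprod(Dv)
    e <- eigen(R, symmetric = TRUE)
    k <- min(n_components, p)
    rot <- e$vectors[, seq_len(k), drop = FALSE]
    flip <- apply(rot, 2, function(v) { s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s })
    rot <- sweep(rot, 2, flip, `*`)
    # class moments of the z-scores projected to the components
    nci <- nc; nci[ci] <- nci[ci] - 1L
    W <- matrix(0, p, p)
    mu <- list()
    for (cl in cls) {
      Scl <- Sc[cl, ]; Qcl <- Qc[[cl]]
      if (cl == ci) { Scl <- Scl - xi; Qcl <- Qcl - tcrossprod(xi) }
      mcl <- Scl / nci[cl]
      mu[[cl]] <- drop(crossprod(rot, Dv * (mcl - m)))
      W <- W + (Qcl - nci[cl] * tcrossprod(mcl))
    }
    Wz <- (W * tcrossprod(Dv)) / (n1 - 2)
    Sp <- crossprod(rot, Wz %*% rot)
    wv <- solve(Sp, mu$bcc - mu$normal)
    ti <- drop(crossprod(rot, Dv * (xi - m)))
    score <- sum((ti - (mu$bcc + mu$normal) / 2) * wv) +
      log(nci["bcc"] / nci["normal"])
    out_class[i] <- if (score > 0) "bcc" else "normal"
    out_post[i] <- stats::plogis(score)
  }
  list(class = out_class, posterior_bcc = out_post)
}

#' Per-patient fraction of BCC-classified cells
#'
#' @param predictions Output of [loo_classify()].
#' @param excluded_patients Patients with no usable ROIs (e.g. from
#'   [apply_photon_filters()]); reported with `excluded = TRUE`.
#' @return Tibble of class `patient_summary`: `patient_id`, `diagnosis`,
#'   `n_rois_used`, `fraction_bcc`, `excluded`.
#' @export
patient_fractions <- function(predictions, excluded_patients = character()) {
  out <- predictions %>%
    group_by(.data$patient_id) %>%
    summarise(diagnosis = .data$class_label[1],
              n_rois_used = dplyr::n(),
              fraction_bcc = mean(.data$.pred_class == "bcc"),
              .groups = "drop") %>%
    mutate(excluded = FALSE)
  if (length(excluded_patients)) {
    out <- bind_rows(out, tibble(patient_id = excluded_patients,
                                 diagnosis = NA_character_,
                                 n_rois_used = 0L, fraction_bcc = NA_real_,
                                 excluded = TRUE))
  }
  arrange(out, .data$patient_id)
}

#' Patient-level ROC curve and AUC
#'
#' AUC by Mann–Whitney pair counting on the per-patient BCC fractions
#' (ties count one half); curve points from all observed thresholds with
#' the inclusive `fraction >= threshold` convention.
#'
#' @param summaries Output of [patient_fractions()] (excluded patients are
#'   dropped).
#' @return Object of class `flim_roc`: `auc`, `curve` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `n_bcc`, `n_normal`.
#' @export
roc_auc_over_patients <- function(summaries) {
  s <- filter(summaries, !.data$excluded)
  b <- s$fraction_bcc[s$diagnosis == "bcc"]
  n <- s$fraction_bcc[s$diagnosis == "normal"]
  if (length(b) == 0 || length(n) == 0)
    abort("both classes must be present", class = "flim_param_error")
  auc <- mannwhitney_auc(b, n)
  th <- sort(unique(c(0, s$fraction_bcc, 1 + 1e-9)))
  curve <- tibble(threshold = th,
                  sensitivity = vapply(th, function(t) mean(b >= t), 0),
                  specificity = vapply(th, function(t) mean(n < t), 0))
  structure(list(auc = auc, curve = curve, n_bcc = length(b),
                 n_normal = length(n)),
            class = "flim_roc")
}

#' @export
print.flim_roc <- function(x, ...) {
  cat(sprintf("<flim_roc: AUC %.3f (%d bcc vs %d normal patients)>\n",
              x$auc, x$n_bcc, x$n_normal))
  invisible(x)
}

#' Sensitivity and specificity at a BCC-fraction threshold
#'
#' A patient is called BCC iff their fraction of BCC-classified cells is
#' `>= threshold` (inclusive, default 30%).
#'
#' @param summaries Output of [patient_fractions()].
#' @param threshold Fraction threshold in `[0, 1]`.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `tp`, `fn`, `tn`, `fp`.
#' @export
sens_spec_at_threshold <- function(summaries, threshold = 0.30) {
  s <- filter(summaries, !.data$excluded)
  isb <- s$diagnosis == "bcc"
  call_bcc <- s$fraction_bcc >= threshold
  tibble(threshold = threshold,
         sensitivity = if (any(isb)) mean(call_bcc[isb]) else NA_real_,
         specificity = if (any(!isb)) mean(!call_bcc[!isb]) else NA_real_,
         tp = sum(call_bcc & isb), fn = sum(!call_bcc & isb),
         tn = sum(!call_bcc & !isb), fp = sum(call_bcc & !isb))
}

#' Segmentation-free whole-image classification
#'
#' Integrates each sample's whole-image decay per spectral channel, fits the
#' bi-exponential model, and feeds the resulting one-record-per-image
#' features through the same PCA + LDA leave-one-out chain, with the
#' patient fraction computed over images. For roi-rendered samples the
#' "image" is the union of the sample's ROI decays.
#'
#' @param cohort A `flim_cohort`.
#' @param n_components,threshold As in the segmented analysis.
#' @return List: `features`, `predictions`, `summaries`, `roc`,
#'   `sens_spec`.
#' @export
classify_unsegmented <- function(cohort, n_components = 4, threshold = 0.30) {
  stopifnot(inherits(cohort, "flim_cohort"))
  rows <- lapply(cohort, function(s) {
    bw <- s$tb$bin_width_ps
    fits <- lapply(.flim_channels, function(ch) {
      y <- if (!is.null(s$stack)) {
        full <- matrix(TRUE, stack_dims(s$stack)[1], stack_dims(s$stack)[2])
        integrate_roi_decay(s$stack, full, ch)$counts
      } else {
        d <- s$roi_decays[s$roi_decays$channel == ch, ]
        if (nrow(d) == 0) return(NULL)
        as.integer(Reduce(`+`, d$counts))
      }
      fit_biexp(y, s$irfs$channels[[ch]], bin_width_ps = bw, wrap = s$wrap,
                fit_shift = FALSE)
    })
    names(fits) <- .flim_channels
    ph <- vapply(fits, function(f) as.numeric(f$photon_count), 0)
    vals <- lapply(.flim_channels, function(ch) {
      f <- fits[[ch]]
      setNames(c(f$tau1, f$tau2, f$tau_mean, f$amplitude_fraction),
               paste0(c("tau1_", "tau2_", "tau_mean_", "frac1_"), ch))
    })
    sp <- setNames(as.numeric(spectral_contribution(ph)),
                   paste0("spectral_", .flim_channels))
    tibble(patient_id = s$patient_id, sample_id = s$patient_id,
           roi_id = 0L, class_label = s$class_label,
           !!!unlist(vals), !!!sp)
  })
  feats <- bind_rows(rows)
  preds <- loo_classify(feats, loo_unit = "roi",
                        n_components = n_components)
  summ <- patient_fractions(preds)
  roc <- roc_auc_over_patients(summ)
  list(features = feats, predictions = preds, summaries = summ, roc = roc,
       sens_spec = sens_spec_at_threshold(summ, threshold))
}
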