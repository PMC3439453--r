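#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
dplyr::`%>%`

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (lifetimes in ps).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("tau1", "tau2", "a1", "a2", "amplitude_fraction",
                  "tau_mean", "background", "shift_ps"),
         estimate = c(x$tau1, x$tau2, x$a1, x$a2, x$amplitude_fraction,
                      x$tau_mean, x$background, x$shift_ps))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(chi2_reduced = x$chi2_reduced, photon_count = x$photon_count,
         converged = x$converged, status = x$status)
}

#' Tidy a diagnostic classifier
#'
#' @param x A `flim_classifier`.
#' @param ... Unused.
#' @return Tibble of feature loadings per retained principal component and
#'   the component's linear-discriminant weight.
#' @method tidy flim_classifier
#' @export
tidy.flim_classifier <- function(x, ...) {
  rot <- x$rotation
  ld <- setNames(as.numeric(x$lda$scaling), colnames(rot))
  out <- as_tibble(rot, rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
  out$ld_weight <- ld[out$component]
  out
}

#' @rdname tidy.flim_classifier
#' @method glance flim_classifier
#' @export
glance.flim_classifier <- function(x, ...) {
  tibble(n_features = length(x$features), n_components = x$n_components,
         n_training_patients = length(x$training_ids))
}

#' Tidy a patient-level ROC
#'
#' @param x A `flim_roc`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `sensitivity`, `specificity`).
#' @method tidy flim_roc
#' @export
tidy.flim_roc <- function(x, ...) x$curve

#' @rdname tidy.flim_roc
#' @method glance flim_roc
#' @export
glance.flim_roc <- function(x, ...) {
  tibble(auc = x$auc, n_bcc = x$n_bcc, n_normal = x$n_normal)
}
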