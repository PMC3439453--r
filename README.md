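# flimcyte

Cell-level analysis of multispectral multiphoton fluorescence lifetime
(FLIM) images of skin, aimed at discriminating basal cell carcinoma (BCC)
from normal keratinocytes — with a synthetic-data generator that stands in
for clinical images, so every stage of the pipeline is testable end to end.

**Who it is for.** Researchers working with time-correlated single photon
counting (TCSPC) FLIM of tissue who want a reproducible, scriptable version
of the standard cell-level workflow: per-pixel lifetime maps, ROI-level
bi-exponential reconvolution fits, automatic cell detection, spatial
morphology features, and a per-patient diagnostic read-out.

## The model at the core

Each pixel (or cell ROI) is a 256-bin photon-arrival histogram across four
spectral bands (blue 360–425, green 425–515, yellow 515–620, red
620–655 nm). The decay model is a two-component exponential reconvolved
with the instrument response, with periodic wrap-around of incomplete
decays across the 12.5 ns repetition window:

    I(t) = IRF ⊛ [a₁·exp(−t/τ₁) + a₂·exp(−t/τ₂)] + b,   counts ~ Poisson

fitted by variable projection (lifetimes by grid + Nelder–Mead, amplitudes
and background by constrained linear solve), with the amplitude-weighted
mean lifetime τₘ = (a₁τ₁ + a₂τ₂)/(a₁ + a₂) as the summary statistic.
Downstream, each cell becomes a feature record (per-channel τ₁, τ₂, τₘ,
amplitude fraction, spectral contribution; Gabriel-graph flattening,
orientation SD, confluency), the records are z-scored, projected onto the
first 4 principal components, classified normal/BCC by linear discriminant
analysis under leave-one-out, and each patient is summarized by the
fraction of their cells called BCC (patient called BCC when ≥ 30%).

## A worked example

```r
library(flimcyte)

# a small two-class cohort: 4 patients per class, 15 cells each
coh   <- simulate_cohort(4, 4, cells_per_patient = 15, seed = 11)
fits  <- fit_rois(coh)                      # per-ROI x channel biexp fits
filt  <- apply_photon_filters(fits)         # 1000-photon exclusion rules
rec   <- assemble_features(filt, coh)       # one record per surviving cell
preds <- loo_classify(rec)                  # leave-one-out PCA+LDA
summ  <- patient_fractions(preds, filt$excluded_patients)
roc_auc_over_patients(summ)
#> <flim_roc: AUC 1.000 (4 bcc vs 4 normal patients)>
sens_spec_at_threshold(summ, 0.30)
#> # A tibble: 1 × 7
#>   threshold sensitivity specificity    tp    fn    tn    fp
#>       <dbl>       <dbl>       <dbl> <int> <int> <int> <int>
#> 1       0.3           1           1     4     0     4     0

head(group_summaries(rec)[, c("parameter", "median_bcc", "median_normal",
                              "percent_difference", "auc")], 4)
#>   parameter       median_bcc median_normal percent_difference   auc
#> 1 tau1_red              524.          257.              104.  0.972
#> 2 tau_mean_yellow      1818.         1433.               26.9 0.891
#> 3 tau_mean_red         1425.         1116.               27.7 0.877
#> 4 tau_mean_blue        2301.         1779.               29.3 0.873
```

At this toy scale the classes separate completely (AUC 1.0); the group
table shows the simulated lifetime contrasts — e.g. BCC mean lifetimes
longer in every channel — ranked by per-parameter Mann–Whitney AUC.

Image-rendered samples drive the segmentation and imaging paths:

```r
s   <- simulate_sample(bcc_spec(), n_cells = 20, render = "image", seed = 5)
det <- segment_auto(s$stack, default_tophat_params())   # top-hat detector
match_rois(det, s$rois)$recall
img <- make_flim_image(s$stack, "green", s$irfs)        # per-pixel lifetimes
autoplot(img)
```

An end-to-end run (`run_pipeline(list(seed = 1), "out/")`) writes the
cohort, fit/feature tables, per-patient summaries, ROC points and a
`metrics.json` into a reproducible run directory; the same stages are
reachable from a shell via `inst/cli/flimcyte.R`.

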