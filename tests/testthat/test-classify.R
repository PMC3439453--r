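test_that("the PCA+LDA model separates well-separated clouds and not permuted labels", {
  rec <- make_gaussian_records(separation = 3, seed = 1)
  m <- fit_model(rec, features = paste0("feat", 1:6))
  pr <- predict(m, rec)
  expect_gt(mean(pr$.pred_class == rec$class_label), 0.95)

  set.seed(2)
  rec_perm <- rec
  rec_perm$class_label <- sample(rec$class_label)
  # permuting destroys the patient/class link; accuracy collapses to chance
  rec_perm$patient_id <- paste0(rec_perm$class_label, seq_len(nrow(rec_perm)) %% 4)
  m0 <- fit_model(rec_perm, features = paste0("feat", 1:6))
  acc0 <- mean(predict(m0, rec_perm)$.pred_class == rec_perm$class_label)
  expect_lt(abs(acc0 - 0.5), 0.15)

  rec_dup <- rec
  rec_dup$feat6 <- rec_dup$feat5
  err <- tryCatch(fit_model(rec_dup, features = paste0("feat", 1:6)),
                  error = function(e) e)
  expect_s3_class(err, "flim_collinear_error")
  expect_match(conditionMessage(err), "feat") # names the offending column
  expect_error(fit_model(dplyr::filter(rec, class_label == "bcc"),
                         features = paste0("feat", 1:6)),
               class = "flim_param_error")
})

test_that("the retained projection has exactly the requested components", {
  rec <- make_gaussian_records(separation = 1, n_features = 8, seed = 3)
  m <- fit_model(rec, features = paste0("feat", 1:8), n_components = 4)
  expect_equal(ncol(m$rotation), 4)
  expect_equal(glance(m)$n_components, 4)
  td <- tidy(m)
  expect_setequal(unique(td$component), paste0("PC", 1:4))
})

test_that("ROI-level LOO equals brute-force refitting and patient mode is leak-free", {
  rec <- make_gaussian_records(n_patients_per_class = 3, rois_per_patient = 8,
                               separation = 2, seed = 4)
  feats <- paste0("feat", 1:6)
  fast <- loo_classify(rec, loo_unit = "roi", features = feats)
  for (i in c(1, 9, 25, 48)) {
    m <- fit_model(rec[-i, ], features = feats)
    expect_equal(fast$.pred_class[i], predict(m, rec[i, ])$.pred_class)
  }
  # LOO hygiene (patient mode): the model scoring a held-out patient is
  # provably independent of that patient's data — its predictions equal
  # those of a model fitted with the patient absent, even after the
  # patient's features are perturbed
  hold <- rec$patient_id == "B01"
  m_wo <- fit_model(rec[!hold, ], features = feats)
  rec2 <- rec
  rec2[hold, feats] <- rec2[hold, feats] + 3
  pert <- loo_classify(rec2, loo_unit = "patient", features = feats)
  expect_identical(pert$.pred_class[hold],
                   predict(m_wo, rec2[hold, ])$.pred_class)
})

test_that("perfectly separable cohorts classify every ROI correctly", {
  rec <- make_gaussian_records(n_patients_per_class = 4, rois_per_patient = 10,
                               separation = 8, seed = 5)
  pred <- loo_classify(rec, features = paste0("feat", 1:6))
  expect_equal(mean(pred$.pred_class == pred$class_label), 1)
  # a single-ROI patient is still classified
  rec1 <- dplyr::bind_rows(rec, dplyr::mutate(rec[1, ], patient_id = "N99",
                                              sample_id = "N99"))
  pred1 <- loo_classify(rec1, features = paste0("feat", 1:6))
  expect_false(is.na(pred1$.pred_class[nrow(pred1)]))
})

test_that("identical class distributions give chance-level patient fractions", {
  rec <- make_gaussian_records(n_patients_per_class = 10, rois_per_patient = 20,
                               separation = 0, seed = 6)
  pred <- loo_classify(rec, features = paste0("feat", 1:6))
  summ <- patient_fractions(pred)
  auc <- roc_auc_over_patients(summ)$auc
  expect_gt(auc, 0.2)
  expect_lt(auc, 0.8)
  expect_gt(sd(summ$fraction_bcc), 0) # fractions spread around chance
})

test_that("patient fractions count exactly and track exclusions", {
  pred <- tibble::tibble(patient_id = rep(c("A", "B"), c(10, 4)),
                         class_label = rep(c("bcc", "normal"), c(10, 4)),
                         .pred_class = c(rep("bcc", 3), rep("normal", 7),
                                         rep("normal", 4)))
  s <- patient_fractions(pred, excluded_patients = "C")
  expect_equal(s$fraction_bcc[s$patient_id == "A"], 0.30)
  expect_equal(sum(s$n_rois_used), nrow(pred))
  expect_true(s$excluded[s$patient_id == "C"])
  expect_equal(s$n_rois_used[s$patient_id == "C"], 0L)
})

test_that("patient-level AUC is Mann-Whitney pair counting with curve endpoints", {
  s <- tibble::tibble(patient_id = letters[1:4],
                      diagnosis = c("normal", "normal", "bcc", "bcc"),
                      n_rois_used = 10L,
                      fraction_bcc = c(0.1, 0.2, 0.8, 0.9), excluded = FALSE)
  r <- roc_auc_over_patients(s)
  expect_equal(r$auc, 1.0)
  s2 <- s; s2$fraction_bcc <- rep(0.4, 4)
  expect_equal(roc_auc_over_patients(s2)$auc, 0.5)

  set.seed(9)
  s3 <- tibble::tibble(patient_id = as.character(1:20),
                       diagnosis = rep(c("normal", "bcc"), 10),
                       n_rois_used = 5L,
                       fraction_bcc = round(runif(20), 1), excluded = FALSE)
  b <- s3$fraction_bcc[s3$diagnosis == "bcc"]
  n <- s3$fraction_bcc[s3$diagnosis == "normal"]
  expect_equal(roc_auc_over_patients(s3)$auc, oracle_auc(b, n))
  expect_equal(roc_auc_over_patients(s3)$auc,
               suppressMessages(as.numeric(pROC::auc(
                 pROC::roc(s3$diagnosis, s3$fraction_bcc, levels = c("normal", "bcc"),
                           direction = "<")))))
})

test_that("threshold rule is inclusive and hits the degenerate endpoints", {
  s <- tibble::tibble(patient_id = letters[1:4],
                      diagnosis = c("normal", "normal", "bcc", "bcc"),
                      n_rois_used = 10L,
                      fraction_bcc = c(0.0, 0.30, 0.30, 0.9), excluded = FALSE)
  at30 <- sens_spec_at_threshold(s, 0.30)
  expect_equal(at30$sensitivity, 1.0) # 0.30 is called bcc (inclusive)
  expect_equal(at30$specificity, 0.5)
  expect_equal(sens_spec_at_threshold(s, 0)$sensitivity, 1.0)
  t2 <- sens_spec_at_threshold(s, 1.5)
  expect_equal(t2$sensitivity, 0.0)
  expect_equal(t2$specificity, 1.0)
})

test_that("segmentation-free whole-image analysis is consistent and discriminates", {
  coh <- simulate_cohort(6, 6, 10, seed = 31, render = "image",
                         image_size = 64, field_size_um = 87.5)
  # the whole-image decay equals an all-pixels ROI integration
  s1 <- coh[[1]]
  full <- matrix(TRUE, 64, 64)
  d <- integrate_roi_decay(s1$stack, full, "green")
  expect_equal(d$counts, as.integer(apply(s1$stack$channels$green, 3, sum)))

  u <- classify_unsegmented(coh)
  expect_gt(u$roc$auc, 0.9)
  expect_equal(nrow(u$features), length(coh))
})
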