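test_that("percent differences reproduce the published per-channel values", {
  expect_identical(percent_difference(2419, 1797), 34.6) # blue
  expect_identical(percent_difference(2624, 2189), 19.9) # green
  expect_identical(percent_difference(1908, 1380), 38.3) # yellow
  expect_identical(percent_difference(1448, 1036), 39.8) # red
  expect_identical(percent_difference(1234, 1234), 0)
  expect_error(percent_difference(1, 0), class = "flim_param_error")
})

test_that("exact rank-sum p equals full enumeration on all small splits", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    n1 <- sample(2:(n - 2), 1)
    v <- sample(c(rnorm(n - 2), rnorm(1), rnorm(1))) # may contain ties below
    if (rep %% 3 == 0) v[2] <- v[1] # force ties sometimes
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_equal(wilcoxon_ranksum(a, b), oracle_wilcoxon_exact(a, b))
  }
  expect_equal(wilcoxon_ranksum(c(3, 3, 3), c(3, 3, 3)), 1.0)
  p <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(p, oracle_wilcoxon_exact(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(p, 0.1) # 2/20 assignments as extreme
  expect_error(wilcoxon_ranksum(numeric(), 1:3), class = "flim_param_error")
})

test_that("large-sample rank-sum approximation tracks a permutation oracle", {
  set.seed(12)
  a <- rnorm(200, 0.15)
  b <- rnorm(200)
  p_approx <- wilcoxon_ranksum(a, b)
  p_perm <- oracle_wilcoxon_perm(a, b, nperm = 1e5)
  expect_lt(abs(p_approx - p_perm) / p_perm, 0.05)
})

test_that("Cohen's d matches hand arithmetic and simulation", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 1)), 0)
  expect_equal(cohens_d(c(0, 0, 1, 1), c(1, 1, 2, 2)), sqrt(3))
  set.seed(13)
  d <- cohens_d(rnorm(1e4), rnorm(1e4, 1))
  expect_lt(abs(d - 1), 0.05)
  expect_error(cohens_d(1, c(1, 2)), class = "flim_param_error")
})

test_that("Mann-Whitney AUC equals pair enumeration with fixed orientation", {
  expect_equal(mannwhitney_auc(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_equal(mannwhitney_auc(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(mannwhitney_auc(c(1, 3), c(2, 4)), 0.25)
  set.seed(14)
  for (rep in 1:10) {
    a <- sample(1:8, 6, replace = TRUE)
    b <- sample(1:8, 9, replace = TRUE)
    expect_identical(mannwhitney_auc(a, b), oracle_auc(a, b))
    # complementarity under swapped groups (ties counted half on both sides)
    expect_equal(mannwhitney_auc(a, b) + mannwhitney_auc(b, a), 1)
  }
})

test_that("group summaries rank features by AUC and flag degenerate groups", {
  set.seed(15)
  rec <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:8), each = 10),
    class_label = rep(c("normal", "bcc"), each = 40),
    tau_mean_blue = rnorm(80, rep(c(1797, 2419), each = 40), 150),
    tau_mean_green = rnorm(80, rep(c(2189, 2250), each = 40), 150),
    flattening_factor = runif(80))
  gs <- group_summaries(rec)
  expect_equal(gs$parameter[1], "tau_mean_blue") # strongest separation first
  expect_true(all(diff(gs$auc) <= 0))
  expect_true(all(gs$iqr_lo_bcc <= gs$median_bcc & gs$median_bcc <= gs$iqr_hi_bcc))
  pd <- gs$percent_difference[gs$parameter == "tau_mean_blue"]
  expect_lt(abs(pd - 34.6), 10)

  # roi-level and patient-median groupings both run
  gs2 <- group_summaries(rec, grouping = "roi_level")
  expect_equal(nrow(gs2), nrow(gs))

  single <- tibble::tibble(patient_id = c("a", "b"),
                           class_label = c("normal", "bcc"),
                           tau_mean_blue = c(1800, 2400))
  gs3 <- group_summaries(single, parameters = "tau_mean_blue")
  expect_true(gs3$degenerate)
})

test_that("histogram binning covers the data with positive-width bins", {
  rec <- tibble::tibble(class_label = rep(c("normal", "bcc"), each = 200),
                        v = c(rnorm(200, 0), rnorm(200, 2)))
  h <- feature_histogram(rec, "v")
  expect_setequal(unique(h$class_label), c("normal", "bcc"))
  expect_equal(sum(h$count), 400)
})
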