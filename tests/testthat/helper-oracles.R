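# Independent brute-force oracles used to check the package's implementations.

# Gabriel graph by the literal definition: edge (i,j) iff no third point lies
# strictly inside the circle whose diameter is the segment ij.
oracle_gabriel_edges <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(), ncol = 2)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      cx <- (pts[i, 1] + pts[j, 1]) / 2
      cy <- (pts[i, 2] + pts[j, 2]) / 2
      r2 <- ((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2) / 4
      blocked <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if ((pts[k, 1] - cx)^2 + (pts[k, 2] - cy)^2 < r2 - 1e-9) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) edges <- rbind(edges, c(i, j))
    }
  }
  edges
}

# AUC by explicit double-loop pair enumeration.
oracle_auc <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# Exact two-sided rank-sum p by enumerating every assignment of labels.
oracle_wilcoxon_exact <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  n <- length(r)
  sets <- utils::combn(n, n1)
  stat <- apply(sets, 2, function(s) sum(r[s]))
  obs <- sum(r[seq_len(n1)])
  mean(abs(stat - mean(stat)) >= abs(obs - mean(stat)) - 1e-9)
}

# Monte-Carlo permutation rank-sum p (two-sided on the rank-sum statistic).
oracle_wilcoxon_perm <- function(a, b, nperm = 1e5) {
  n1 <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n1)])
  stat <- replicate(nperm, sum(r[sample.int(length(r), n1)]))
  mean(abs(stat - mean(stat)) >= abs(obs - mean(stat)) - 1e-9)
}

# Greedy IoU matching, written directly over pixel sets.
oracle_greedy_match <- function(det_lab, tru_lab, iou_min = 0.2) {
  dids <- setdiff(sort(unique(as.vector(det_lab))), 0)
  tids <- setdiff(sort(unique(as.vector(tru_lab))), 0)
  cand <- data.frame(d = integer(), t = integer(), iou = double())
  for (d in dids) for (t in tids) {
    dp <- which(det_lab == d); tp <- which(tru_lab == t)
    i <- length(intersect(dp, tp))
    if (i > 0) {
      iou <- i / length(union(dp, tp))
      if (iou >= iou_min) cand <- rbind(cand, data.frame(d = d, t = t, iou = iou))
    }
  }
  cand <- cand[order(-cand$iou), ]
  taken_d <- c(); taken_t <- c(); out <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (cand$d[i] %in% taken_d || cand$t[i] %in% taken_t) next
    out <- rbind(out, cand[i, ])
    taken_d <- c(taken_d, cand$d[i]); taken_t <- c(taken_t, cand$t[i])
  }
  out
}

# Rasterised shapes for morphology tests.
make_disc_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- expand.grid(x = 1:n, y = 1:n)
  m <- matrix(FALSE, n, n)
  m[cbind(g$x, g$y)] <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  m
}

make_rect_mask <- function(n, w, h, angle_deg = 0) {
  c0 <- (n + 1) / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(x = 1:n, y = 1:n)
  u <- (g$x - c0) * cos(th) + (g$y - c0) * sin(th)
  v <- -(g$x - c0) * sin(th) + (g$y - c0) * cos(th)
  m <- matrix(FALSE, n, n)
  m[cbind(g$x, g$y)] <- abs(u) <= w / 2 & abs(v) <= h / 2
  m
}

# Small fast populations for cohort-level tests.
fast_normal_spec <- function(...) normal_skin_spec(...)
fast_bcc_spec <- function(...) bcc_spec(...)

# A "bcc-labelled" copy of the normal population (null separation).
null_bcc_spec <- function() {
  s <- normal_skin_spec()
  s$class_label <- "bcc"
  s
}

# Synthetic feature records with patient structure, for classifier tests
# that do not need the FLIM forward model.
make_gaussian_records <- function(n_patients_per_class = 4, rois_per_patient = 10,
                                  separation = 3, n_features = 6, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cl in c("normal", "bcc")) {
    mu <- if (cl == "bcc") separation else 0
    for (p in seq_len(n_patients_per_class)) {
      pid <- sprintf("%s%02d", toupper(substr(cl, 1, 1)), p)
      pe <- rnorm(1, 0, 0.3)
      X <- matrix(rnorm(rois_per_patient * n_features, mu + pe), rois_per_patient)
      colnames(X) <- paste0("feat", seq_len(n_features))
      rows[[length(rows) + 1]] <- tibble::as_tibble(X) |>
        dplyr::mutate(patient_id = pid, sample_id = pid,
                      roi_id = dplyr::row_number(), class_label = cl)
    }
  }
  dplyr::bind_rows(rows)
}
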