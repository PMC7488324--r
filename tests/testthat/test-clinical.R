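test_that("tertile labeling splits ordered durations at the boundary order statistics", {
  lab <- tertile_labels(1:9)
  expect_equal(lab$lower_cutoff, 3)
  expect_equal(lab$upper_cutoff, 7)
  expect_equal(lab$labels$label,
               c(rep("non-responder", 3), rep("unlabeled", 3),
                 rep("responder", 3)))
  # shuffled input labels by value, not position
  set.seed(1)
  d <- sample(1:12)
  lab2 <- tertile_labels(d)
  expect_equal(sum(lab2$labels$label == "responder"), 4)
  expect_equal(sum(lab2$labels$label == "non-responder"), 4)
  expect_true(all(lab2$labels$duration_months[
    lab2$labels$label == "responder"] >
      lab2$labels$duration_months[lab2$labels$label == "unlabeled"]))
})

test_that("ties at a cutoff resolve toward the middle group", {
  d <- c(1, 2, 3, 3, 5, 6, 7, 8, 9)
  lab <- tertile_labels(d)
  expect_equal(sum(lab$labels$label == "non-responder"), 2)
  expect_true(all(lab$labels$label[d == 3] == "unlabeled"))
})

test_that("degenerate and undersized duration vectors are handled", {
  expect_warning(lab <- tertile_labels(rep(5, 12)), "unlabeled")
  expect_true(all(lab$labels$label == "unlabeled"))
  expect_error(tertile_labels(1:8), class = "dconet_error")
  expect_error(tertile_labels(c(1:8, -1)), class = "dconet_error")
})

# Cohort where one gene marks the long-benefit patients.
pfs_cohort <- function(seed = 1, n = 60, hr = 3) {
  set.seed(seed)
  m <- matrix(rbinom(n * 15, 1, 0.12), n, 15,
              dimnames = list(sprintf("p%03d", seq_len(n)),
                              sprintf("g%02d", 1:15)))
  m[, "g01"] <- rbinom(n, 1, 0.4)
  am <- alteration_matrix(m)
  carrier <- unclass(am)[, "g01"] == 1
  scale <- 6 * ifelse(carrier, 1, hr^(-1 / 1.2))
  dur <- rweibull(n, 1.2, scale)
  list(am = am,
       outcomes = tibble::tibble(patient_id = rownames(m),
                                 duration_months = pmax(dur, 0.05),
                                 event = 1L),
       carrier = carrier)
}

test_that("the continuous pipeline recovers a survival-linked driver", {
  coh <- pfs_cohort(seed = 42)
  lab <- tertile_labels(coh$outcomes$duration_months,
                        coh$outcomes$patient_id)
  fit <- fit_continuous(coh$am, lab, n_permutations = 80, seed = 3)
  expect_true("g01" %in%
                fit$diffd$gene[fit$diffd$resp_diffd])
  expect_true("g01" %in% fit$networks$Resp$nodes$gene)
  # middle-third patients are scored but never trained on
  expect_equal(nrow(fit$scores), nrow(coh$am))
  trained <- fit$bundle$combined$sample_id
  middle <- lab$labels$patient_id[lab$labels$label == "unlabeled"]
  expect_length(intersect(trained, middle), 0)
  # empty extreme group errors
  lab_bad <- lab
  lab_bad$labels$label[lab_bad$labels$label == "responder"] <- "unlabeled"
  expect_error(fit_continuous(coh$am, lab_bad, seed = 1),
               class = "dconet_ineligible_arm_error")
})

test_that("confidence thresholds respect the FDR bound", {
  # perfectly separated scores: zero FDR on both sides
  scores <- c(seq(-1, -0.2, length.out = 10), seq(0.2, 1, length.out = 10))
  labels <- c(rep("non-responder", 10), rep("responder", 10))
  th <- select_confidence_thresholds(scores, labels)
  expect_equal(th$fdr_upper, 0)
  expect_equal(th$fdr_lower, 0)
  expect_lte(th$lower, th$upper)
  expect_equal(th$n_confident, 20)

  # a single mislabeled outlier forces the threshold past it
  scores2 <- c(scores, 1.5)
  labels2 <- c(labels, "non-responder")
  th2 <- select_confidence_thresholds(scores2, labels2, max_fdr = 0.30)
  expect_lte(th2$fdr_upper, 0.30)
  # brute-force check: the chosen upper threshold is the least extreme
  # positive candidate meeting the bound
  cand <- sort(unique(scores2[scores2 > 0]))
  ok <- vapply(cand, function(t) {
    sel <- scores2 >= t
    sum(sel) > 0 &&
      sum(labels2[sel] == "non-responder") / sum(sel) <= 0.30
  }, logical(1))
  expect_equal(th2$upper, min(cand[ok]))
})

test_that("random scores often yield no confident calls", {
  n_sentinel <- 0
  for (s in 1:20) {
    set.seed(s)
    scores <- stats::rnorm(80)
    labels <- sample(rep(c("responder", "non-responder"), 40))
    th <- suppressMessages(
      select_confidence_thresholds(scores, labels, max_fdr = 0.10))
    if (is.na(th$upper) && is.na(th$lower)) n_sentinel <- n_sentinel + 1
  }
  expect_gte(n_sentinel, 4)
})

test_that("raising the FDR bound never shrinks coverage", {
  set.seed(9)
  scores <- stats::rnorm(60) + rep(c(0.8, -0.8), 30)
  labels <- rep(c("responder", "non-responder"), 30)
  bounds <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  cov <- vapply(bounds, function(b) {
    suppressMessages(
      select_confidence_thresholds(scores, labels, max_fdr = b))$n_confident
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("the log-rank statistic matches exhaustive risk-set tabulation", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1L, 6)
  group <- c("a", "b", "a", "b", "a", "b")
  ev <- survival_evaluation(group, time, event, min_group = 3)
  oracle <- oracle_logrank(time, event, group)
  expect_equal(ev$logrank_chisq, oracle$chisq, tolerance = 1e-9)
  expect_equal(ev$logrank_p, oracle$p, tolerance = 1e-9)
})

test_that("survival evaluation reports medians, censoring and the score effect", {
  set.seed(11)
  n <- 60
  group <- rep(c("responder", "non-responder"), each = n / 2)
  time <- rweibull(n, 1.2, ifelse(group == "responder", 12, 4))
  event <- rbinom(n, 1, 0.9)
  score <- ifelse(group == "responder", 1, -1) + stats::rnorm(n, 0, 0.3)
  ev <- survival_evaluation(group, time, event, scores = score)
  expect_lt(ev$logrank_p, 0.01)
  med <- ev$medians
  expect_gt(med$median_months[med$group == "responder"],
            med$median_months[med$group == "non-responder"])
  expect_lt(ev$cox_coef, 0) # higher score, lower hazard
  # a fully censored group reports its median as not reached
  ev2 <- survival_evaluation(group, time,
                             ifelse(group == "responder", 0L, 1L))
  expect_true(is.na(
    ev2$medians$median_months[ev2$medians$group == "responder"]))
  expect_error(survival_evaluation(rep("a", 10), time[1:10], event[1:10]),
               class = "dconet_error")
})
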