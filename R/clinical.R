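# Adaptation to continuous clinical outcomes: extreme-tertile labeling of
# treatment durations, the standard binary pipeline on the two extreme
# groups, FDR-bounded confidence thresholds on the combined score, and
# survival evaluation of the predicted groups.

#' Extreme-tertile labels from treatment durations
#'
#' Partitions patients into three equally sized groups (up to rounding)
#' by treatment duration: the shortest third are labeled non-responders,
#' the longest third responders, and the middle third stays unlabeled.
#' Cutoffs are the boundary order statistics; patients tied with a cutoff
#' value resolve toward the middle (unlabeled) group.
#'
#' @param durations Positive numeric vector, months; length >= 9.
#' @param ids Optional identifiers aligned to `durations`.
#' @return A list of class `tertile_labeling` with `lower_cutoff`,
#'   `upper_cutoff`, and `labels` (tibble: `patient_id`,
#'   `duration_months`, `label`).
#' @export
tertile_labels <- function(durations, ids = NULL) {
  n <- length(durations)
  if (n < 9) {
    stop_dconet("at least 9 patients are required for tertile labeling",
                "dconet_input_error")
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop_dconet("durations must be positive and finite", "dconet_input_error")
  }
  ids <- ids %||% as.character(seq_len(n))
  third <- floor(n / 3)
  s <- sort(durations)
  lower_cutoff <- s[third]
  upper_cutoff <- s[n - third + 1]
  label <- dplyr::case_when(
    durations < lower_cutoff ~ "non-responder",
    durations > upper_cutoff ~ "responder",
    .default = "unlabeled"
  )
  # Ranks beat strict inequalities only when the cutoff value is unique;
  # ties at a cutoff stay in the middle group by construction above, but
  # untied boundary patients must be labeled.
  ord <- order(durations)
  r <- integer(n); r[ord] <- seq_len(n)
  unique_low <- sum(durations == lower_cutoff) == 1
  unique_high <- sum(durations == upper_cutoff) == 1
  if (unique_low) label[r <= third] <- "non-responder"
  if (unique_high) label[r > n - third] <- "responder"
  if (all(label == "unlabeled")) {
    warn("all durations tie: every patient is unlabeled")
  }
  structure(
    list(lower_cutoff = lower_cutoff, upper_cutoff = upper_cutoff,
         labels = tibble::tibble(patient_id = ids,
                                 duration_months = durations,
                                 label = label)),
    class = "tertile_labeling"
  )
}

#' @export
print.tertile_labeling <- function(x, ...) {
  cat(sprintf("<tertile_labeling> cutoffs %.3g / %.3g months: %d non-resp, %d unlabeled, %d resp\n",
              x$lower_cutoff, x$upper_cutoff,
              sum(x$labels$label == "non-responder"),
              sum(x$labels$label == "unlabeled"),
              sum(x$labels$label == "responder")))
  invisible(x)
}

#' Fit the DCO pipeline on extreme outcome groups
#'
#' Runs differential-driver selection, pair selection, network assembly
#' and classifier training on the responder (longest-benefit) and
#' non-responder (shortest-benefit) thirds only; middle-third patients
#' never enter a training fold but receive combined scores from the
#' final per-flavor models.
#'
#' @param am An [alteration_matrix()] with one row per patient.
#' @param labeling A `tertile_labeling` from [tertile_labels()].
#' @param treatment_id Identifier for the treatment under study.
#' @param n_permutations,swap_multiplier,seed Null-model controls, see
#'   [build_rewiring_null()].
#' @param prob_threshold,min_count,min_rate Selection thresholds, see
#'   [select_diff_drivers()].
#' @param coordinates Optional gene coordinates for linkage annotation.
#' @param ... Passed on to [train_treatment_model()] (e.g. `tune`,
#'   `hyper`).
#' @return A list with `bundle` (the `treatment_model_bundle` on the
#'   extreme groups), `networks`, `diffd`, `pairs`, and `scores` (tibble
#'   of combined scores for all patients, including unlabeled ones).
#' @export
fit_continuous <- function(am, labeling, treatment_id = "continuous",
                           n_permutations = 1000, swap_multiplier = 10,
                           seed = 1, prob_threshold = 0.95, min_count = 2,
                           min_rate = 0.05, coordinates = NULL, ...) {
  stopifnot(inherits(labeling, "tertile_labeling"))
  lab <- labeling$labels
  extreme <- lab[lab$label != "unlabeled", , drop = FALSE]
  response <- tibble::tibble(sample_id = extreme$patient_id,
                             response = extreme$label)
  if (!arm_eligible(response)) {
    stop_dconet("each extreme group needs at least 5 patients",
                "dconet_ineligible_arm_error")
  }
  am_extreme <- alteration_matrix(
    unclass(am)[extreme$patient_id, , drop = FALSE])
  diffd <- select_diff_drivers(am_extreme, response,
                               prob_threshold = prob_threshold,
                               min_count = min_count, min_rate = min_rate)
  null <- build_rewiring_null(am_extreme, n_permutations = n_permutations,
                              swap_multiplier = swap_multiplier, seed = seed)
  pairs <- select_pairs(am_extreme, response, null = null,
                        prob_threshold = prob_threshold,
                        min_count = min_count, min_rate = min_rate)
  networks <- build_dco_networks(diffd, pairs, treatment_id,
                                 coordinates = coordinates)
  bundle <- train_treatment_model(am_extreme, response, networks,
                                  treatment_id, seed = seed, ...)
  scores <- predict_samples(bundle, am)
  list(bundle = bundle, networks = networks, diffd = diffd, pairs = pairs,
       scores = dplyr::left_join(scores,
                                 lab[, c("patient_id", "label")],
                                 by = dplyr::join_by("sample_id" ==
                                                       "patient_id")))
}

#' Score samples with a trained model bundle
#'
#' Applies the three final flavor classifiers to any alteration matrix
#' and combines them with the LOOCV balanced-accuracy weights.
#'
#' @param bundle A `treatment_model_bundle`.
#' @param am An [alteration_matrix()]; genes missing from a flavor's
#'   feature list are treated as unaltered.
#' @return A tibble: `sample_id`, per-flavor probabilities, `wcomb`,
#'   `pred_class`.
#' @export
predict_samples <- function(bundle, am) {
  stopifnot(inherits(bundle, "treatment_model_bundle"))
  mat <- unclass(am)
  flavor_out <- lapply(bundle$flavors, function(fl) {
    if (is.null(fl$model)) {
      return(list(prob = rep(NA_real_, nrow(mat)), pred = rep(NA, nrow(mat))))
    }
    X <- matrix(0L, nrow(mat), length(fl$feature_genes),
                dimnames = list(rownames(mat), fl$feature_genes))
    shared <- intersect(fl$feature_genes, colnames(mat))
    X[, shared] <- mat[, shared]
    prob <- predict_prob(fl$model, X)
    list(prob = prob, pred = ifelse(prob >= 0.5, 1, -1))
  })
  wcomb <- combine_flavor_scores(
    flavor_out$General$pred, flavor_out$General$prob,
    bundle$flavors$General$bacc,
    flavor_out$Resp$pred, flavor_out$Resp$prob, bundle$flavors$Resp$bacc,
    flavor_out$NonResp$pred, flavor_out$NonResp$prob,
    bundle$flavors$NonResp$bacc
  )
  tibble::tibble(
    sample_id = rownames(mat),
    prob_general = flavor_out$General$prob,
    prob_resp = flavor_out$Resp$prob,
    prob_nonresp = flavor_out$NonResp$prob,
    wcomb = wcomb,
    pred_class = sign(wcomb)
  )
}

#' FDR-bounded confidence thresholds on the combined score
#'
#' Scans candidate thresholds over the labeled leave-one-out scores,
#' independently per side: the response threshold is the least extreme
#' score cutoff whose predicted responders (labeled patients with score
#' above it) contain at most `max_fdr` false responders, and
#' symmetrically below for non-response. Unlabeled patients never enter
#' the FDR computation.
#'
#' @param scores Numeric combined scores of the labeled patients.
#' @param labels `"responder"`/`"non-responder"` truth per score.
#' @param max_fdr Maximum tolerated false discovery rate per side
#'   (default 0.30).
#' @return A list of class `confidence_thresholds`: `upper`, `lower`,
#'   `fdr_upper`, `fdr_lower`, `n_confident`; a side with no attainable
#'   threshold reports `NA` (no confident calls on that side).
#' @export
select_confidence_thresholds <- function(scores, labels, max_fdr = 0.30) {
  stopifnot(length(scores) == length(labels))
  truth <- encode_labels(labels)
  ok <- is.finite(scores)
  scores <- scores[ok]; truth <- truth[ok]
  # A confident response call must at least be a response prediction
  # (positive combined score), and symmetrically for non-response, so the
  # candidate cutoffs are the observed scores of the matching sign. This
  # keeps the two call regions disjoint (upper > 0 > lower) and mirrors
  # the sign convention of the combined score.
  cand_up <- sort(unique(scores[scores > 0]))
  upper <- NA_real_; fdr_upper <- NA_real_
  for (t in cand_up) {
    sel <- scores >= t
    fdr <- sum(truth[sel] == 0) / sum(sel)
    if (fdr <= max_fdr) {
      upper <- t; fdr_upper <- fdr
      break
    }
  }
  cand_lo <- sort(unique(scores[scores < 0]), decreasing = TRUE)
  lower <- NA_real_; fdr_lower <- NA_real_
  for (t in cand_lo) {
    sel <- scores <= t
    fdr <- sum(truth[sel] == 1) / sum(sel)
    if (fdr <= max_fdr) {
      lower <- t; fdr_lower <- fdr
      break
    }
  }
  n_conf <- sum(!is.na(upper) & scores >= upper) +
    sum(!is.na(lower) & scores <= lower)
  if (is.na(upper) && is.na(lower)) {
    inform("select_confidence_thresholds: no confident calls attainable")
  }
  structure(
    list(upper = upper, lower = lower, fdr_upper = fdr_upper,
         fdr_lower = fdr_lower, max_fdr = max_fdr, n_confident = n_conf),
    class = "confidence_thresholds"
  )
}

#' @export
print.confidence_thresholds <- function(x, ...) {
  cat(sprintf("<confidence_thresholds> response > %s (FDR %s), non-response < %s (FDR %s); %d confident calls\n",
              format(x$upper), format(round(x$fdr_upper, 3)),
              format(x$lower), format(round(x$fdr_lower, 3)),
              x$n_confident))
  invisible(x)
}

#' Survival comparison of predicted response groups
#'
#' Kaplan-Meier median time-to-event per predicted group, the two-group
#' log-rank test, and a Cox proportional-hazards fit of the event hazard
#' on the continuous combined score.
#'
#' @param groups Predicted group per patient (e.g. `"responder"` /
#'   `"non-responder"`); exactly two distinct values, each with at least
#'   `min_group` members.
#' @param durations Follow-up durations (months).
#' @param events Event indicator (1 = progressed, 0 = censored).
#' @param scores Optional continuous scores for the Cox fit; when
#'   absent the Cox component is skipped.
#' @param min_group Minimum per-group size (default 5).
#' @return A list of class `survival_evaluation`: `logrank_chisq`,
#'   `logrank_p`, `medians` (tibble per group; `NA` = not reached),
#'   `cox_coef`, `cox_hr`, `cox_p`.
#' @export
survival_evaluation <- function(groups, durations, events, scores = NULL,
                                min_group = 5) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) != 2 || any(tab < min_group)) {
    stop_dconet(sprintf("need exactly 2 predicted groups with >= %d members",
                        min_group), "dconet_input_error")
  }
  surv <- survival::Surv(durations, events)
  sd <- survival::survdiff(surv ~ groups)
  logrank_chisq <- unname(sd$chisq)
  logrank_p <- stats::pchisq(logrank_chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ groups)
  med <- summary(fit)$table
  medians <- tibble::tibble(
    group = sub("^groups=", "", rownames(med)),
    n = as.integer(med[, "records"]),
    median_months = as.numeric(med[, "median"])
  )
  cox_coef <- cox_hr <- cox_p <- NA_real_
  if (!is.null(scores)) {
    cx <- survival::coxph(surv ~ scores)
    cox_coef <- unname(stats::coef(cx))
    cox_hr <- exp(cox_coef)
    cox_p <- summary(cx)$coefficients[1, "Pr(>|z|)"]
  }
  structure(
    list(logrank_chisq = logrank_chisq, logrank_p = logrank_p,
         medians = medians, cox_coef = cox_coef, cox_hr = cox_hr,
         cox_p = cox_p),
    class = "survival_evaluation"
  )
}

#' @export
print.survival_evaluation <- function(x, ...) {
  cat(sprintf("<survival_evaluation> log-rank chisq %.3f (p = %.3g)\n",
              x$logrank_chisq, x$logrank_p))
  print(x$medians)
  if (!is.na(x$cox_coef)) {
    cat(sprintf("Cox on score: coef %.3f (HR %.3f, p = %.3g)\n",
                x$cox_coef, x$cox_hr, x$cox_p))
  }
  invisible(x)
}

#' @describeIn survival_evaluation per-group medians as a tibble.
#' @param x A `survival_evaluation`.
#' @param ... Unused.
#' @export
tidy.survival_evaluation <- function(x, ...) x$medians

#' @describeIn survival_evaluation one-row test summary.
#' @export
glance.survival_evaluation <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
                 cox_coef = x$cox_coef, cox_hr = x$cox_hr, cox_p = x$cox_p)
}
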