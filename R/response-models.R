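# Per-treatment drug-response classifiers on DCO features: gradient-boosted
# trees (xgboost backend), tuned by repeated stratified cross-validation,
# evaluated by leave-one-out, and combined across the three network flavors
# with balanced-accuracy weights.

#' Feature matrix of a DCO network
#'
#' One binary column per network gene (sorted lexicographically for
#' determinism), one row per sample. Edges are deliberately not encoded:
#' the boosting backend models pairwise feature interactions natively, so
#' co-occurrence information is exploited without explicit edge features.
#'
#' @param am An [alteration_matrix()].
#' @param network A `dco_network` (or a character vector of genes).
#' @return An integer matrix, samples by genes; zero columns when the
#'   network is empty.
#' @export
build_features <- function(am, network) {
  genes <- if (inherits(network, "dco_network")) {
    network_genes(network)
  } else {
    sort(unique(as.character(network)))
  }
  genes <- intersect(genes, colnames(am))
  unclass(am)[, genes, drop = FALSE]
}

#' The hyperparameter grid searched during tuning
#'
#' 100 trees throughout; depth 1-7, learning rate 0.2-1, L2 leaf
#' regularization 1-10, discretized as depth {1..7} x learning rate
#' {0.2, 0.4, 0.6, 0.8, 1} x L2 {1, 3, 5, 10}.
#'
#' @return A tibble with columns `max_depth`, `learning_rate`, `l2`.
#' @export
default_hyperparameter_grid <- function() {
  tidyr::expand_grid(max_depth = 1:7,
                     learning_rate = c(0.2, 0.4, 0.6, 0.8, 1),
                     l2 = c(1, 3, 5, 10))
}

#' Default classifier hyperparameters used when tuning is skipped
#' @return A named list with `max_depth`, `learning_rate`, `l2`, `n_trees`.
#' @export
default_hyperparameters <- function() {
  list(max_depth = 3, learning_rate = 0.4, l2 = 3, n_trees = 100)
}

# Single xgboost fit. Labels are 1 = response, 0 = non-response internally;
# the package-level class encoding {1, -1} is applied at prediction time.
fit_gbm <- function(X, y01, hyper, seed = 1) {
  params <- list(
    objective = "binary:logistic",
    max_depth = hyper$max_depth,
    eta = hyper$learning_rate,
    lambda = hyper$l2,
    base_score = 0.5,
    nthread = 1,
    seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(X, label = y01)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hyper$n_trees %||% 100, verbose = 0)
}

predict_prob <- function(model, X) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(X)))
}

make_stratified_folds <- function(y01, k, seed) {
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    fold <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    train_ok <- vapply(seq_len(k), function(f) {
      length(unique(y01[fold != f])) == 2
    }, logical(1))
    if (all(train_ok)) return(fold)
  }
  stop_dconet("cannot stratify folds with both classes in every training split",
              "dconet_input_error")
}

#' Tune boosting hyperparameters by repeated stratified cross-validation
#'
#' Scores every grid point by the mean validation AUC over `iterations`
#' repeats of stratified `folds`-fold cross-validation and returns the
#' maximizer. Ties are broken toward the simpler model: smaller depth,
#' then smaller learning rate, then larger L2 penalty.
#'
#' @param X Binary feature matrix (samples x genes).
#' @param labels Character (`"responder"`/`"non-responder"`) or numeric
#'   (1/-1) labels aligned to rows of `X`.
#' @param grid Hyperparameter grid, default
#'   [default_hyperparameter_grid()].
#' @param folds Number of folds (default 5).
#' @param iterations Number of repeats (default 30).
#' @param seed Integer seed.
#' @param n_trees Trees per model (default 100).
#' @return A list with the chosen `max_depth`, `learning_rate`, `l2`,
#'   `n_trees`, and the achieved `mean_auc`.
#' @export
tune_hyperparameters <- function(X, labels, grid = default_hyperparameter_grid(),
                                 folds = 5, iterations = 30, seed = 1,
                                 n_trees = 100) {
  y01 <- encode_labels(labels)
  if (length(y01) < 10) {
    stop_dconet("at least 10 samples are required for tuning",
                "dconet_input_error")
  }
  if (length(unique(y01)) < 2) {
    stop_dconet("both classes must be present", "dconet_input_error")
  }
  fold_sets <- lapply(seq_len(iterations), function(i) {
    make_stratified_folds(y01, folds, seed * 1000 + i)
  })
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    hyper <- list(max_depth = grid$max_depth[g],
                  learning_rate = grid$learning_rate[g],
                  l2 = grid$l2[g], n_trees = n_trees)
    fold_aucs <- unlist(lapply(fold_sets, function(fold) {
      vapply(seq_len(folds), function(f) {
        tr <- fold != f
        m <- fit_gbm(X[tr, , drop = FALSE], y01[tr], hyper, seed = seed)
        auc_rank(predict_prob(m, X[!tr, , drop = FALSE]), y01[!tr])
      }, numeric(1))
    }))
    mean(fold_aucs, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-aucs, grid$max_depth, grid$learning_rate, -grid$l2)
  best <- ord[1]
  list(max_depth = grid$max_depth[best],
       learning_rate = grid$learning_rate[best],
       l2 = grid$l2[best], n_trees = n_trees,
       mean_auc = aucs[best])
}

encode_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("responder", "non-responder"))
    if (length(bad) > 0) {
      stop_dconet("labels must be responder/non-responder or 1/-1",
                  "dconet_input_error")
    }
    as.integer(labels == "responder")
  } else {
    if (!all(labels %in% c(1, -1, 0))) {
      stop_dconet("numeric labels must be 1 (response) or -1 (non-response)",
                  "dconet_input_error")
    }
    as.integer(labels == 1)
  }
}

#' Balanced accuracy of binary predictions
#'
#' Mean of sensitivity (recall on responders) and specificity (recall on
#' non-responders).
#'
#' @param truth,predicted Vectors in class encoding 1 (response) /
#'   -1 (non-response), or `"responder"`/`"non-responder"`.
#' @return Balanced accuracy in `[0, 1]`; `NA` if a class is absent from
#'   `truth`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  t01 <- encode_labels(truth)
  p01 <- encode_labels(predicted)
  sens <- mean(p01[t01 == 1] == 1)
  spec <- mean(p01[t01 == 0] == 0)
  (sens + spec) / 2
}

#' Leave-one-out cross-validation of a boosted classifier
#'
#' Each sample is predicted by a model trained on the remaining `n - 1`;
#' the out-of-fold class probabilities, predicted classes (1/-1), the
#' balanced accuracy over the held-out predictions, and the mean feature
#' importance (gain) across folds are returned.
#'
#' @inheritParams tune_hyperparameters
#' @param hyper Hyperparameter list (see [default_hyperparameters()]).
#' @return A list with `predictions` (tibble: `sample_id`,
#'   `prob_response`, `pred_class`, `truth`), `bacc`, and `importance`
#'   (tibble: `gene`, `importance`).
#' @export
loocv <- function(X, labels, hyper = default_hyperparameters(), seed = 1) {
  y01 <- encode_labels(labels)
  n <- nrow(X)
  if (n < 10) {
    stop_dconet("at least 10 samples are required for LOOCV",
                "dconet_input_error")
  }
  if (length(unique(y01)) < 2) {
    stop_dconet("both classes must be present", "dconet_input_error")
  }
  probs <- numeric(n)
  imp_acc <- setNames(numeric(ncol(X)), colnames(X))
  for (i in seq_len(n)) {
    m <- fit_gbm(X[-i, , drop = FALSE], y01[-i], hyper, seed = seed)
    probs[i] <- predict_prob(m, X[i, , drop = FALSE])
    imp <- tryCatch(xgboost::xgb.importance(model = m), error = function(e) NULL)
    if (!is.null(imp) && nrow(imp) > 0) {
      imp_acc[imp$Feature] <- imp_acc[imp$Feature] + imp$Gain
    }
  }
  pred_class <- ifelse(probs >= 0.5, 1, -1)
  truth <- ifelse(y01 == 1, 1, -1)
  list(
    predictions = tibble::tibble(
      sample_id = rownames(X) %||% as.character(seq_len(n)),
      prob_response = probs,
      pred_class = pred_class,
      truth = truth
    ),
    bacc = balanced_accuracy(truth, pred_class),
    importance = tibble::tibble(gene = names(imp_acc),
                                importance = unname(imp_acc) / n)
  )
}

#' Combine the three flavor classifiers into a weighted score
#'
#' The general classifier contributes its balanced accuracy times the
#' predicted-class probability, signed by the predicted class (positive
#' for response, negative for non-response). The responder-network
#' classifier contributes only when it predicts response (positively);
#' the non-responder-network classifier only when it predicts
#' non-response (negatively). A flavor without a trained model (`NA`
#' balanced accuracy) contributes 0.
#'
#' @param pred_general,pred_resp,pred_nonresp Predicted classes (1/-1).
#' @param prob_general,prob_resp,prob_nonresp Probability of the
#'   *response* class from each classifier.
#' @param bacc_general,bacc_resp,bacc_nonresp LOOCV balanced accuracies
#'   used as weights.
#' @return The combined score; its sign is the combined predicted class
#'   (0 = no call).
#' @export
combine_flavor_scores <- function(pred_general, prob_general, bacc_general,
                                  pred_resp, prob_resp, bacc_resp,
                                  pred_nonresp, prob_nonresp, bacc_nonresp) {
  z <- function(x) ifelse(is.na(x), 0, x)
  general <- z(bacc_general) *
    (z(pred_general == 1) * z(prob_general) -
       z(pred_general == -1) * (1 - z(prob_general)))
  resp <- z(bacc_resp) * z(pred_resp == 1) * z(prob_resp)
  nonresp <- z(bacc_nonresp) * z(pred_nonresp == -1) * (1 - z(prob_nonresp))
  general + resp - nonresp
}

#' Combine gene-level biomarker calls into a weighted score
#'
#' Sum of the per-arm balanced accuracies of the altered response
#' biomarkers minus the same sum over altered non-response biomarkers.
#' Duplicate (gene, direction) records are collapsed before summation. A
#' sample with no altered biomarker scores 0 and is flagged not
#' applicable.
#'
#' @param am An [alteration_matrix()].
#' @param biomarkers Tibble with columns `gene`, `direction`
#'   (`response`/`non-response`) and `bacc` (per-arm balanced accuracy of
#'   the single-gene prediction).
#' @return A tibble with `sample_id`, `wcomb_bmk`, `applicable`.
#' @export
combine_biomarker_scores <- function(am, biomarkers) {
  bm <- dplyr::distinct(biomarkers, .data$gene, .data$direction,
                        .keep_all = TRUE)
  known <- bm$gene %in% colnames(am)
  if (any(!known)) {
    inform(sprintf("combine_biomarker_scores: %d biomarker genes absent from the matrix (ignored)",
                   sum(!known)), class = "dconet_join_note")
    bm <- bm[known, , drop = FALSE]
  }
  mat <- unclass(am)
  score <- rep(0, nrow(mat))
  hits <- rep(0L, nrow(mat))
  for (i in seq_len(nrow(bm))) {
    s <- mat[, bm$gene[i]]
    sign <- if (bm$direction[i] == "response") 1 else -1
    score <- score + sign * bm$bacc[i] * s
    hits <- hits + s
  }
  tibble::tibble(sample_id = rownames(mat), wcomb_bmk = unname(score),
                 applicable = unname(hits > 0))
}

#' Per-gene biomarker balanced accuracies in a treatment arm
#'
#' Each biomarker gene predicts response (or non-response, per its
#' direction) exactly when altered; the balanced accuracy of that rule
#' over the full arm is the biomarker's weight.
#'
#' @param am An [alteration_matrix()].
#' @param response Data frame with `sample_id`, `response`.
#' @param catalog Biomarker catalog tibble (see
#'   [read_biomarker_catalog()]), already restricted to the arm's drug
#'   family.
#' @return The catalog rows found in the matrix, with a `bacc` column.
#' @export
biomarker_arm_bacc <- function(am, response, catalog) {
  grp <- response_groups(am, response)
  arm <- c(grp$responders, grp$nonresponders)
  truth <- ifelse(arm %in% grp$responders, 1, -1)
  keep <- catalog$gene %in% colnames(am)
  if (any(!keep)) {
    inform(sprintf("biomarker_arm_bacc: %d catalog genes absent from the matrix (ignored)",
                   sum(!keep)), class = "dconet_join_note")
  }
  cat2 <- catalog[keep, , drop = FALSE]
  mat <- unclass(am)
  cat2$bacc <- vapply(seq_len(nrow(cat2)), function(i) {
    s <- mat[arm, cat2$gene[i]]
    pred <- if (cat2$direction[i] == "response") {
      ifelse(s == 1, 1, -1)
    } else {
      ifelse(s == 1, -1, 1)
    }
    balanced_accuracy(truth, pred)
  }, numeric(1))
  cat2
}

flavor_placeholder <- function(status) {
  list(model = NULL, hyper = NULL, bacc = NA_real_, loocv = NULL,
       importance = tibble::tibble(gene = character(),
                                   importance = numeric()),
       status = status)
}

#' Train the per-treatment model bundle
#'
#' Fits one boosted classifier per network flavor (General, Resp,
#' NonResp) on the flavor's DCO feature matrix, evaluates each by
#' leave-one-out cross-validation, and combines the three out-of-fold
#' predictions into the weighted score of [combine_flavor_scores()]. The
#' `variant` selects the feature source: the DCO networks, the biomarker
#' genes, or their union.
#'
#' @param am An [alteration_matrix()].
#' @param response Data frame with `sample_id`, `response` for this arm.
#' @param networks Named list of `dco_network`s from
#'   [build_dco_networks()].
#' @param treatment_id Treatment identifier.
#' @param variant `"dco"` (default), `"biomarkers"`, or
#'   `"dco+biomarkers"`.
#' @param biomarker_genes Character vector of biomarker genes for the
#'   arm's drug family (required by the two biomarker variants).
#' @param tune Tune hyperparameters per flavor (default `FALSE`: use
#'   `hyper`).
#' @param hyper Hyperparameters when not tuning.
#' @param grid,folds,iterations Tuning controls, see
#'   [tune_hyperparameters()].
#' @param seed Integer seed.
#' @param min_group Minimum per-group size for eligibility (default 5).
#' @return A `treatment_model_bundle`: per-flavor models, LOOCV tables,
#'   balanced accuracies and importances, plus the combined per-sample
#'   scores and the combined balanced accuracy.
#' @export
train_treatment_model <- function(am, response, networks, treatment_id,
                                  variant = c("dco", "biomarkers",
                                              "dco+biomarkers"),
                                  biomarker_genes = NULL,
                                  tune = FALSE,
                                  hyper = default_hyperparameters(),
                                  grid = default_hyperparameter_grid(),
                                  folds = 5, iterations = 30, seed = 1,
                                  min_group = 5) {
  variant <- match.arg(variant)
  if (!arm_eligible(response, min_group)) {
    stop_dconet(sprintf("arm %s ineligible: fewer than %d samples in a response group",
                        treatment_id, min_group),
                "dconet_ineligible_arm_error")
  }
  grp <- response_groups(am, response)
  arm <- c(grp$responders, grp$nonresponders)
  labels <- ifelse(arm %in% grp$responders, 1, -1)
  am_arm <- alteration_matrix(unclass(am)[arm, , drop = FALSE])

  flavor_genes <- function(fl) {
    dco <- network_genes(networks[[fl]])
    switch(variant,
           "dco" = dco,
           "biomarkers" = sort(unique(biomarker_genes)),
           "dco+biomarkers" = sort(union(dco, biomarker_genes)))
  }
  if (variant != "dco" && is.null(biomarker_genes)) {
    stop_dconet("biomarker variants need `biomarker_genes`",
                "dconet_input_error")
  }

  flavors <- lapply(c(General = "General", Resp = "Resp",
                      NonResp = "NonResp"), function(fl) {
    X <- build_features(am_arm, flavor_genes(fl))
    if (ncol(X) == 0) return(flavor_placeholder("no-features"))
    hp <- if (tune) {
      tune_hyperparameters(X, labels, grid = grid, folds = folds,
                           iterations = iterations, seed = seed)
    } else {
      hyper
    }
    cv <- loocv(X, labels, hyper = hp, seed = seed)
    final <- fit_gbm(X, encode_labels(labels), hp, seed = seed)
    list(model = final, hyper = hp, bacc = cv$bacc,
         loocv = cv$predictions, importance = cv$importance,
         status = "trained", feature_genes = colnames(X))
  })

  combined <- tibble::tibble(sample_id = arm, truth = labels)
  getcol <- function(fl, col, default) {
    if (is.null(flavors[[fl]]$loocv)) rep(default, length(arm))
    else flavors[[fl]]$loocv[[col]]
  }
  combined$wcomb <- combine_flavor_scores(
    getcol("General", "pred_class", NA), getcol("General", "prob_response", NA),
    flavors$General$bacc,
    getcol("Resp", "pred_class", NA), getcol("Resp", "prob_response", NA),
    flavors$Resp$bacc,
    getcol("NonResp", "pred_class", NA), getcol("NonResp", "prob_response", NA),
    flavors$NonResp$bacc
  )
  combined$pred_class <- sign(combined$wcomb)
  called <- combined$pred_class != 0
  bacc_combined <- if (any(called)) {
    balanced_accuracy(combined$truth[called], combined$pred_class[called])
  } else {
    NA_real_
  }
  structure(
    list(treatment_id = treatment_id, variant = variant,
         flavors = flavors, combined = combined,
         bacc_combined = bacc_combined, seed = seed,
         n_resp = length(grp$responders),
         n_nonresp = length(grp$nonresponders)),
    class = "treatment_model_bundle"
  )
}

#' @export
print.treatment_model_bundle <- function(x, ...) {
  cat(sprintf("<treatment_model_bundle> %s (%s): combined BAcc %.3f over %d samples\n",
              x$treatment_id, x$variant,
              x$bacc_combined, nrow(x$combined)))
  for (fl in names(x$flavors)) {
    cat(sprintf("  %-8s %s  BAcc %s\n", fl, x$flavors[[fl]]$status,
                format(round(x$flavors[[fl]]$bacc, 3))))
  }
  invisible(x)
}

#' @describeIn train_treatment_model per-sample combined predictions as a
#'   tibble.
#' @param x A `treatment_model_bundle`.
#' @param ... Unused.
#' @export
tidy.treatment_model_bundle <- function(x, ...) {
  dplyr::mutate(x$combined, treatment_id = x$treatment_id,
                variant = x$variant, .before = 1)
}

#' @describeIn train_treatment_model one-row summary (per-flavor and
#'   combined balanced accuracies).
#' @export
glance.treatment_model_bundle <- function(x, ...) {
  tibble::tibble(
    treatment_id = x$treatment_id, variant = x$variant,
    n_resp = x$n_resp, n_nonresp = x$n_nonresp,
    bacc_general = x$flavors$General$bacc,
    bacc_resp = x$flavors$Resp$bacc,
    bacc_nonresp = x$flavors$NonResp$bacc,
    bacc_combined = x$bacc_combined
  )
}

#' Evaluate a collection of treatment model bundles
#'
#' @param bundles List of `treatment_model_bundle`s.
#' @param bacc_cutoff High-confidence threshold on the combined balanced
#'   accuracy (default 0.6).
#' @return A list with `table` (per-treatment balanced accuracies),
#'   `macro_bacc` (mean over treatments with a defined balanced
#'   accuracy), and `high_confidence` (the subset at or above the
#'   cutoff).
#' @export
evaluate_models <- function(bundles, bacc_cutoff = 0.6) {
  if (inherits(bundles, "treatment_model_bundle")) bundles <- list(bundles)
  tab <- purrr::map_dfr(bundles, glance)
  defined <- !is.na(tab$bacc_combined)
  if (!any(defined)) {
    warn("no treatment arm has a defined balanced accuracy")
  } else if (any(!defined)) {
    inform(sprintf("evaluate_models: %d arms with undefined balanced accuracy excluded from the macro average",
                   sum(!defined)))
  }
  list(
    table = tab,
    macro_bacc = mean(tab$bacc_combined[defined]),
    high_confidence = tab[defined & tab$bacc_combined >= bacc_cutoff, ,
                          drop = FALSE]
  )
}
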