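# End-to-end orchestration: per-treatment DCO inference and classifier
# training from an alteration matrix plus binary response calls, with a
# reproducible configuration object.

#' Default pipeline configuration
#'
#' The stage thresholds used throughout: selection probability 0.95,
#' minimum alteration rate 0.05, minimum count 2, 1000 permutations,
#' swap budget 10 per altered entry, high-confidence balanced-accuracy
#' cutoff 0.6, maximum clinical FDR 0.30, and the boosting defaults of
#' [default_hyperparameters()].
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    prob_threshold = 0.95,
    min_count = 2,
    min_rate = 0.05,
    n_permutations = 1000,
    swap_multiplier = 10,
    bacc_cutoff = 0.6,
    max_fdr = 0.30,
    tune = FALSE,
    hyper = default_hyperparameters(),
    folds = 5,
    iterations = 30,
    min_group = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_dconet(sprintf("unknown configuration keys: %s",
                        paste(unknown, collapse = ", ")),
                "dconet_config_error")
  }
  cfg[names(dots)] <- dots
  if (cfg$prob_threshold <= 0 || cfg$prob_threshold >= 1) {
    stop_dconet("prob_threshold must lie in (0, 1)", "dconet_config_error")
  }
  if (cfg$max_fdr < 0 || cfg$max_fdr > 1) {
    stop_dconet("max_fdr must lie in [0, 1]", "dconet_config_error")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the DCO pipeline for one or more treatment arms
#'
#' For every eligible treatment arm: differential-driver selection, pair
#' selection against a margin-preserving rewiring null, network
#' assembly, classifier training with leave-one-out evaluation, and
#' combined scoring. Ineligible arms (fewer than `min_group` samples in
#' a response group) are skipped with a log entry.
#'
#' @param am An [alteration_matrix()].
#' @param responses Tibble with columns `treatment_id`, `sample_id`,
#'   `response`.
#' @param config A [pipeline_config()].
#' @param coordinates Optional gene coordinates for linkage annotation.
#' @param seed Master seed; per-arm seeds are derived from it.
#' @return A list of per-treatment results (`diffd`, `pairs`,
#'   `networks`, `bundle`), plus `evaluation` from [evaluate_models()]
#'   and `skipped` (ineligible arms).
#' @export
run_pipeline <- function(am, responses, config = pipeline_config(),
                         coordinates = NULL, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("treatment_id", "sample_id", "response")
  if (!all(need %in% names(responses))) {
    stop_dconet("`responses` needs treatment_id, sample_id, response",
                "dconet_input_error")
  }
  treatments <- unique(responses$treatment_id)
  arm_seeds <- derive_seeds(seed, length(treatments))
  results <- list()
  skipped <- character(0)
  for (i in seq_along(treatments)) {
    tr <- treatments[i]
    arm <- responses[responses$treatment_id == tr,
                     c("sample_id", "response")]
    if (!arm_eligible(arm, config$min_group)) {
      inform(sprintf("run_pipeline: arm %s ineligible (needs >= %d per group); skipped",
                     tr, config$min_group))
      skipped <- c(skipped, tr)
      next
    }
    am_arm <- alteration_matrix(unclass(am)[arm$sample_id, , drop = FALSE])
    diffd <- select_diff_drivers(am_arm, arm,
                                 prob_threshold = config$prob_threshold,
                                 min_count = config$min_count,
                                 min_rate = config$min_rate)
    null <- build_rewiring_null(am_arm,
                                n_permutations = config$n_permutations,
                                swap_multiplier = config$swap_multiplier,
                                seed = arm_seeds[i])
    pairs <- select_pairs(am_arm, arm, null = null,
                          prob_threshold = config$prob_threshold,
                          min_count = config$min_count,
                          min_rate = config$min_rate)
    networks <- build_dco_networks(diffd, pairs, tr,
                                   coordinates = coordinates)
    bundle <- train_treatment_model(
      am_arm, arm, networks, tr,
      tune = config$tune, hyper = config$hyper, folds = config$folds,
      iterations = config$iterations, seed = arm_seeds[i],
      min_group = config$min_group
    )
    results[[tr]] <- list(diffd = diffd, pairs = pairs,
                          networks = networks, bundle = bundle)
  }
  bundles <- lapply(results, function(r) r$bundle)
  evaluation <- if (length(bundles) > 0) {
    evaluate_models(bundles, bacc_cutoff = config$bacc_cutoff)
  }
  list(treatments = results, evaluation = evaluation, skipped = skipped,
       config = config, seed = seed)
}

#' Rank candidate treatments for new samples
#'
#' Scores each sample with every high-confidence treatment model
#' (combined LOOCV balanced accuracy at or above the cutoff) and ranks
#' treatments per sample by decreasing combined score.
#'
#' @param results Output of [run_pipeline()], or a list of
#'   `treatment_model_bundle`s.
#' @param am Alteration matrix of the samples to score.
#' @param bacc_cutoff High-confidence cutoff (default 0.6).
#' @return A tibble: `sample_id`, `treatment_id`, `wcomb`,
#'   `pred_class`, `rank` (1 = most promising), restricted to
#'   high-confidence models. Samples with no high-confidence model
#'   return zero rows.
#' @export
rank_treatments <- function(results, am, bacc_cutoff = 0.6) {
  bundles <- if (!is.null(results$treatments)) {
    lapply(results$treatments, function(r) r$bundle)
  } else {
    results
  }
  keep <- purrr::keep(bundles, function(b) {
    !is.na(b$bacc_combined) && b$bacc_combined >= bacc_cutoff
  })
  if (length(keep) == 0) return(tibble::tibble(
    sample_id = character(), treatment_id = character(),
    wcomb = numeric(), pred_class = numeric(), rank = integer()
  ))
  purrr::map_dfr(keep, function(b) {
    dplyr::mutate(predict_samples(b, am)[, c("sample_id", "wcomb",
                                             "pred_class")],
                  treatment_id = b$treatment_id, .after = 1)
  }) |>
    dplyr::mutate(rank = rank(-.data$wcomb, ties.method = "first"),
                  .by = "sample_id") |>
    dplyr::arrange(.data$sample_id, .data$rank)
}
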