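# Model interpretation: exact per-sample Shapley contributions computed in
# double precision from the parsed tree ensemble, pairwise interaction
# ranking, status-stratified interaction summaries, and the biomarker
# overlap test.

# Parse an xgboost booster into flat per-tree arrays (0-based indices)
# consumable by the C++ kernels. `feature_names` fixes column order.
parse_booster <- function(model, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  trees <- split(as.data.frame(dt), dt$Tree)
  lapply(trees, function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    idx <- setNames(seq_len(nrow(tr)) - 1L, tr$ID)
    is_leaf <- tr$Feature == "Leaf"
    feature <- ifelse(is_leaf, -1L,
                      match(tr$Feature, feature_names) - 1L)
    if (anyNA(feature)) {
      stop_dconet("model splits on features absent from the feature matrix",
                  "dconet_input_error")
    }
    list(
      left = unname(ifelse(is_leaf, -1L, idx[tr$Yes])),
      right = unname(ifelse(is_leaf, -1L, idx[tr$No])),
      feature = as.integer(feature),
      threshold = ifelse(is_leaf, 0, tr$Split),
      value = ifelse(is_leaf, tr$Gain, 0),
      cover = tr$Cover
    )
  })
}

#' Exact Shapley explanations of a boosted model
#'
#' Per-sample, per-feature additive contributions on the margin (log-odds)
#' scale, computed in double precision with the polynomial-time tree
#' Shapley algorithm over the parsed ensemble. The additivity identity
#' `base_value + sum(contributions) == margin` is asserted to `1e-6` for
#' every sample before returning (it holds to near machine precision).
#'
#' @param model An `xgb.Booster`, or a `treatment_model_bundle` (in which
#'   case `flavor` selects the classifier).
#' @param X Binary feature matrix with exactly the model's feature
#'   columns.
#' @param flavor Flavor to explain when `model` is a bundle (default
#'   `"General"`).
#' @return A tibble with columns `sample_id`, `gene`, `contribution`;
#'   attributes `base_value` (scalar) and `margin` (per-sample margin).
#' @export
explain <- function(model, X, flavor = "General") {
  if (inherits(model, "treatment_model_bundle")) {
    fl <- model$flavors[[flavor]]
    if (is.null(fl$model)) {
      stop_dconet(sprintf("flavor %s has no trained model", flavor),
                  "dconet_input_error")
    }
    model <- fl$model
  }
  feature_names <- colnames(X)
  # Split features are matched to X by name inside parse_booster(), so a
  # reordered X is handled and a missing column raises an error there.
  trees <- parse_booster(model, feature_names)
  Xd <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  phi <- tree_shap_cpp(unname(trees), Xd)
  base <- phi[1, ncol(phi)]
  contrib <- phi[, seq_len(ncol(X)), drop = FALSE]
  margin <- tree_margin_cpp(unname(trees), Xd)
  gap <- max(abs(base + rowSums(contrib) - margin))
  if (gap > 1e-6) {
    stop_dconet(sprintf("Shapley additivity violated (gap %.3g)", gap),
                "dconet_computation_error")
  }
  out <- tibble::tibble(
    sample_id = rep(rownames(X) %||% as.character(seq_len(nrow(X))),
                    times = ncol(X)),
    gene = rep(feature_names, each = nrow(X)),
    contribution = as.numeric(contrib)
  )
  attr(out, "base_value") <- base
  attr(out, "margin") <- margin
  out
}

#' Rank feature pairs by interaction strength
#'
#' Mean absolute pairwise Shapley interaction value over the supplied
#' samples, as computed natively by the boosting backend; pairs are
#' returned in descending strength with lexicographic tie-breaking.
#' Depth-1 ensembles cannot encode interactions and return all-zero
#' strengths.
#'
#' @inheritParams explain
#' @return A tibble with `gene_a`, `gene_b` (canonical order) and
#'   `strength` (>= 0), sorted by decreasing strength.
#' @export
rank_interactions <- function(model, X, flavor = "General") {
  if (inherits(model, "treatment_model_bundle")) {
    model <- model$flavors[[flavor]]$model
    if (is.null(model)) {
      stop_dconet(sprintf("flavor %s has no trained model", flavor),
                  "dconet_input_error")
    }
  }
  inter <- predict(model, xgboost::xgb.DMatrix(X), predinteraction = TRUE)
  p <- ncol(X)
  genes <- colnames(X)
  strength <- apply(abs(inter[, seq_len(p), seq_len(p), drop = FALSE]),
                    c(2, 3), mean)
  ut <- which(upper.tri(strength), arr.ind = TRUE)
  tibble::tibble(
    gene_a = genes[ut[, 1]],
    gene_b = genes[ut[, 2]],
    strength = strength[ut]
  ) |>
    dplyr::arrange(dplyr::desc(.data$strength), .data$gene_a, .data$gene_b)
}

#' Status-stratified interaction summary for a driver pair
#'
#' Samples are split into the four status categories of genes A and B
#' (both altered, only A, only B, neither); within each category the mean
#' Shapley contribution of each gene is reported, exposing how alteration
#' of one driver shifts the contribution of the other. When coordinates
#' are supplied the pair is flagged as genomically linked if both genes
#' lie on the same chromosome arm.
#'
#' @param explanations Tibble from [explain()].
#' @param X The feature matrix the explanations were computed on.
#' @param gene_a,gene_b The pair to summarise (must be feature columns).
#' @param coordinates Optional tibble from [read_gene_coordinates()].
#' @return A tibble with one row per category: `category`, `n`,
#'   `mean_contrib_a`, `mean_contrib_b` (empty categories report `NA`),
#'   plus constant columns `gene_a`, `gene_b`, `linked`, `distance_bp`.
#' @export
interaction_summary <- function(explanations, X, gene_a, gene_b,
                                coordinates = NULL) {
  if (!all(c(gene_a, gene_b) %in% colnames(X))) {
    stop_dconet("both genes must be feature columns", "dconet_input_error")
  }
  sample_order <- rownames(X) %||% as.character(seq_len(nrow(X)))
  ca <- explanations$contribution[explanations$gene == gene_a][
    match(sample_order,
          explanations$sample_id[explanations$gene == gene_a])]
  cb <- explanations$contribution[explanations$gene == gene_b][
    match(sample_order,
          explanations$sample_id[explanations$gene == gene_b])]
  a <- X[, gene_a] == 1
  b <- X[, gene_b] == 1
  cats <- list("A&B" = a & b, "A&!B" = a & !b,
               "!A&B" = !a & b, "!A&!B" = !a & !b)
  linked <- NA
  dist_bp <- NA_real_
  if (!is.null(coordinates)) {
    ann <- annotate_linkage(tibble::tibble(gene_a = gene_a, gene_b = gene_b),
                            coordinates)
    linked <- ann$linked
    dist_bp <- ann$distance_bp
  }
  purrr::map_dfr(names(cats), function(nm) {
    sel <- cats[[nm]]
    tibble::tibble(
      category = nm, n = sum(sel),
      mean_contrib_a = if (any(sel)) mean(ca[sel]) else NA_real_,
      mean_contrib_b = if (any(sel)) mean(cb[sel]) else NA_real_
    )
  }) |>
    dplyr::mutate(gene_a = gene_a, gene_b = gene_b, linked = linked,
                  distance_bp = dist_bp)
}

#' Fisher's exact test for biomarker / DCO-association overlap
#'
#' Builds the 2x2 table for the overlap between the drug-gene
#' associations captured by DCO networks and those annotated in a
#' biomarker catalog, over a common universe of eligible drug-gene
#' pairs, and tests independence.
#'
#' @param n_overlap Associations in both sets.
#' @param n_biomarker_assoc Total catalog associations in the universe.
#' @param n_dco_assoc Total DCO-captured associations in the universe.
#' @param n_universe Size of the eligible-pair universe.
#' @return A one-row tibble: `odds_ratio` (conditional MLE, as returned
#'   by [stats::fisher.test()]), `sample_odds_ratio` (ad/bc), `p_value`
#'   (two-sided), and the four table cells.
#' @export
biomarker_overlap_fisher <- function(n_overlap, n_biomarker_assoc,
                                     n_dco_assoc, n_universe) {
  a <- n_overlap
  b <- n_dco_assoc - n_overlap
  c <- n_biomarker_assoc - n_overlap
  d <- n_universe - a - b - c
  if (a < 0 || b < 0 || c < 0 || d < 0) {
    stop_dconet("inconsistent overlap counts", "dconet_input_error")
  }
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  ft <- fisher.test(tab)
  tibble::tibble(
    odds_ratio = unname(ft$estimate),
    sample_odds_ratio = (a * d) / (b * c),
    p_value = ft$p.value,
    n_overlap = a, n_dco_only = b, n_biomarker_only = c, n_neither = d
  )
}
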