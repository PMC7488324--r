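# Co-occurring driver pairs against a margin-preserving rewiring null.
# Permuted matrices keep every sample's driver load and every gene's
# alteration frequency, so excess co-occurrence cannot be explained by
# marginal rates alone.

#' Rewire a binary alteration matrix, preserving all marginals
#'
#' Performs repeated checkerboard swaps: two altered entries
#' `(s1, g1)`, `(s2, g2)` with both opposite corners unaltered are
#' exchanged for `(s1, g2)`, `(s2, g1)`. Every accepted swap preserves
#' row and column sums exactly, giving a degree-preserving null for
#' co-occurrence statistics.
#'
#' @param am An [alteration_matrix()] with at least 2 rows, 2 columns and
#'   2 altered entries.
#' @param n_swaps Number of successful swaps to perform; default
#'   `swap_multiplier` times the number of altered entries.
#' @param swap_multiplier Swap budget per altered entry (default 10),
#'   used when `n_swaps` is `NULL`.
#' @param seed Optional integer seed.
#' @return A rewired [alteration_matrix()] with identical marginals. If no
#'   valid swap exists (degenerate matrix), the input is returned
#'   unchanged with a warning.
#' @export
rewire_matrix <- function(am, n_swaps = NULL, swap_multiplier = 10,
                          seed = NULL) {
  if (!inherits(am, "alteration_matrix")) am <- alteration_matrix(am)
  if (!is.null(seed)) set.seed(seed)
  n_ones <- sum(am)
  if (nrow(am) < 2 || ncol(am) < 2 || n_ones < 2) {
    warn("matrix too small to rewire; returned unchanged")
    return(am)
  }
  if (is.null(n_swaps)) n_swaps <- swap_multiplier * n_ones
  res <- rewire_checkerboard_cpp(unclass(am), as.integer(n_swaps),
                                 max_tries = 200 * n_swaps + 1e4)
  done <- attr(res, "swaps_done")
  if (done == 0) {
    warn("no valid checkerboard swap exists; matrix returned unchanged")
    return(am)
  }
  attr(res, "swaps_done") <- NULL
  out <- alteration_matrix(res)
  stopifnot(identical(rowSums(out), rowSums(unclass(am))),
            identical(colSums(out), colSums(unclass(am))))
  out
}

#' Build a rewiring null model
#'
#' Generates `n_permutations` independent margin-preserving permutations
#' of the full arm matrix. The same permutations are reused for the
#' responder and non-responder restrictions, keeping the two groups
#' comparable under the null.
#'
#' @inheritParams rewire_matrix
#' @param n_permutations Number of permuted matrices (default 1000).
#' @param seed Integer seed (required: the null must be reproducible).
#' @return An object of class `rewiring_null`.
#' @export
build_rewiring_null <- function(am, n_permutations = 1000,
                                swap_multiplier = 10, seed) {
  if (!inherits(am, "alteration_matrix")) am <- alteration_matrix(am)
  stopifnot(is.numeric(seed), length(seed) == 1)
  seeds <- derive_seeds(seed, n_permutations)
  perms <- lapply(seq_len(n_permutations), function(i) {
    unclass(suppressWarnings(
      rewire_matrix(am, swap_multiplier = swap_multiplier, seed = seeds[i])
    ))
  })
  structure(
    list(perms = perms, n_permutations = n_permutations,
         swap_multiplier = swap_multiplier, seed = seed,
         source_dim = dim(am)),
    class = "rewiring_null"
  )
}

#' @export
print.rewiring_null <- function(x, ...) {
  cat(sprintf("<rewiring_null> %d permutations of a %d x %d matrix (seed %s)\n",
              x$n_permutations, x$source_dim[1], x$source_dim[2],
              format(x$seed)))
  invisible(x)
}

#' Co-occurrence count and rate of a gene pair
#'
#' @param am An [alteration_matrix()].
#' @param gene_a,gene_b Gene identifiers present in `am`.
#' @param samples Optional character vector restricting the sample set.
#' @return A one-row tibble with `count` and `rate`.
#' @export
pair_cooccurrence <- function(am, gene_a, gene_b, samples = NULL) {
  if (!all(c(gene_a, gene_b) %in% colnames(am))) {
    stop_dconet("both genes must be present in the matrix",
                "dconet_input_error")
  }
  samples <- samples %||% rownames(am)
  if (length(samples) == 0) {
    stop_dconet("empty sample subset", "dconet_input_error")
  }
  m <- unclass(am)[samples, , drop = FALSE]
  count <- sum(m[, gene_a] * m[, gene_b])
  tibble::tibble(count = as.integer(count), rate = count / length(samples))
}

# Mean of the memoised inequality probability of an observed count against
# a vector of permuted counts at common group size n.
tendency_from_counts <- function(k_obs, k_perm, n, prior) {
  tab <- table(k_perm)
  ks <- as.integer(names(tab))
  probs <- beta_inequality_prob(rep.int(k_obs, length(ks)), n, ks, n,
                                prior = prior)
  sum(probs * as.integer(tab)) / length(k_perm)
}

#' Co-occurrence tendency of a pair against the rewiring null
#'
#' The average, over permutations, of the probability that the observed
#' co-alteration rate exceeds the permuted one, both modeled as beta
#' posteriors over co-alteration counts in the same sample subset.
#'
#' @inheritParams pair_cooccurrence
#' @param null A `rewiring_null` built from the same matrix.
#' @param prior Beta pseudo-counts, see [beta_inequality_prob()].
#' @return The average probability (scalar).
#' @export
pair_tendency <- function(am, null, gene_a, gene_b, samples = NULL,
                          prior = c(1, 1)) {
  stopifnot(inherits(null, "rewiring_null"))
  samples <- samples %||% rownames(am)
  n <- length(samples)
  k_obs <- pair_cooccurrence(am, gene_a, gene_b, samples)$count
  k_perm <- vapply(null$perms, function(p) {
    sum(p[samples, gene_a] * p[samples, gene_b])
  }, numeric(1))
  tendency_from_counts(k_obs, k_perm, n, prior)
}

# Upper-triangle co-occurrence counts for the candidate genes in a sample
# subset, for the observed matrix and every permutation. Returns a list
# with the observed integer vector and an n_pairs x n_perm matrix.
pair_count_tables <- function(mat, perms, genes, samples) {
  sub <- mat[samples, genes, drop = FALSE]
  cp <- crossprod(sub)
  ut <- upper.tri(cp)
  obs <- cp[ut]
  perm_counts <- vapply(perms, function(p) {
    crossprod(p[samples, genes, drop = FALSE])[ut]
  }, numeric(sum(ut)))
  if (is.null(dim(perm_counts))) {
    perm_counts <- matrix(perm_counts, nrow = sum(ut))
  }
  idx <- which(ut, arr.ind = TRUE)
  list(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
       obs = as.integer(obs), perm = perm_counts)
}

#' Select co-occurring driver pairs for a treatment arm
#'
#' Candidate pairs (both genes altered at least `min_count` times in the
#' arm) are scored against a margin-preserving rewiring null
#' ([build_rewiring_null()]):
#' \itemize{
#'  \item `general_ps`: co-occurrence tendency above `prob_threshold`
#'    over all arm samples, plus count/rate filters in the arm;
#'  \item `resp_ps`: tendency above threshold within responders, AND
#'    probability of a higher co-alteration rate in responders than
#'    non-responders above threshold, AND that probability exceeding the
#'    95th percentile of its own permutation-null distribution, AND
#'    count/rate filters within responders;
#'  \item `nonresp_ps`: the symmetric selection for non-responders.
#' }
#'
#' @inheritParams select_diff_drivers
#' @param null Optional pre-built `rewiring_null` for `am`; built on the
#'   fly otherwise.
#' @param n_permutations,swap_multiplier Passed to
#'   [build_rewiring_null()] when `null` is `NULL`.
#' @param seed Integer seed used when building the null.
#' @param null_quantile Percentile of the permutation distribution that
#'   the differential-co-occurrence probability must exceed (default
#'   0.95).
#' @return A tibble with one row per candidate pair: per-scope counts,
#'   rates and tendencies, the differential-co-occurrence probability and
#'   its permutation-null 95th percentiles, membership flags and a
#'   compact `memberships` string. Pairs are canonically ordered
#'   (`gene_a < gene_b`).
#' @export
select_pairs <- function(am, response, null = NULL, n_permutations = 1000,
                         swap_multiplier = 10, prob_threshold = 0.95,
                         min_count = 2, min_rate = 0.05, prior = c(1, 1),
                         null_quantile = 0.95, seed = NULL) {
  grp <- response_groups(am, response)
  arm_samples <- c(grp$responders, grp$nonresponders)
  mat <- unclass(am)
  if (is.null(null)) {
    if (is.null(seed)) {
      stop_dconet("`seed` is required when building the null in-place",
                  "dconet_input_error")
    }
    null <- build_rewiring_null(am, n_permutations = n_permutations,
                                swap_multiplier = swap_multiplier,
                                seed = seed)
  }
  gene_counts <- colSums(mat[arm_samples, , drop = FALSE])
  cand <- sort(colnames(am)[gene_counts >= min_count])
  if (length(cand) < 2) {
    return(empty_pair_table())
  }
  n_all <- length(arm_samples)
  n_r <- length(grp$responders)
  n_n <- length(grp$nonresponders)

  all_t <- pair_count_tables(mat, null$perms, cand, arm_samples)
  resp_t <- pair_count_tables(mat, null$perms, cand, grp$responders)
  non_t <- pair_count_tables(mat, null$perms, cand, grp$nonresponders)
  n_pairs <- length(all_t$obs)

  tendency <- function(tbl, n) {
    vapply(seq_len(n_pairs), function(i) {
      tendency_from_counts(tbl$obs[i], tbl$perm[i, ], n, prior)
    }, numeric(1))
  }
  tendency_all <- tendency(all_t, n_all)
  tendency_resp <- tendency(resp_t, n_r)
  tendency_nonresp <- tendency(non_t, n_n)

  p_diff <- beta_inequality_prob(resp_t$obs, n_r, non_t$obs, n_n,
                                 prior = prior)
  # Null distribution of the same differential probability: each permuted
  # matrix split by the true labels.
  n_perm <- ncol(all_t$perm)
  q95_resp <- numeric(n_pairs)
  q95_nonresp <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    combos <- paste(resp_t$perm[i, ], non_t$perm[i, ], sep = "|")
    tab <- table(combos)
    kk <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    p_null_u <- beta_inequality_prob(as.integer(kk[, 1]), n_r,
                                     as.integer(kk[, 2]), n_n, prior = prior)
    p_null <- rep(p_null_u, as.integer(tab))
    q95_resp[i] <- unname(quantile(p_null, null_quantile, type = 7))
    q95_nonresp[i] <- unname(quantile(1 - p_null, null_quantile, type = 7))
  }

  rate_all <- all_t$obs / n_all
  rate_resp <- resp_t$obs / n_r
  rate_nonresp <- non_t$obs / n_n
  general_ps <- tendency_all > prob_threshold & all_t$obs >= min_count &
    rate_all >= min_rate
  resp_ps <- tendency_resp > prob_threshold & p_diff > prob_threshold &
    p_diff > q95_resp & resp_t$obs >= min_count & rate_resp >= min_rate
  nonresp_ps <- tendency_nonresp > prob_threshold &
    (1 - p_diff) > prob_threshold & (1 - p_diff) > q95_nonresp &
    non_t$obs >= min_count & rate_nonresp >= min_rate

  tibble::tibble(
    gene_a = all_t$gene_a, gene_b = all_t$gene_b,
    count_all = all_t$obs, rate_all = rate_all,
    count_resp = resp_t$obs, rate_resp = rate_resp,
    count_nonresp = non_t$obs, rate_nonresp = rate_nonresp,
    tendency_all = tendency_all, tendency_resp = tendency_resp,
    tendency_nonresp = tendency_nonresp,
    p_diff_cooccurrence = p_diff,
    null_q95_resp = q95_resp, null_q95_nonresp = q95_nonresp,
    general_ps = general_ps, resp_ps = resp_ps, nonresp_ps = nonresp_ps,
    memberships = membership_string(resp_ps, nonresp_ps, general_ps)
  )
}

empty_pair_table <- function() {
  tibble::tibble(
    gene_a = character(), gene_b = character(),
    count_all = integer(), rate_all = numeric(),
    count_resp = integer(), rate_resp = numeric(),
    count_nonresp = integer(), rate_nonresp = numeric(),
    tendency_all = numeric(), tendency_resp = numeric(),
    tendency_nonresp = numeric(), p_diff_cooccurrence = numeric(),
    null_q95_resp = numeric(), null_q95_nonresp = numeric(),
    general_ps = logical(), resp_ps = logical(), nonresp_ps = logical(),
    memberships = character()
  )
}
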