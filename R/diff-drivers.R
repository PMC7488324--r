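# Differential-driver selection: per-gene alteration rates are compared
# between response groups with the analytic beta-inequality probability,
# then filtered on recurrence and minimum rate.

#' Differentially altered driver genes between response groups
#'
#' For every gene, the responder and non-responder alteration rates are
#' modeled as independent beta posteriors over the observed counts and the
#' probability \eqn{P(p_{resp} > p_{nonresp})} is computed analytically
#' ([beta_inequality_prob()]). Three gene sets are derived per arm:
#' \itemize{
#'  \item `resp_diffd`: probability above `prob_threshold`, plus altered
#'    at least `min_count` times and at rate `>= min_rate` in responders;
#'  \item `nonresp_diffd`: the symmetric selection in non-responders;
#'  \item `general_diffd`: `max(P, 1 - P) > prob_threshold` (two-sided)
#'    with the count/rate filters applied in the enriched group.
#' }
#'
#' @param am An [alteration_matrix()].
#' @param response Data frame with columns `sample_id`, `response`; all
#'   samples must be rows of `am`.
#' @param prob_threshold Inequality-probability cutoff (default 0.95).
#' @param min_count Minimum alteration count in the enriched group
#'   (default 2, i.e. "altered more than once").
#' @param min_rate Minimum alteration rate in the enriched group
#'   (default 0.05).
#' @param prior Beta pseudo-counts, see [beta_inequality_prob()].
#' @return A tibble with one row per gene: counts and rates per group,
#'   `p_resp_gt_nonresp`, the three membership flags, and a compact
#'   `memberships` string.
#' @export
select_diff_drivers <- function(am, response, prob_threshold = 0.95,
                                min_count = 2, min_rate = 0.05,
                                prior = c(1, 1)) {
  grp <- response_groups(am, response)
  n_resp <- length(grp$responders)
  n_nonresp <- length(grp$nonresponders)
  if (n_resp == 0 || n_nonresp == 0) {
    stop_dconet("both response groups must be non-empty", "dconet_input_error")
  }
  k_resp <- colSums(unclass(am)[grp$responders, , drop = FALSE])
  k_nonresp <- colSums(unclass(am)[grp$nonresponders, , drop = FALSE])
  p <- beta_inequality_prob(k_resp, n_resp, k_nonresp, n_nonresp,
                            prior = prior)
  rate_resp <- k_resp / n_resp
  rate_nonresp <- k_nonresp / n_nonresp
  pass_resp <- k_resp >= min_count & rate_resp >= min_rate
  pass_nonresp <- k_nonresp >= min_count & rate_nonresp >= min_rate
  resp_diffd <- p > prob_threshold & pass_resp
  nonresp_diffd <- (1 - p) > prob_threshold & pass_nonresp
  general_diffd <- (pmax(p, 1 - p) > prob_threshold) &
    ifelse(p >= 0.5, pass_resp, pass_nonresp)
  tibble::tibble(
    gene = colnames(am),
    k_resp = as.integer(k_resp), n_resp = n_resp,
    k_nonresp = as.integer(k_nonresp), n_nonresp = n_nonresp,
    rate_resp = rate_resp, rate_nonresp = rate_nonresp,
    p_resp_gt_nonresp = p,
    resp_diffd = unname(resp_diffd),
    nonresp_diffd = unname(nonresp_diffd),
    general_diffd = unname(general_diffd),
    memberships = membership_string(resp_diffd, nonresp_diffd, general_diffd)
  )
}

membership_string <- function(resp, nonresp, general,
                              labels = c("Resp", "NonResp", "General")) {
  vapply(seq_along(resp), function(i) {
    paste(c(labels[1][resp[i]], labels[2][nonresp[i]], labels[3][general[i]]),
          collapse = ";")
  }, character(1))
}

#' Write a differential-driver table as TSV
#'
#' @param diffd Tibble from [select_diff_drivers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_drivers <- function(diffd, path) {
  readr::write_tsv(diffd, path, progress = FALSE)
  invisible(path)
}
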