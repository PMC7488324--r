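# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can branch on error category.
stop_dconet <- function(message, class, ...) {
  abort(message, class = c(class, "dconet_error"), ...)
}

assert_binary_response <- function(response) {
  if (!is.data.frame(response) ||
      !all(c("sample_id", "response") %in% names(response))) {
    stop_dconet(
      "`response` must be a data frame with columns `sample_id` and `response`.",
      "dconet_input_error"
    )
  }
  bad <- setdiff(unique(response$response), c("responder", "non-responder"))
  if (length(bad) > 0) {
    stop_dconet(
      sprintf("`response` values must be 'responder'/'non-responder'; found: %s",
              paste(bad, collapse = ", ")),
      "dconet_input_error"
    )
  }
  invisible(response)
}

# Split sample ids by response group, checking that every sample is present
# in the alteration matrix.
response_groups <- function(am, response) {
  assert_binary_response(response)
  missing <- setdiff(response$sample_id, sample_ids(am))
  if (length(missing) > 0) {
    stop_dconet(
      sprintf("%d response samples absent from the alteration matrix (e.g. %s)",
              length(missing), missing[1]),
      "dconet_input_error"
    )
  }
  list(
    responders = response$sample_id[response$response == "responder"],
    nonresponders = response$sample_id[response$response == "non-responder"]
  )
}

# Rank-based AUC (Mann-Whitney statistic). Called thousands of times inside
# the tuning loop, hence not routed through a full ROC object.
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Derive a stream of distinct 31-bit seeds from one master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  }
  s
}
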