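#' Tumor volume from caliper axes
#'
#' Converts caliper measurements of the major (`l`) and minor (`w`) tumor
#' axes into a volume estimate using the prolate-spheroid formula
#' \eqn{l \cdot w^2 \cdot \pi / 6}.
#'
#' @param l Major axis, mm.
#' @param w Minor axis, mm; must satisfy `w <= l` elementwise.
#' @return Volume in cubic millimetres.
#' @examples
#' volume_from_caliper(10, 5) # 250 * pi / 6
#' @export
volume_from_caliper <- function(l, w) {
  if (any(w < 0) || any(l < 0)) {
    stop_dconet("caliper axes must be non-negative", "dconet_input_error")
  }
  if (any(w > l)) {
    stop_dconet("minor axis w exceeds major axis l: check axis order",
                "dconet_axis_order_error")
  }
  l * w^2 * pi / 6
}

# Locate the baseline (earliest-day) volume and validate the series.
series_baseline <- function(day, volume) {
  if (length(day) != length(volume) || length(day) == 0) {
    stop_dconet("day and volume must be equal-length, non-empty",
                "dconet_input_error")
  }
  if (is.unsorted(day, strictly = TRUE)) {
    stop_dconet("days must be strictly increasing", "dconet_input_error")
  }
  if (any(volume <= 0)) {
    if (volume[1] == 0) {
      stop_dconet("baseline volume is zero; percent change undefined",
                  "dconet_degenerate_baseline_error")
    }
    stop_dconet("volumes must be positive", "dconet_input_error")
  }
  volume[1]
}

#' Percent change in tumor volume from baseline
#'
#' \eqn{\Delta Vol_t = (V_t - V_i) / V_i \cdot 100} where `V_i` is the
#' earliest-day (baseline) volume. The baseline itself maps to 0.
#'
#' @param day Strictly increasing observation days; the first entry is the
#'   baseline day (day 0 in a standard screen).
#' @param volume Positive volumes (mm^3) aligned to `day`.
#' @return Numeric vector of percent changes aligned to `day`.
#' @export
pct_change_series <- function(day, volume) {
  v0 <- series_baseline(day, volume)
  (volume - v0) / v0 * 100
}

#' Best response of a tumor-volume series
#'
#' The minimum percent volume change over observations at `min_day` or
#' later. Earlier observations are never candidates.
#'
#' @inheritParams pct_change_series
#' @param min_day Earliest eligible evaluation day (default 10).
#' @return Best response, percent.
#' @export
best_response <- function(day, volume, min_day = 10) {
  dvol <- pct_change_series(day, volume)
  ok <- day >= min_day & seq_along(day) > 1
  if (!any(ok)) {
    stop_dconet(sprintf("no observation at day >= %g; insufficient follow-up",
                        min_day), "dconet_follow_up_error")
  }
  min(dvol[ok])
}

#' Best average response of a tumor-volume series
#'
#' For each observation at `min_day` or later, the running mean of percent
#' volume change over all post-baseline observations up to and including
#' that day is a candidate; the minimum candidate is returned. The
#' baseline's zero change is excluded from every mean; observations before
#' `min_day` contribute to later running means but are never themselves
#' evaluation points.
#'
#' @inheritParams best_response
#' @return Best average response, percent.
#' @export
best_average_response <- function(day, volume, min_day = 10) {
  dvol <- pct_change_series(day, volume)
  post <- seq_along(day) > 1
  if (!any(post & day >= min_day)) {
    stop_dconet(sprintf("no observation at day >= %g; insufficient follow-up",
                        min_day), "dconet_follow_up_error")
  }
  run_mean <- cumsum(dvol[post]) / seq_len(sum(post))
  eligible <- day[post] >= min_day
  min(run_mean[eligible])
}

#' Modified RECIST classification of a response summary
#'
#' Applies the four volume-based response classes in fixed order; the
#' first matching rule wins and anything unmatched falls through to PD:
#' \itemize{
#'   \item CR: best < -95 and best average < -40
#'   \item PR: best < -50 and best average < -20
#'   \item SD: best < 35 and best average < 30
#'   \item PD: otherwise
#' }
#'
#' @param best_resp Best response, percent (finite).
#' @param best_avg_resp Best average response, percent (finite).
#' @return Character vector of classes among `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @examples
#' mrecist_classify(-96, -41) # CR
#' mrecist_classify(-96, -10) # SD: fails CR and PR on the average criterion
#' @export
mrecist_classify <- function(best_resp, best_avg_resp) {
  m <- max(length(best_resp), length(best_avg_resp))
  b <- rep_len(best_resp, m)
  a <- rep_len(best_avg_resp, m)
  if (any(!is.finite(b)) || any(!is.finite(a))) {
    stop_dconet("response summaries must be finite", "dconet_input_error")
  }
  dplyr::case_when(
    b < -95 & a < -40 ~ "CR",
    b < -50 & a < -20 ~ "PR",
    b < 35 & a < 30 ~ "SD",
    .default = "PD"
  )
}

#' Binary responder label from a response class
#'
#' Tumors that progressed (PD) are non-responders; stable disease or any
#' regression (SD, PR, CR) counts as response.
#'
#' @param mrecist_class Character vector of classes.
#' @return `"responder"` / `"non-responder"`.
#' @export
binarize_response <- function(mrecist_class) {
  bad <- setdiff(unique(mrecist_class), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0) {
    stop_dconet(sprintf("unknown response class: %s",
                        paste(bad, collapse = ", ")), "dconet_input_error")
  }
  ifelse(mrecist_class == "PD", "non-responder", "responder")
}

#' Call drug response from tumor-volume trajectories
#'
#' Tidy wrapper over the per-series summaries: takes a long table of
#' volume observations, one trajectory per (model, treatment), and returns
#' one row per trajectory with both response summaries, the volume-based
#' response class and the binary responder label. If the table carries
#' caliper columns `l_mm` and `w_mm` instead of `volume_mm3`, volumes are
#' derived with [volume_from_caliper()] first.
#'
#' @param volumes Data frame with columns `model_id`, `treatment_id`,
#'   `day`, and `volume_mm3` (or `l_mm` + `w_mm`).
#' @param min_day Earliest eligible evaluation day (default 10).
#' @return A tibble with columns `model_id`, `treatment_id`,
#'   `best_response`, `best_average_response`, `mrecist_class`,
#'   `binary_response`.
#' @export
call_response <- function(volumes, min_day = 10) {
  need <- c("model_id", "treatment_id", "day")
  if (!is.data.frame(volumes) || !all(need %in% names(volumes))) {
    stop_dconet("`volumes` must have columns model_id, treatment_id, day",
                "dconet_input_error")
  }
  if (!"volume_mm3" %in% names(volumes)) {
    if (!all(c("l_mm", "w_mm") %in% names(volumes))) {
      stop_dconet("`volumes` needs volume_mm3 or caliper columns l_mm, w_mm",
                  "dconet_input_error")
    }
    volumes <- dplyr::mutate(volumes,
                             volume_mm3 = volume_from_caliper(.data$l_mm,
                                                              .data$w_mm))
  }
  volumes |>
    dplyr::arrange(.data$model_id, .data$treatment_id, .data$day) |>
    dplyr::summarise(
      best_response = best_response(.data$day, .data$volume_mm3, min_day),
      best_average_response =
        best_average_response(.data$day, .data$volume_mm3, min_day),
      .by = c("model_id", "treatment_id")
    ) |>
    dplyr::mutate(
      mrecist_class = mrecist_classify(.data$best_response,
                                       .data$best_average_response),
      binary_response = binarize_response(.data$mrecist_class)
    )
}

#' Treatment-arm eligibility for response modeling
#'
#' An arm supports classifier training only when both response groups hold
#' at least `min_group` samples.
#'
#' @param response Data frame with columns `sample_id` and `response`
#'   (`"responder"`/`"non-responder"`).
#' @param min_group Minimum per-group size (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
arm_eligible <- function(response, min_group = 5) {
  assert_binary_response(response)
  sum(response$response == "responder") >= min_group &&
    sum(response$response == "non-responder") >= min_group
}
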