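# ggplot2 views of the main result types. All plot_* functions return a
# ggplot object so callers can restyle them.

#' Plot tumor-volume trajectories as percent change from baseline
#'
#' @param volumes Long volume table (see [call_response()]).
#' @param calls Optional response-call tibble to color trajectories by
#'   response class.
#' @param min_day Evaluation-day cutoff drawn as a vertical reference.
#' @return A ggplot object.
#' @export
plot_volume_series <- function(volumes, calls = NULL, min_day = 10) {
  df <- volumes |>
    dplyr::arrange(.data$model_id, .data$treatment_id, .data$day) |>
    dplyr::mutate(
      dvol = pct_change_series(.data$day, .data$volume_mm3),
      .by = c("model_id", "treatment_id")
    )
  if (!is.null(calls)) {
    df <- dplyr::left_join(df,
                           calls[, c("model_id", "treatment_id",
                                     "mrecist_class")],
                           by = c("model_id", "treatment_id"))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$dvol,
                                          group = .data$model_id,
                                          color = .data$mrecist_class))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$dvol,
                                          group = .data$model_id))
  }
  p +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = min_day, linetype = 3) +
    ggplot2::labs(x = "Day", y = "Volume change from baseline (%)",
                  color = "Class")
}

#' Plot a DCO network
#'
#' Nodes are laid out with a force-directed algorithm; fill encodes the
#' responder-enrichment probability and shape the node source (DiffD,
#' DiP or both); selected co-occurring pairs are drawn as edges.
#'
#' @param network A `dco_network`.
#' @param seed Layout seed (default 1).
#' @return A ggplot object.
#' @export
plot_dco_network <- function(network, seed = 1) {
  stopifnot(inherits(network, "dco_network"))
  if (nrow(network$nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- dco_as_igraph(network)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(network$nodes, x = xy[, 1], y = xy[, 2])
  p <- ggplot2::ggplot()
  if (nrow(network$edges) > 0) {
    seg <- dplyr::left_join(
      network$edges[, c("gene_a", "gene_b")],
      nodes[, c("gene", "x", "y")], by = c("gene_a" = "gene")
    ) |>
      dplyr::left_join(nodes[, c("gene", "x", "y")],
                       by = c("gene_b" = "gene"),
                       suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_b, yend = .data$y_b),
      color = "grey60"
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, fill = .data$p_resp_gt_nonresp,
                   shape = .data$source),
      size = 5
    ) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$gene),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_shape_manual(
      values = c(DiffD = 21, DiP = 22, both = 23), drop = TRUE) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "grey90", high = "#b2182b",
                                  na.value = "grey80",
                                  limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s DCO network: %s", network$flavor,
                                  network$treatment_id),
                  fill = "P(resp > nonresp)", shape = "Source") +
    ggplot2::theme_void()
}

#' @rdname plot_dco_network
#' @param object A `dco_network`.
#' @param ... Unused.
#' @export
autoplot.dco_network <- function(object, ...) plot_dco_network(object)

#' Plot combined LOOCV scores of a model bundle
#'
#' Waterfall of per-sample combined scores, colored by the true response
#' group; the score sign is the predicted class.
#'
#' @param bundle A `treatment_model_bundle`.
#' @return A ggplot object.
#' @export
plot_combined_scores <- function(bundle) {
  stopifnot(inherits(bundle, "treatment_model_bundle"))
  df <- bundle$combined |>
    dplyr::arrange(.data$wcomb) |>
    dplyr::mutate(idx = dplyr::row_number(),
                  truth_label = ifelse(.data$truth == 1, "responder",
                                       "non-responder"))
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$wcomb,
                                   fill = .data$truth_label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Sample (sorted)", y = "Combined score",
                  fill = "True group",
                  title = sprintf("%s: combined LOOCV scores (BAcc %.2f)",
                                  bundle$treatment_id,
                                  bundle$bacc_combined))
}

#' @rdname plot_combined_scores
#' @param object A `treatment_model_bundle`.
#' @param ... Unused.
#' @export
autoplot.treatment_model_bundle <- function(object, ...) {
  plot_combined_scores(object)
}

#' Plot a status-stratified interaction summary
#'
#' @param summary Tibble from [interaction_summary()].
#' @return A ggplot object.
#' @export
plot_interaction_summary <- function(summary) {
  long <- tidyr::pivot_longer(summary,
                              c("mean_contrib_a", "mean_contrib_b"),
                              names_to = "gene_role",
                              values_to = "mean_contribution") |>
    dplyr::mutate(gene = ifelse(.data$gene_role == "mean_contrib_a",
                                .data$gene_a, .data$gene_b))
  ggplot2::ggplot(long, ggplot2::aes(.data$category,
                                     .data$mean_contribution,
                                     fill = .data$gene)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Alteration status (A & B)",
                  y = "Mean Shapley contribution", fill = "Gene")
}

#' Kaplan-Meier plot of predicted response groups
#'
#' @param groups,durations,events As in [survival_evaluation()].
#' @return A ggplot object.
#' @export
plot_survival_groups <- function(groups, durations, events) {
  fit <- survival::survfit(survival::Surv(durations, events) ~ groups)
  df <- tibble::tibble(
    time = fit$time,
    surv = fit$surv,
    group = rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Progression-free fraction",
                  color = "Predicted group")
}
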