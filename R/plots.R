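# ggplot2 views of the pipeline's result objects.

#' Histogram of probabilistic match scores
#'
#' Score distribution of scored candidate pairs, with the acceptance
#' threshold marked. If a ground-truth table is supplied, bars are filled
#' by true-pair status, showing the separation the threshold exploits.
#'
#' @param scored Output of [score_pairs()].
#' @param threshold Threshold to mark.
#' @param truth Optional ground-truth tibble.
#' @return A ggplot object.
#' @export
plot_match_scores <- function(scored, threshold = fs_default_threshold(),
                              truth = NULL) {
  d <- scored
  if (!is.null(truth)) {
    d <- d |>
      left_join(mutate(truth, .true = TRUE),
                by = c("study_id", "offender_id")) |>
      mutate(pair = if_else(is.na(.data$.true), "false pair", "true pair"))
  } else {
    d$pair <- "candidate pair"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$pair)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "match score (sum of log2 likelihood-ratio weights)",
                  y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Linkage flow chart as a bar diagram
#'
#' @param flow A [flow_report()] tibble.
#' @return A ggplot object.
#' @export
plot_flow <- function(flow) {
  d <- mutate(flow, stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.15,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .12))) +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}

#' Offence-group mix of eligible records
#'
#' @param linked_events Output of [filter_events()] (or any tibble with an
#'   `offence_group` column).
#' @return A ggplot object.
#' @export
plot_offence_mix <- function(linked_events) {
  d <- linked_events |>
    count(.data$offence_group) |>
    mutate(share = 100 * .data$n / sum(.data$n))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$share,
    y = stats::reorder(.data$offence_group, .data$share))) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "% of records", y = NULL) +
    ggplot2::theme_minimal()
}

#' In-area residence proportion by birthday age
#'
#' @param denominator A [denominator_summary()] result.
#' @return A ggplot object.
#' @export
plot_denominator <- function(denominator) {
  ggplot2::ggplot(denominator$by_age,
                  ggplot2::aes(x = .data$age, y = .data$proportion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = denominator$all_ages,
                        linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "age (birthday)", y = "proportion resident in area") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a link table
#'
#' @param object A `link_table`.
#' @param ... Unused.
#' @return A ggplot object: links by method and deterministic strength.
#' @export
autoplot.link_table <- function(object, ...) {
  d <- object$links |>
    mutate(class = dplyr::coalesce(
      ifelse(.data$method == "deterministic",
             paste0("deterministic s", .data$strength), NA),
      "probabilistic")) |>
    count(.data$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::labs(x = NULL, y = "links") +
    ggplot2::theme_minimal()
}
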