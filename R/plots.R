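#' Plot an evaluation report
#'
#' Point estimates for precision and recall with their exact binomial
#' confidence intervals.
#'
#' @param object An `ocs_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocs_eval <- function(object, ...) {
  d <- tidy(object) %>% dplyr::filter(.data$metric != "f1")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "Instance-level performance",
                  subtitle = sprintf("%.0f%% exact binomial intervals",
                                     100 * object$conf_level)) +
    ggplot2::theme_minimal()
}

#' Plot detection results
#'
#' Instance counts by fired inclusion rule, split by final verdict — a
#' quick audit of which routes and vetoes are doing the work.
#'
#' @param object An `ocs_annotations` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocs_annotations <- function(object, ...) {
  d <- object$instances %>%
    dplyr::count(.data$fired_rule, .data$final)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fired_rule, y = .data$n,
                                  fill = .data$final)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "inclusion route", y = "instances",
                  fill = "verdict",
                  title = "Instances by inclusion route and verdict") +
    ggplot2::theme_minimal()
}

#' Plot exclusion-category frequencies
#'
#' How often each veto category fired across a set of classified
#' instances.
#'
#' @param annotations An `ocs_annotations` object.
#' @return A ggplot object.
#' @export
plot_exclusion_counts <- function(annotations) {
  d <- annotations$instances %>%
    dplyr::select("instance_id", "exclusions") %>%
    tidyr::unnest("exclusions")
  if (!nrow(d)) {
    d <- tibble::tibble(category = character(), n = integer())
  } else {
    d <- dplyr::count(d, .data$category)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "exclusion category", y = "triggers fired",
                  title = "Exclusion triggers across instances") +
    ggplot2::theme_minimal()
}
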