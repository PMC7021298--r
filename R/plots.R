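# ggplot2 displays for flags, calls and validation reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise key identifiers: frequency, sensitivity, specificity
#'
#' Per-identifier frequency among all episodes and, when gold-standard
#' labels are present, the identifier's own sensitivity and specificity for
#' true AIS (the screening-property display of the flag panel).
#'
#' @param flags A flags tibble from [extract_identifiers()], optionally
#'   carrying `true_ais`.
#' @return A tibble with `identifier`, `frequency` and, with labels,
#'   `sensitivity` and `specificity`.
#' @export
summarise_identifiers <- function(flags) {
  flags <- as_tibble(flags)
  ids <- identifier_names()
  out <- tibble(
    identifier = factor(ids, levels = ids),
    frequency = vapply(ids, function(i) mean(flags[[i]]), numeric(1))
  )
  if ("true_ais" %in% names(flags)) {
    out$sensitivity <- vapply(
      ids, function(i) mean(flags[[i]][flags$true_ais]), numeric(1)
    )
    out$specificity <- vapply(
      ids, function(i) mean(!flags[[i]][!flags$true_ais]), numeric(1)
    )
  }
  out
}

#' Plot the key-identifier summary
#'
#' Dot plot of per-identifier frequency, and sensitivity/specificity when
#' labels are available.
#'
#' @inheritParams summarise_identifiers
#' @return A ggplot object.
#' @export
plot_identifier_summary <- function(flags) {
  s <- summarise_identifiers(flags)
  long <- tidyr::pivot_longer(s, -identifier, names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = value, y = identifier,
                                     colour = metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = "Key identifiers") +
    ggplot2::theme_minimal()
}

#' @describeIn classify_episodes Plot episodes per trajectory, coloured by
#'   call label.
#' @param object A `stroke_calls` object.
#' @param ... Unused.
#' @export
autoplot.stroke_calls <- function(object, ...) {
  counts <- as_tibble(object) %>%
    count(trajectory_id, label)
  ggplot2::ggplot(counts, ggplot2::aes(x = n, y = trajectory_id,
                                       fill = label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "episodes", y = NULL, fill = "call",
                  title = "Episodes per decision trajectory") +
    ggplot2::theme_minimal()
}

#' @describeIn validate_algorithm Bar chart of the five diagnostic metrics
#'   by partition.
#' @param object A `stroke_validation` object.
#' @param ... Unused.
#' @export
autoplot.stroke_validation <- function(object, ...) {
  long <- tidy(object) %>% filter(partition != "overall")
  ggplot2::ggplot(long, ggplot2::aes(x = metric, y = estimate,
                                     fill = partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Diagnostic performance by partition") +
    ggplot2::theme_minimal()
}
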