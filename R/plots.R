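# ggplot2 views of the result tables: binned deletion-length distributions
# and length scatter plots with group medians.

#' @importFrom ggplot2 ggplot aes geom_col geom_jitter facet_wrap labs
#'   stat_summary theme_bw autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a binned deletion-length distribution
#'
#' @param object A `length_distribution` from [bin_deletions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot length_distribution
#' @export
autoplot.length_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$fraction)) +
    geom_col(fill = "grey35") +
    labs(x = "deletion length (bp)", y = "fraction of events") +
    theme_bw()
}

#' Deletion-length distributions per genotype and nuclease
#'
#' Grouped bar chart of the binned deletion-length fractions produced by
#' [run_analyze()] (its `distributions` table) or built manually.
#'
#' @param distributions Tibble with `genotype`, `nuclease`, `bin`,
#'   `fraction`.
#' @return A ggplot.
#' @export
plot_deletion_bins <- function(distributions) {
  ggplot(distributions,
         aes(x = .data$bin, y = .data$fraction, fill = .data$genotype)) +
    geom_col(position = "dodge") +
    facet_wrap(~nuclease) +
    labs(x = "deletion length (bp)", y = "fraction of events",
         fill = "genotype") +
    theme_bw()
}

#' Scatter plot of event lengths with group medians
#'
#' Deletion or insertion lengths per genotype, one jittered point per
#' deduplicated event, with the group median drawn as a horizontal bar.
#'
#' @param events Deduplicated event tibble.
#' @param measure `"del_len"` or `"ins_len"`.
#' @return A ggplot.
#' @export
plot_length_scatter <- function(events, measure = c("del_len", "ins_len")) {
  measure <- match.arg(measure)
  df <- if (measure == "del_len") {
    filter(events, .data$event_class %in% c("deletion", "delins"))
  } else {
    filter(events, .data$event_class %in% c("insertion", "delins")) |>
      mutate(ins_len = nchar(.data$ins_seq))
  }
  ggplot(df, aes(x = .data$genotype, y = .data[[measure]])) +
    geom_jitter(width = 0.2, alpha = 0.6, size = 1) +
    stat_summary(fun = median, geom = "crossbar", width = 0.5,
                 linewidth = 0.4, colour = "red") +
    labs(x = NULL,
         y = if (measure == "del_len") "deletion length (bp)"
             else "insertion length (bp)") +
    theme_bw()
}
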