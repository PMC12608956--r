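#' Bubble-plot data for the step-count-ratio distributions
#'
#' Aggregates ratios into bubbles per condition x rounded ratio value, with
#' bubble size (area) proportional to the number of observations, plus the
#' per-condition mean — the numeric content behind the distribution plots.
#'
#' @param data A `ratio_dataset`.
#' @param bin Ratio rounding width for bubble aggregation (default 0.05,
#'   i.e. one device count at 20 true steps).
#' @return A list with `bubbles` (pat, condition, ratio, n) and `means`
#'   (pat, condition, mean_ratio).
#' @export
ratio_distribution_data <- function(data, bin = 0.05) {
  d <- data.frame(pat = data$pat,
                  condition = factor(data$condition,
                                     levels = intersect(protocol_codes(),
                                                        unique(data$condition))),
                  ratio = round(data$ratio / bin) * bin)
  bubbles <- stats::aggregate(list(n = d$ratio),
                              by = list(pat = d$pat,
                                        condition = d$condition,
                                        ratio = d$ratio),
                              FUN = length)
  means <- stats::aggregate(list(mean_ratio = data$ratio),
                            by = list(pat = data$pat,
                                      condition = factor(
                                        data$condition,
                                        levels = levels(d$condition))),
                            FUN = mean)
  list(bubbles = bubbles[order(bubbles$pat, bubbles$condition,
                               bubbles$ratio), ],
       means = means[order(means$pat, means$condition), ])
}

#' Plot the step-count-ratio distributions per tracker and condition
#'
#' One panel per tracker: bubbles at each (condition, ratio) with area
#' proportional to the number of observations, overlaid with the
#' per-condition mean curve. Rendering details are best-effort; the
#' underlying numbers come from [ratio_distribution_data()].
#'
#' @inheritParams ratio_distribution_data
#' @param file Optional path (e.g. `.png` or `.pdf`) to save the figure to.
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_ratio_distributions <- function(data, bin = 0.05, file = NULL) {
  dd <- ratio_distribution_data(data, bin = bin)
  p <- ggplot2::ggplot(dd$bubbles,
                       ggplot2::aes(x = condition, y = ratio)) +
    ggplot2::geom_point(ggplot2::aes(size = n), alpha = 0.6,
                        colour = "grey30") +
    ggplot2::geom_line(data = dd$means,
                       ggplot2::aes(y = mean_ratio, group = 1),
                       colour = "red") +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::facet_wrap(~pat) +
    ggplot2::labs(x = "condition", y = "step count ratio",
                  size = "trials") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 6)
    return(invisible(p))
  }
  p
}

#' Plot intra-rater reproducibility per participant
#'
#' Dot plot of each participant's intra-rater kappa and ICC for the
#' analysed trackers, with a dashed line at the across-participant mean.
#'
#' @param report A `study_report`.
#' @param file Optional output path.
#' @return The ggplot object.
#' @export
plot_intra_rater <- function(report, file = NULL) {
  stopifnot(inherits(report, "study_report"))
  tab <- report$intra
  long <- rbind(
    data.frame(pat = tab$pat, participant_id = tab$participant_id,
               statistic = "kappa",
               value = ifelse(tab$kappa_suppressed, NA, tab$kappa)),
    data.frame(pat = tab$pat, participant_id = tab$participant_id,
               statistic = "ICC",
               value = ifelse(tab$icc_suppressed, NA, tab$icc)))
  means <- stats::aggregate(value ~ pat + statistic, data = long,
                            FUN = mean, na.rm = TRUE)
  p <- ggplot2::ggplot(long[!is.na(long$value), ],
                       ggplot2::aes(x = value,
                                    y = factor(participant_id))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = value),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(pat ~ statistic) +
    ggplot2::labs(x = "value", y = "participant") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 6)
    return(invisible(p))
  }
  p
}
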