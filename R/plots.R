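#' Plot a Pareto frontier
#'
#' Parsimony (rule + affix bits) against fit (total stem bits), both axes
#' oriented so better grammars sit toward the upper right; frontier points
#' are labeled with their rule/affix analysis.
#'
#' @param object A `pareto_frontier` (from [pareto_synthesize()] or
#'   [agl_pareto()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_frontier <- function(object, ...) {
  df <- tibble::tibble(parsimony = -object$parsimony_bits,
                       fit = -object$fit_bits,
                       label = object$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parsimony, y = .data$fit)) +
    ggplot2::geom_step(direction = "hv", colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       hjust = -0.05, vjust = -0.4, size = 2.8) +
    ggplot2::labs(x = "parsimony (-(rule + affix) bits)",
                  y = "fit to data (-stem bits)",
                  title = "Pareto frontier of consistent grammars") +
    ggplot2::theme_minimal()
}

#' Plot AGL discrimination results
#'
#' Mean log-odds (consistent vs inconsistent held-out words) with one bar
#' per condition and the individual word pairs overplotted.
#'
#' @param results A tibble with columns `pattern`, `n`, `mode` and
#'   `log_odds` (one row per test pair), e.g. built from [log_odds()]
#'   outputs.
#' @return A ggplot object.
#' @export
plot_log_odds <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$n), y = .data$log_odds,
                               fill = .data$mode)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.9),
                        size = 0.7, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$pattern) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "training words (n)",
                  y = "log P(consistent) - log P(inconsistent)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
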