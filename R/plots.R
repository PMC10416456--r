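## ggplot2 figures for the main result types. Plain defaults; aesthetics
## are the caller's business.

#' Plot the metagene density of peak midpoints
#'
#' @param metagene Output of [metagene_density()].
#' @return A ggplot: density over the normalized transcript coordinate with
#'   the 5'UTR/CDS/3'UTR segment boundaries marked.
#' @export
plot_metagene <- function(metagene) {
  ggplot2::ggplot(metagene, ggplot2::aes(x = .data$coord, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = c(0.5, 1.5, 2.5),
                                labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "peak density")
}

#' Plot per-stage m6A level distributions
#'
#' @param object An [m6a_profile()] object.
#' @param ... Unused.
#' @return A ggplot: per-stage boxplots of log2 peak m6A levels.
#' @method autoplot m6a_profile
#' @export
autoplot.m6a_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$stage, y = log2(.data$level))) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "log2 m6A level (IP/input)")
}

#' Plot change-class and origin fractions
#'
#' @param object A [peak_dynamics()] object.
#' @param ... Unused.
#' @return A ggplot: bar chart of the change-count class fractions.
#' @method autoplot peak_dynamics
#' @export
autoplot.peak_dynamics <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$change_count),
                               y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "transitions with m6A change", y = "fraction of peaks")
}

#' Plot co-dynamics category counts
#'
#' @param object A [co_dynamics()] result.
#' @param ... Unused.
#' @return A ggplot: bar chart of the five category counts.
#' @method autoplot m6a_codynamics
#' @export
autoplot.m6a_codynamics <- function(object, ...) {
  labels <- c("1 no change", "2 access only", "3 m6A only",
              "4 discordant", "5 concordant")
  dat <- object$summary %>% mutate(label = labels[.data$category])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot m6A change magnitude along the PCC rank
#'
#' @param bins Output of [pcc_bins()].
#' @return A ggplot: mean absolute fold change per bin, one line per
#'   transition.
#' @export
plot_pcc_bins <- function(bins) {
  ggplot2::ggplot(bins$bins,
                  ggplot2::aes(x = .data$bin, y = .data$mean_abs_fc,
                               colour = .data$transition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "PCC rank bin (accessibility vs m6A)",
                  y = "mean |fold change| of m6A")
}
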