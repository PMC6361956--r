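# ggplot2 autoplot() methods for the main result types.

#' Plot a stage-2 protein fit
#'
#' Density of the posterior fold-change distribution with the test threshold
#' marked, mirroring the per-protein probability-distribution plots a study
#' database would show.
#'
#' @param object An `itraq_fit`.
#' @param threshold Fold-change threshold to mark (default 1.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itraq_fit <- function(object, threshold = 1.05, ...) {
  df <- tibble::tibble(fc = exp(object$theta_draws))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(1 / threshold, threshold),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fold change (case / control)", y = "posterior density",
                  title = object$protein,
                  subtitle = sprintf("mean log ratio %.3f, 95%% HPD [%.3f, %.3f]",
                                     object$mean_log_ratio,
                                     object$hpd["lower"], object$hpd["upper"]))
}

#' Plot normalisation factors
#'
#' Posterior mean and +/- 2 SD interval of the median log ratio for each
#' channel, faceted by run.
#'
#' @param object An `itraq_norm` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itraq_norm <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                          ymax = .data$mean + 2 * .data$sd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~run) +
    ggplot2::labs(x = "iTRAQ channel", y = "median log ratio vs 113",
                  title = "Sample normalisation factors")
}

#' Plot differential calls
#'
#' Posterior mean log fold change against local FDR, coloured by global-FDR
#' significance.
#'
#' @param object An `itraq_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itraq_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$significant %in% TRUE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_log_ratio, y = .data$lfdr,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "posterior mean log fold change (case / control)",
                  y = "local FDR", colour = "significant")
}

#' Plot per-region change proportions
#'
#' @param object An `itraq_region_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itraq_region_summary <- function(object, ...) {
  df <- object$per_region
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "region", y = "proportion of quantified proteins changed")
}
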