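# ggplot2 views of the result objects.

#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linetype = "dotted", linewidth = 0.5, colour = "grey30") +
    ggplot2::labs(x = "Mean of methods", y = "Difference",
                  title = sprintf("Bland-Altman (bias %.3g, LoA %.3g to %.3g)",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mountain_plot <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$diff, y = .data$folded)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$median, linewidth = 0.5) +
    ggplot2::geom_vline(xintercept = object$ci95, linetype = "dashed") +
    ggplot2::labs(x = "Difference", y = "Folded empirical CDF",
                  title = "Mountain plot") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.match_profile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$count)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "in-silico CT slice", y = "matched keypoints",
                  title = sprintf("Keypoint profile (matched index %d)",
                                  object$matched_index)) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "darkorange")
  p
}

#' @export
autoplot.agreement_report <- function(object, ...) {
  dfs <- lapply(names(object$bland_altman), function(p) {
    d <- object$bland_altman[[p]]$data
    d$parameter <- p
    d
  })
  df <- dplyr::bind_rows(dfs)
  stats <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::geom_hline(data = stats, ggplot2::aes(yintercept = .data$bias),
                        linewidth = 0.5) +
    ggplot2::geom_hline(data = stats, ggplot2::aes(yintercept = .data$loa_low),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = stats, ggplot2::aes(yintercept = .data$loa_high),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (B - A)") +
    ggplot2::theme_minimal()
}
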