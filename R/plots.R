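#' Score plot of an OPLS model
#'
#' Predictive vs orthogonal component scores, coloured by class, with
#' the Hotelling T-squared confidence ellipse used for homogeneity
#' screening.
#'
#' @param object A fitted `opls` model.
#' @param level Confidence level of the ellipse (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot opls
#' @export
autoplot.opls <- function(object, level = 0.95, ...) {
  s <- object$scores
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$Tp, y = .data$To,
                                       colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "predictive score (Tp)",
                  y = "orthogonal score (To)", colour = NULL) +
    ggplot2::theme_minimal()
  if (object$has_orth && nrow(s) > 3) {
    V <- stats::cov(cbind(s$Tp, s$To))
    n <- nrow(s)
    r2 <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
    ang <- seq(0, 2 * pi, length.out = 181)
    ell <- t(chol(V)) %*% rbind(cos(ang), sin(ang)) * sqrt(r2)
    edf <- tibble::tibble(Tp = ell[1, ] + mean(s$Tp),
                          To = ell[2, ] + mean(s$To))
    p <- p + ggplot2::geom_path(data = edf, ggplot2::aes(x = .data$Tp,
                                                         y = .data$To),
                                inherit.aes = FALSE, colour = "grey40")
  }
  p
}

#' Volcano-style overview of screening results
#'
#' Status effect size (partial eta-squared, signed by direction)
#' against -log10 p, with the significance threshold marked.
#'
#' @param object A `screen_result` from [screen_variables()].
#' @param alpha Significance threshold to draw (default the one used
#'   for coding).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, alpha = NULL, ...) {
  alpha <- alpha %||% attr(object, "alpha") %||% 0.05
  d <- dplyr::mutate(tibble::as_tibble(object),
                     signed_eta = ifelse(.data$direction == "up", 1, -1) *
                       .data$eta_p_sq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_eta,
                                  y = -log10(.data$p_MS))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_MS < alpha),
                        show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(paste("signed ", eta[p]^2,
                                       " (patients vs controls)")),
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Trend-triplet panel plot
#'
#' Diverging bars of significant-up and significant-down counts per
#' panel, annotated with the trend-test p-value.
#'
#' @param trends A tibble from [panel_trends()].
#' @return A ggplot object.
#' @export
plot_trends <- function(trends) {
  d <- tidyr::pivot_longer(trends, c("n_up", "n_down"),
                           names_to = "side", values_to = "count")
  d$count <- ifelse(d$side == "n_down", -d$count, d$count)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count,
                                  y = stats::reorder(.data$group_name,
                                                     .data$p_value),
                                  fill = .data$side)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_text(data = trends,
                       ggplot2::aes(x = Inf, y = .data$group_name,
                                    label = .data$label),
                       inherit.aes = FALSE, hjust = 1.02, size = 3) +
    ggplot2::scale_fill_manual(values = c(n_up = "firebrick",
                                          n_down = "steelblue")) +
    ggplot2::labs(x = "significantly lower | higher (count)", y = NULL) +
    ggplot2::theme_minimal()
}
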