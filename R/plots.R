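# ggplot2 visualisations for the main result types.

#' Plot a fitted efficiency mixture over its data
#'
#' Histogram of the fitted efficiencies with the weighted component densities
#' and their sum overlaid.
#'
#' @param object A [fit_gmm()] result.
#' @param bins Histogram bins (display only; the fit itself is unbinned).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gmm_fit <- function(object, bins = 80, ...) {
  df <- tibble(e = object$data)
  grid <- tibble(e = seq(min(df$e), max(df$e), length.out = 512))
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble(e = grid$e, component = paste0("S", j),
           density = object$weights[j] * dnorm(grid$e, object$means[j],
                                               object$sigmas[j]))
  })
  total <- comp %>%
    group_by(.data$e) %>%
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linewidth = 0.9) +
    ggplot2::labs(x = "FRET efficiency", y = "density",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a BIC scan
#'
#' @param object A [scan_k()] result.
#' @param ... Unused.
#' @return A ggplot with the selected state count highlighted.
#' @export
autoplot.bic_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of states k", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Plot a Hill dose-response fit
#'
#' @param object A [fit_hill()] result.
#' @param ... Unused.
#' @return A ggplot of the replicate data and the fitted curve on a
#'   log-concentration axis.
#' @export
autoplot.hill_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration_uM,
                                         y = .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = "response (% of control)") +
    ggplot2::theme_minimal()
  if (!is.na(object$ic50)) {
    grid <- tibble(concentration_uM = exp(seq(log(min(dat$concentration_uM)),
                                              log(max(dat$concentration_uM)),
                                              length.out = 200)))
    grid$response_pct <- hill_response(grid$concentration_uM, object$A,
                                       object$B, object$ic50, object$hill_n)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot the binning/cross-correlation control
#'
#' Mean donor/acceptor Pearson correlation (with SD ribbon) against bin
#' size: fast switching is strongly anti-correlated at native resolution and
#' collapses to zero once many transitions are averaged into each bin.
#'
#' @param object A [control_experiment()] summary.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crosscorr_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_size, y = .data$mean_rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rho - .data$sd_rho,
                                      ymax = .data$mean_rho + .data$sd_rho),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = object$bin_size) +
    ggplot2::labs(x = "frames per bin", y = "Pearson ρ (I_DD vs I_DA)") +
    ggplot2::theme_minimal()
}
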