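#' Plot binned accuracy of a simulation
#'
#' Accuracy per trial bin with vertical lines at the task-rule switches and a
#' dashed line at chance level.
#'
#' @param object A `sync_sim`.
#' @param n_bins Number of bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sync_sim <- function(object, n_bins = 120, ...) {
  bins <- bin_metrics(object, n_bins)
  switches <- which(diff(bins$block) != 0) + 0.5
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = switches, colour = "red", alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed") +
    ggplot2::labs(x = "trial bin", y = "accuracy",
                  title = paste0(object$model, ", beta = ", object$beta)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a learning-rate sweep
#'
#' Mean accuracy, plasticity and stability against the learning rate with
#' `mean +/- 2 SD / sqrt(Nrep)` ribbons.
#'
#' @param object A `sync_sweep` from [sweep_learning_rate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sync_sweep <- function(object, ...) {
  summ <- summarize_sweep(object) |>
    tidyr::pivot_longer(-dplyr::any_of(c("beta", "freq_ctrl", "freq_proc",
                                         "damp_ctrl", "rmin_ctrl", "n_rep")),
                        names_to = c("metric", "stat"), names_sep = "_(?=mean$|ci$)") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$beta, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$ci,
                                      ymax = .data$mean + .data$ci),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "learning rate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of a time-frequency (or contrast) matrix
#'
#' @param object A `sync_tfr` or `sync_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sync_contrast <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time since feedback (s)", y = "frequency (Hz)",
                  fill = "error - correct") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sync_contrast
#' @export
autoplot.sync_tfr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
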