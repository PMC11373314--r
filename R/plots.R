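# ggplot2 displays for fit objects and evaluation reports.

#' Plot the training history of a linker VAE
#'
#' Loss components (total, reconstruction, KL) and decision accuracy per
#' epoch.
#'
#' @param object A `linker_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linker_fit
#' @export
autoplot.linker_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss_curve,
                            cols = c("total", "recon", "kl", "accuracy"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Linker VAE training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot an evaluation report
#'
#' Bar chart of the six generation metrics.
#'
#' @param object A `linker_eval` ([evaluate_molecules()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linker_eval
#' @export
autoplot.linker_eval <- function(object, ...) {
  metrics <- c("validity", "uniqueness", "novelty", "sa_pass",
               "aromatic_ring_pass", "pains_pass")
  df <- tibble::tibble(
    metric = factor(metrics, levels = metrics),
    value = as.numeric(object[1, metrics])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction",
                  title = "Generation metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Compare pass rates between sampling arms
#'
#' Side-by-side bars of property pass rates ([pass_rates()]) for, e.g.,
#' random versus rejection-sampled generation.
#'
#' @param ... Named pass-rate tibbles (one per arm).
#' @return A ggplot object.
#' @export
plot_pass_rate_comparison <- function(...) {
  arms <- list(...)
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    stop("pass-rate tibbles must be named by arm", call. = FALSE)
  }
  df <- dplyr::bind_rows(lapply(names(arms), function(nm) {
    dplyr::mutate(arms[[nm]], arm = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$pass_rate,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "pass rate") +
    ggplot2::theme_minimal()
}
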