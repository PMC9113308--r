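## ggplot2 displays for the harness result types.

#' Plot a closed-form verification report
#'
#' One point per grid cell and topology, showing the Monte-Carlo z-score of
#' the closed-form prediction; the dashed lines mark the +/- 4 SE band.
#'
#' @param object a `closed_form_report` from [check_closed_forms()].
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.closed_form_report <- function(object, ...) {
  df <- object$cells |>
    dplyr::mutate(cell = paste0(.data$shape, "/", .data$dup_case, " x=",
                                .data$x, " y=", .data$y,
                                ifelse(is.na(.data$t), "",
                                       paste0(" t=", .data$t)))) |>
    tidyr::pivot_longer(dplyr::all_of(c("z_match", "z_alt1", "z_alt2")),
                        names_to = "topology", values_to = "z",
                        names_prefix = "z_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$cell,
                                   colour = .data$topology)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-4, 4), linetype = "dashed") +
    ggplot2::labs(x = "(closed form - MC) / SE", y = NULL,
                  title = "Closed-form quartet probabilities vs simulation") +
    ggplot2::theme_minimal()
}

#' Plot a convergence report
#'
#' Fraction of replicate datasets whose dominant quartet equals the
#' species-tree quartet, against the number of gene families.
#'
#' @param object a `convergence_report` from [convergence_experiment()].
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.convergence_report <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$m, y = .data$fraction_correct,
                               colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "gene families", y = "fraction recovering species tree",
                  title = "Quartet-based species-tree recovery under DLCoal") +
    ggplot2::theme_minimal()
}

#' @export
plot.closed_form_report <- function(x, ...) print(autoplot.closed_form_report(x, ...))

#' @export
plot.convergence_report <- function(x, ...) print(autoplot.convergence_report(x, ...))
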