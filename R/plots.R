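#' Plot a fitted model
#'
#' `type = "curves"` overlays observed response curves and fitted regression
#' curves for a few subjects; `type = "theta"` shows the estimated component
#' scales as a lollipop chart, selected components highlighted.
#'
#' @param object an [fcr_fit()].
#' @param type `"curves"` or `"theta"`.
#' @param subjects subject ids to show (default the first 4).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fcr_fit
#' @export
autoplot.fcr_fit <- function(object, type = c("curves", "theta"),
                             subjects = NULL, ...) {
  type <- match.arg(type)
  if (type == "theta") {
    td <- tidy(object)
    td$term <- factor(td$term, levels = td$term)
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$theta,
                                       colour = .data$selected)) +
        ggplot2::geom_segment(ggplot2::aes(xend = .data$term, yend = 0)) +
        ggplot2::geom_point(size = 2) +
        ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                                `FALSE` = "grey65")) +
        ggplot2::labs(x = NULL, y = expression(hat(theta)[v]),
                      colour = "selected") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    )
  }
  aug <- augment(object)
  if (is.null(subjects)) subjects <- utils::head(unique(aug$subject_id), 4L)
  aug <- dplyr::filter(aug, .data$subject_id %in% subjects)
  long <- tidyr::pivot_longer(aug, c("y", ".fitted"), names_to = "series",
                              values_to = "value")
  long$series <- factor(long$series, levels = c("y", ".fitted"),
                        labels = c("observed", "fitted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "t", y = "y(t)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot simulation-study summaries
#'
#' Mean test RMSE per estimator (with one-standard-deviation bars), faceted
#' by model and noise level, against the training-set size.
#'
#' @param object an [fcr_study()].
#' @param metric `"rmse"`, `"spe"`, `"sen"` or `"f1"` (the selection metrics
#'   are available for the selection estimator only).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fcr_study
#' @export
autoplot.fcr_study <- function(object, metric = c("rmse", "spe", "sen", "f1"),
                               ...) {
  metric <- match.arg(metric)
  s <- object$summary
  if (metric != "rmse") s <- dplyr::filter(s, .data$method == "l1")
  mcol <- paste0("mean_", metric); scol <- paste0("sd_", metric)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$n), y = .data[[mcol]],
                                  colour = .data$method,
                                  group = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.15) +
    ggplot2::facet_grid(sigma ~ model,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "training-set size n", y = paste("mean", metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
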