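#' Plot a simulated learner's error curve
#'
#' Mean unsigned error per shot with a plus/minus one SD ribbon across
#' repetitions.
#'
#' @param object A `vml_curves` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vml_curves <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shot, y = .data$mean_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$mean_error - .data$sd_error, 0),
        ymax = .data$mean_error + .data$sd_error
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "shot", y = "mean unsigned error",
      title = paste0(object$order, "-order learner (", object$n_reps, " repetitions)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot subject-by-subject contest results
#'
#' One cluster per subject: the human early error beside each doppelganger's
#' mean early error with its min-max repetition range.
#'
#' @param object A `vml_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vml_pipeline <- function(object, ...) {
  df <- object$contests |>
    dplyr::mutate(order = factor(.data$order, c("zeroth", "first", "second")))
  humans <- df |>
    dplyr::distinct(.data$subject, .data$human_early)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$subject))) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$dopp_mean, fill = .data$order),
      position = ggplot2::position_dodge(width = 0.8), width = 0.7, alpha = 0.7
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$dopp_min, ymax = .data$dopp_max,
        group = .data$order
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::geom_point(
      data = humans,
      ggplot2::aes(y = .data$human_early),
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "subject", y = "early error (shots 3-7)",
      fill = "learner order",
      title = "Human early error (red) vs optimized doppelgangers"
    ) +
    ggplot2::theme_minimal()
}

#' Plot human and doppelganger error curves for one subject
#'
#' @param pipeline A `vml_pipeline`.
#' @param subject Subject index.
#' @return A ggplot overlaying the subject's own 15-shot error curve with the
#'   mean curves of its doppelgangers.
#' @export
plot_subject_curves <- function(pipeline, subject = 1) {
  prof <- cohort_profiles(pipeline$cohort)
  human <- tibble::tibble(
    shot = seq_along(prof$error_curve[[subject]]),
    mean_error = prof$error_curve[[subject]],
    who = "human"
  )
  dopp <- pipeline$curves |>
    dplyr::filter(.data$subject == .env$subject) |>
    dplyr::transmute(.data$shot, .data$mean_error, who = .data$order)
  ggplot2::ggplot(
    dplyr::bind_rows(human, dopp),
    ggplot2::aes(.data$shot, .data$mean_error, colour = .data$who)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "shot", y = "mean unsigned error", colour = NULL,
      title = paste("Subject", subject, "vs its doppelgangers")
    ) +
    ggplot2::theme_minimal()
}
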