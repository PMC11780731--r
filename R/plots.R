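#' Plot an importance distribution
#'
#' Walk extent against importance on a log-p scale; the threshold range is
#' the rightmost point above the `p_min` line.
#'
#' @param object A [walk_importance()] result.
#' @param p_min Threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_distribution
#' @export
autoplot.importance_distribution <- function(object, p_min = 0.001, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$extent, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = p_min, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "walk extent (Å)", y = "walk importance p",
      title = "Walk importance vs extent"
    )
}

#' Plot a many-bodyness profile
#'
#' @param object A [many_bodyness()] result.
#' @param ... Unused.
#' @return A ggplot object; gamma per distance bin, retained bins filled.
#' @method autoplot many_body_profile
#' @export
autoplot.many_body_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$bin_center, y = .data$gamma, alpha = .data$retained)
  ) +
    ggplot2::geom_col(width = object$bin_width[1] * 0.9) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::labs(
      x = "pair distance (Å)", y = expression(gamma(R)),
      title = sprintf("Many-bodyness (mean over bins = %.3g)",
                      attr(object, "gamma_bar"))
    )
}

#' Plot a decay fit
#'
#' Binned median strengths with both fitted decay laws overlaid.
#'
#' @param object A [decay_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  bins <- object$bins
  grid <- tibble::tibble(
    center = seq(min(bins$center), max(bins$center), length.out = 100)
  )
  grid$exponential <- object$exponential$prefactor *
    exp(-object$exponential$rate * grid$center)
  grid$power_law <- object$power_law$prefactor *
    grid$center^object$power_law$exponent
  long <- tidyr::pivot_longer(grid, -"center",
    names_to = "model", values_to = "strength"
  )
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_strength)) +
    ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$strength, color = .data$model)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "pair distance (Å)", y = "median interaction strength",
      title = paste("Decay of interaction strength; preferred:",
                    object$preferred)
    )
}

#' Plot training history
#'
#' @param model An `ff_model`, or a history tibble with `epoch`,
#'   `train_rmse`, `val_rmse` (and optionally `depth`).
#' @return A ggplot object.
#' @export
plot_training <- function(model) {
  history <- if (inherits(model, "ff_model")) model$history else model
  long <- tidyr::pivot_longer(history,
    dplyr::any_of(c("train_rmse", "val_rmse")),
    names_to = "split", values_to = "rmse"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$rmse, color = .data$split
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "RMSE (kcal/mol)")
  if ("depth" %in% names(long)) {
    p <- p + ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both)
  }
  p
}

#' Plot interaction range tracked over training
#'
#' @param range_tracking The `range_tracking` table of an
#'   [run_experiment()] report.
#' @return A ggplot object: per-checkpoint mean threshold range with SD
#'   ribbon, one facet per model depth.
#' @export
plot_range_tracking <- function(range_tracking) {
  agg <- range_tracking |>
    dplyr::group_by(.data$depth, .data$epoch) |>
    dplyr::summarise(
      mean_lambda = mean(.data$lambda_thresh),
      sd_lambda = stats::sd(.data$lambda_thresh),
      .groups = "drop"
    )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$epoch, y = .data$mean_lambda)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_lambda - .data$sd_lambda,
        ymax = .data$mean_lambda + .data$sd_lambda
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "training epoch", y = "interaction range λ (Å)",
      title = "Interaction range over training"
    )
}
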