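#' Plot a basin-size trajectory
#'
#' Step plot of exhaustive target-basin size against presentation count —
#' the signature staircase of discontinuous basin growth.
#'
#' @param object A `presentation_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot presentation_run
#' @export
autoplot.presentation_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$j,
                                                  y = .data$basin_size)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "target presentations",
                  y = "target basin size (states)") +
    ggplot2::theme_minimal()
}

#' Plot pooled trajectories of a basin study
#'
#' Mean basin size across runs with a band of run-to-run spread.
#'
#' @param object A `basin_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot basin_study
#' @export
autoplot.basin_study <- function(object, ...) {
  summ <- dplyr::summarise(
    dplyr::group_by(object$trajectories, .data$j),
    mean_size = mean(.data$basin_size),
    lo = stats::quantile(.data$basin_size, 0.1),
    hi = stats::quantile(.data$basin_size, 0.9),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$j, y = .data$mean_size)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target presentations",
                  y = "mean target basin size (states)") +
    ggplot2::theme_minimal()
}

#' Plot empirical and fitted distributions of a model comparison
#'
#' Either the CDF on linear axes or the complementary CDF on log-log
#' axes, with the fitted candidate curves overlaid (the CCDF point at the
#' sample maximum is zero and is dropped from the log-scale panel).
#'
#' @param object A `model_comparison`.
#' @param which `"ccdf"` (default) or `"cdf"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, which = c("ccdf", "cdf"), ...) {
  which <- match.arg(which)
  emp <- empirical_cdf_ccdf(object$data)
  grid <- exp(seq(log(min(object$data)), log(max(object$data)),
                  length.out = 200))
  fitted <- purrr::map_dfr(object$fits, function(f) {
    tibble::tibble(model = f$model, value = grid,
                   cdf = dist_fit_cdf(f, grid))
  })
  fitted$ccdf <- 1 - fitted$cdf
  if (which == "cdf") {
    p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$value, y = .data$cdf)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_line(data = fitted,
                         ggplot2::aes(colour = .data$model)) +
      ggplot2::labs(x = "value", y = "CDF", colour = NULL)
  } else {
    p <- ggplot2::ggplot(dplyr::filter(emp, .data$ccdf > 0),
                         ggplot2::aes(x = .data$value, y = .data$ccdf)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_line(data = dplyr::filter(fitted, .data$ccdf > 0),
                         ggplot2::aes(colour = .data$model)) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "value", y = "CCDF", colour = NULL)
  }
  p + ggplot2::theme_minimal()
}

#' Plot sampled-basin accuracy curves
#'
#' Proportion of sampled initial states inside the target basin against
#' presentation count, one curve per Hamming distance.
#'
#' @param object A `sampled_accuracy` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sampled_accuracy
#' @export
autoplot.sampled_accuracy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$j, y = .data$proportion,
                                       colour = factor(.data$k))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "target presentations", y = "proportion in basin",
                  colour = "Hamming k") +
    ggplot2::theme_minimal()
}

#' Plot a condition sweep of jump-size variability
#'
#' Mean per-run CV of positive jump sizes against the swept condition,
#' with standard-error-of-the-mean bars.
#'
#' @param object A `condition_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot condition_sweep
#' @export
autoplot.condition_sweep <- function(object, ...) {
  summ <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(object, !is.na(.data$cv)), .data$condition),
    mean_cv = mean(.data$cv),
    sem = stats::sd(.data$cv) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  xlab <- if (object$sweep[1] == "degradation") {
    "Hamming distance k"
  } else {
    "pretraining stimuli"
  }
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition, y = .data$mean_cv)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_cv - .data$sem,
                                          ymax = .data$mean_cv + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "mean CV of jump sizes") +
    ggplot2::theme_minimal()
}
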