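#' Tidy and glance methods for fitted RSD models and reports
#'
#' Broom-style accessors: `tidy()` returns the model's reference statistics
#' (or the per-method summary for an evaluation report) as a tibble;
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted model (`rsd_naive`, `rsd_step_inferred`,
#'   `rsd_seqmatch`, `rsd_temporal`) or an `rsd_eval` report.
#' @param ... Unused.
#' @return A tibble.
#' @name rsd-tidiers
NULL

#' @rdname rsd-tidiers
#' @export
tidy.rsd_naive <- function(x, ...) {
  tibble::tibble(term = "t_ref_min", estimate = x$t_ref_min)
}

#' @rdname rsd-tidiers
#' @export
glance.rsd_naive <- function(x, ...) {
  tibble::tibble(t_ref_min = x$t_ref_min, n_train = x$n_train)
}

#' @rdname rsd-tidiers
#' @export
tidy.rsd_step_inferred <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$canonical_order),
    step = x$canonical_order,
    t_ref_min = unname(x$t_ref_min[as.character(x$canonical_order)])
  )
}

#' @rdname rsd-tidiers
#' @export
glance.rsd_step_inferred <- function(x, ...) {
  tibble::tibble(
    n_steps = length(x$canonical_order),
    total_ref_min = sum(x$t_ref_min),
    n_train = x$n_train
  )
}

#' @rdname rsd-tidiers
#' @export
tidy.rsd_seqmatch <- function(x, ...) {
  tibble::tibble(
    video_id = x$video_id,
    duration_min = x$duration_sec / 60,
    n_intervals = vapply(x$history, nrow, integer(1))
  )
}

#' @rdname rsd-tidiers
#' @export
glance.rsd_seqmatch <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_history = length(x$history),
    use_instruments = x$use_instruments,
    median_T_min = x$median_T_sec / 60
  )
}

#' @rdname rsd-tidiers
#' @export
tidy.rsd_temporal <- function(x, ...) x$log

#' @rdname rsd-tidiers
#' @export
glance.rsd_temporal <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    variant = cfg$variant,
    hidden_size = cfg$hidden_size,
    epochs = cfg$epochs,
    use_prior_context = cfg$use_prior_context,
    best_epoch = x$best_epoch,
    val_mae_min = x$val_mae_min
  )
}

#' @rdname rsd-tidiers
#' @export
tidy.rsd_eval <- function(x, ...) x$summary

#' @rdname rsd-tidiers
#' @export
glance.rsd_eval <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$summary, "method", "window", "mean_mae_min"),
    names_from = "window", values_from = "mean_mae_min", names_prefix = "mae_"
  )
}

#' Plot methods for timelines and evaluation reports
#'
#' `autoplot.workflow_timeline()` draws the step intervals of one surgery as
#' a horizontal segment chart; `autoplot.rsd_eval()` draws the per-method
#' MAE summary with error bars; `plot_rsd_series()` overlays predicted RSD
#' series against the ground-truth line for one video.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.workflow_timeline <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$start_sec / 60, xend = .data$end_sec / 60,
    y = factor(.data$step), yend = factor(.data$step),
    colour = factor(.data$step)
  )) +
    ggplot2::geom_segment(linewidth = 4, show.legend = FALSE) +
    ggplot2::labs(
      x = "elapsed time (min)", y = "step",
      title = sprintf("workflow '%s'", video_id(object))
    )
}

#' @rdname autoplot.workflow_timeline
#' @export
autoplot.rsd_eval <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(
    x = .data$window, y = .data$mean_mae_min, fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$mean_mae_min - .data$sd_mae_min),
        ymax = .data$mean_mae_min + .data$sd_mae_min
      ),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::labs(x = "window", y = "MAE (min)", fill = "method")
}

#' @rdname autoplot.workflow_timeline
#' @param predictions Named list of prediction tibbles.
#' @param cohort A cohort tibble.
#' @param video One video id.
#' @export
plot_rsd_series <- function(predictions, cohort, video) {
  tl <- cohort$timeline[[match(video, cohort$video_id)]]
  if (is.null(tl)) abort(sprintf("unknown video '%s'", video))
  df <- purrr::imap_dfr(predictions, function(p, nm) {
    dplyr::mutate(p[p$video_id == video, ], method = nm)
  })
  truth <- tibble::tibble(
    sec = seq_len(timeline_duration(tl)) - 1L,
    rsd = true_rsd(tl, seq_len(timeline_duration(tl)) - 1L)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sec / 60, y = .data$rsd_pred_min, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = truth,
      mapping = ggplot2::aes(x = .data$sec / 60, y = .data$rsd),
      colour = "black", linewidth = 0.8, inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "elapsed time (min)", y = "RSD (min)",
      title = sprintf("RSD predictions, video '%s' (truth in black)", video)
    )
}
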