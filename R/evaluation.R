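#' Per-video mean absolute error of RSD predictions
#'
#' MAE is computed within each video over one of three windows — the full
#' duration, the last 20 minutes or the last 10 minutes of the surgery
#' (seconds `[max(0, T - 60K), T)`; videos shorter than the window use their
#' full duration) — and is later mean-averaged across videos so that every
#' surgery weighs equally regardless of length.
#'
#' @param pred A prediction tibble with columns `video_id`, `sec`,
#'   `rsd_pred_min` covering `[0, T)` for each video (see
#'   [predict.rsd_naive()] and friends).
#' @param cohort A cohort tibble holding the ground-truth timelines.
#' @param windows Subset of `c("full", "last20", "last10")`.
#' @return A tibble with columns `video_id`, `window`, `mae_min`.
#' @export
mae_by_video <- function(pred, cohort, windows = c("full", "last20", "last10")) {
  windows <- match.arg(windows, several.ok = TRUE)
  timelines <- setNames(cohort$timeline, cohort$video_id)
  ids <- unique(pred$video_id)
  unknown <- setdiff(ids, names(timelines))
  if (length(unknown) > 0L) {
    abort(sprintf("predictions for unknown video(s): %s", paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(ids, function(id) {
    tl <- timelines[[id]]
    T_sec <- timeline_duration(tl)
    p <- pred[pred$video_id == id, ]
    if (!identical(sort(p$sec), seq_len(T_sec) - 1L)) {
      abort(sprintf("prediction series for '%s' does not cover [0, T) exactly", id))
    }
    p <- p[order(p$sec), ]
    err <- abs(p$rsd_pred_min - true_rsd(tl, p$sec))
    purrr::map_dfr(windows, function(w) {
      k <- switch(w, full = Inf, last20 = 20L, last10 = 10L)
      from <- max(0L, T_sec - ifelse(is.finite(k), 60L * k, T_sec))
      tibble::tibble(
        video_id = id, window = w,
        mae_min = mean(err[p$sec >= from])
      )
    })
  })
}

#' Cohort-level MAE summary
#'
#' Unweighted mean and sample standard deviation of per-video MAE values
#' (averaging over videos, not frames).
#'
#' @param per_video Output of [mae_by_video()] (or any tibble with columns
#'   `window` and `mae_min`).
#' @return A tibble with columns `window`, `mean_mae_min`, `sd_mae_min`, `n`.
#' @export
cohort_mae <- function(per_video) {
  if (nrow(per_video) == 0L) abort("no per-video MAE values")
  per_video |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      mean_mae_min = mean(.data$mae_min),
      sd_mae_min = if (dplyr::n() > 1) sd(.data$mae_min) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on per-video MAE values. Zero differences are
#' dropped before ranking; for fewer than 26 non-zero pairs the p-value is
#' computed from the exact null distribution of the signed-rank statistic
#' (by convolution over the observed — possibly tied — ranks, so the exact
#' distribution remains valid under ties), otherwise from the normal
#' approximation with tie correction.
#'
#' @param a,b Numeric vectors of equal length, paired by video.
#' @return A list with `p_value`, `statistic` (sum of positive ranks),
#'   `n_eff` (non-zero pairs), `method` and `degenerate` (all differences
#'   zero, in which case `p_value = 1`).
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L) {
    abort("a and b must be equal-length, non-empty paired vectors")
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p_value = 1, statistic = NA_real_, n_eff = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n < 26L) {
    # exact null: W+ = sum of a random subset of the doubled ranks / 2;
    # distribution built by convolution so tied (half-integer) ranks work
    r2 <- as.integer(round(2 * r))
    probs <- c(1)  # distribution of 2*W+ over 0..sum(r2)
    for (ri in r2) {
      shifted <- c(numeric(ri), probs)
      probs <- c(probs, numeric(ri)) + shifted
    }
    probs <- probs / 2^n
    w2 <- round(2 * w_pos)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(p_value = p, statistic = w_pos, n_eff = n, method = method,
       degenerate = FALSE)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in the ground
#' truth (classes absent from the truth are excluded to avoid 0/0; a class
#' that is never predicted gets precision 0 by convention).
#'
#' @param truth,pred Equal-length label vectors (any coercible type).
#' @param classes Optional full class set; defaults to the classes observed
#'   in `truth`.
#' @return A single number in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) abort("truth and pred must have equal length")
  if (is.null(classes)) classes <- sort(unique(truth))
  classes <- intersect(classes, unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  mean(f1)
}

#' Evaluate one or more prediction sets against a cohort
#'
#' Builds the full evaluation report: per-video MAE for the three windows,
#' cohort-level mean +/- sd per method, optional step macro-F1, and paired
#' Wilcoxon signed-rank comparisons between every pair of methods within
#' each window.
#'
#' @param predictions A named list of prediction tibbles (one per method).
#' @param cohort A cohort tibble.
#' @param windows MAE windows to report.
#' @return An `rsd_eval` object with tibbles `per_video`, `summary`,
#'   `macro_f1` and `comparisons`.
#' @export
evaluate_rsd <- function(predictions, cohort,
                         windows = c("full", "last20", "last10")) {
  stopifnot(is.list(predictions), length(predictions) > 0L,
            !is.null(names(predictions)))
  per_video <- purrr::imap_dfr(predictions, function(p, nm) {
    dplyr::mutate(mae_by_video(p, cohort, windows), method = nm, .before = 1)
  })
  summary <- per_video |>
    dplyr::group_by(.data$method, .data$window) |>
    dplyr::summarise(
      mean_mae_min = mean(.data$mae_min),
      sd_mae_min = if (dplyr::n() > 1) sd(.data$mae_min) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
  f1 <- purrr::imap_dfr(predictions, function(p, nm) {
    if (!"step_pred" %in% names(p)) return(tibble::tibble())
    timelines <- setNames(cohort$timeline, cohort$video_id)
    truth <- unlist(lapply(unique(p$video_id), function(id) {
      step_at(timelines[[id]], p$sec[p$video_id == id])
    }))
    tibble::tibble(method = nm, macro_f1 = macro_f1(truth, p$step_pred))
  })
  methods <- names(predictions)
  comparisons <- tibble::tibble()
  if (length(methods) > 1L) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      purrr::map_dfr(windows, function(w) {
        wide <- per_video |>
          dplyr::filter(.data$window == w, .data$method %in% pr) |>
          tidyr::pivot_wider(names_from = "method", values_from = "mae_min")
        wt <- wilcoxon_paired(wide[[pr[1]]], wide[[pr[2]]])
        tibble::tibble(
          method_a = pr[1], method_b = pr[2], window = w,
          wilcoxon_p = wt$p_value, n_eff = wt$n_eff, method = wt$method
        )
      })
    })
  }
  structure(
    list(per_video = per_video, summary = summary,
         macro_f1 = f1, comparisons = comparisons),
    class = "rsd_eval"
  )
}

#' @export
print.rsd_eval <- function(x, ...) {
  cat("<rsd_eval>\n")
  print(tidyr::pivot_wider(
    x$summary |>
      dplyr::mutate(mae = sprintf("%.2f +/- %.2f", .data$mean_mae_min, .data$sd_mae_min)) |>
      dplyr::select("method", "window", "mae"),
    names_from = "window", values_from = "mae"
  ))
  if (nrow(x$macro_f1) > 0L) {
    cat("step macro-F1:\n")
    print(x$macro_f1)
  }
  invisible(x)
}
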