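#' Levenshtein distance between label sequences
#'
#' Minimum number of single-symbol insertions, deletions and substitutions
#' transforming `a` into `b`, computed by dynamic programming. This is the
#' similarity primitive of the sequence-matching RSD estimator, applied to
#' run-length-compressed elapsed step (or instrument) sequences.
#'
#' @param a,b Integer (or coercible) label vectors.
#' @return A non-negative integer.
#' @examples
#' levenshtein(c(1, 1, 2), c(1, 2, 2))
#' levenshtein(utf8ToInt("kitten"), utf8ToInt("sitting"))  # 3
#' @export
levenshtein <- function(a, b) {
  lev_dist_cpp(as.integer(a), as.integer(b))
}

new_rsd_model <- function(x, class) {
  structure(x, class = c(class, "rsd_model"))
}

#' Naive mean-duration RSD estimator
#'
#' Uses the mean full duration of the training split as the reference
#' duration `T_ref` and predicts `max(0, T_ref - t_el)`.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param split Which split(s) to fit on.
#' @return An object of class `rsd_naive`.
#' @export
fit_rsd_naive <- function(cohort, split = "train") {
  train <- cohort_split(cohort, split)
  if (nrow(train) == 0L) abort("cannot fit on an empty training split")
  dur_sec <- vapply(train$timeline, timeline_duration, numeric(1))
  new_rsd_model(
    list(t_ref_min = mean(dur_sec) / 60, n_train = nrow(train)),
    "rsd_naive"
  )
}

#' @rdname fit_rsd_naive
#' @param model A fitted `rsd_naive`.
#' @param tel_min Elapsed time in minutes (vectorized).
#' @export
predict_naive_rsd <- function(model, tel_min) {
  stopifnot(inherits(model, "rsd_naive"), all(tel_min >= 0))
  pmax(0, model$t_ref_min - tel_min)
}

#' Step-inferred RSD estimator
#'
#' Assumes a canonical sequential workflow: each step has a reference
#' duration (mean total time spent in the step across training surgeries
#' containing it) and steps are ordered by their mean normalized
#' first-occurrence time. The prediction at elapsed time `t` is
#' `max(0, t_ref[current] - t_el_step) + sum(t_ref[later steps])`, where
#' `t_el_step` is the time already spent in the current step's label. The
#' sequential assumption is knowingly violated by pituitary workflows
#' (optional and repeatable steps), which is the documented weakness of
#' this baseline.
#'
#' @inheritParams fit_rsd_naive
#' @return An object of class `rsd_step_inferred` with fields
#'   `canonical_order` and `t_ref_min` (named by step code).
#' @export
fit_rsd_step_inferred <- function(cohort, split = "train") {
  train <- cohort_split(cohort, split)
  if (nrow(train) == 0L) abort("cannot fit on an empty training split")
  per_video <- purrr::map_dfr(train$timeline, function(tl) {
    T_sec <- timeline_duration(tl)
    tibble::as_tibble(tl) |>
      dplyr::group_by(step = .data$step) |>
      dplyr::summarise(
        total_min = sum(.data$end_sec - .data$start_sec) / 60,
        first_frac = min(.data$start_sec) / T_sec,
        .groups = "drop"
      )
  })
  ref <- per_video |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(
      t_ref_min = mean(.data$total_min),
      mean_first = mean(.data$first_frac),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_first, .data$step)
  new_rsd_model(
    list(
      canonical_order = ref$step,
      t_ref_min = setNames(ref$t_ref_min, ref$step),
      n_train = nrow(train)
    ),
    "rsd_step_inferred"
  )
}

#' @rdname fit_rsd_step_inferred
#' @param model A fitted `rsd_step_inferred`.
#' @param current_step Step label active now.
#' @param tel_step_min Minutes already spent in the current step's label.
#' @export
predict_step_rsd <- function(model, current_step, tel_step_min) {
  stopifnot(inherits(model, "rsd_step_inferred"), tel_step_min >= 0)
  ord <- model$canonical_order
  pos <- match(current_step, ord)
  if (is.na(pos)) {
    abort(sprintf("step %s is not in the canonical order", current_step))
  }
  later <- if (pos < length(ord)) sum(model$t_ref_min[as.character(ord[(pos + 1):length(ord)])]) else 0
  max(0, model$t_ref_min[[as.character(current_step)]] - tel_step_min) + later
}

#' Sequence-matching k-nearest-neighbour RSD estimator
#'
#' The proposed estimator: at elapsed time `t`, the query's run-length
#' compressed elapsed step sequence is compared by Levenshtein distance with
#' each training surgery's compressed step sequence truncated at the same
#' timestamp (surgeries already finished contribute their full sequence).
#' The reference duration is the mean full duration of the `k` nearest
#' neighbours and the prediction is `max(0, T_ref - t_el)`. With instrument
#' annotations enabled, the distance is the unweighted sum of the step and
#' instrument sequence distances.
#'
#' Distance ties are broken deterministically by
#' `(distance, |T_i - median training duration|, training index)`.
#'
#' @inheritParams fit_rsd_naive
#' @param k Number of neighbours (the pituitary default is 3).
#' @param use_instruments Add the instrument-sequence distance (requires
#'   instrument annotations on both the history and the query).
#' @return An object of class `rsd_seqmatch`.
#' @export
fit_rsd_seqmatch <- function(cohort, k = 3L, split = "train",
                             use_instruments = FALSE) {
  train <- cohort_split(cohort, split)
  if (nrow(train) == 0L) abort("cannot fit on an empty training split")
  if (k < 1L || k > nrow(train)) {
    abort(sprintf("k must be in [1, %d] (got %s)", nrow(train), k))
  }
  if (use_instruments &&
      any(vapply(train$timeline, function(tl) is.null(instrument_intervals(tl)), logical(1)))) {
    abort("use_instruments = TRUE requires instrument annotations on every training timeline")
  }
  dur_sec <- vapply(train$timeline, timeline_duration, numeric(1))
  new_rsd_model(
    list(
      history = train$timeline,
      video_id = train$video_id,
      duration_sec = dur_sec,
      median_T_sec = median(dur_sec),
      k = as.integer(k),
      use_instruments = use_instruments
    ),
    "rsd_seqmatch"
  )
}

# compressed prefix sequences of a timeline's interval labels:
# prefixes[[j]] = compressed labels of the first j intervals
compressed_prefixes <- function(intervals) {
  labels <- intervals$step
  comp <- integer(0)
  out <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    if (length(comp) == 0L || comp[length(comp)] != labels[j]) {
      comp <- c(comp, labels[j])
    }
    out[[j]] <- comp
  }
  out
}

# neighbour selection at one cutoff: returns the mean full duration (sec) of
# the k nearest histories under the deterministic tie-break
seqmatch_t_ref_sec <- function(dist, model) {
  ord <- order(dist, abs(model$duration_sec - model$median_T_sec), seq_along(dist))
  chosen <- sort(ord[seq_len(model$k)])
  mean(model$duration_sec[chosen])
}

#' Per-second RSD predictions for a cohort
#'
#' Generates a 1 Hz RSD prediction series for every surgery in the chosen
#' split. The prediction at second `t` uses the step labels observed in
#' frames `0..t` and elapsed time `t` seconds; ground truth at second `t` is
#' `(T - t)/60` minutes.
#'
#' @param object A fitted `rsd_naive`, `rsd_step_inferred` or `rsd_seqmatch`.
#' @param cohort A cohort tibble.
#' @param split Which split to predict on.
#' @param ... Unused.
#' @return A tibble with columns `video_id`, `sec`, `rsd_pred_min`.
#' @name predict-statistical
NULL

#' @rdname predict-statistical
#' @export
predict.rsd_naive <- function(object, cohort, split = "test", ...) {
  videos <- cohort_split(cohort, split)
  purrr::map_dfr(seq_len(nrow(videos)), function(i) {
    T_sec <- timeline_duration(videos$timeline[[i]])
    secs <- seq_len(T_sec) - 1L
    tibble::tibble(
      video_id = videos$video_id[i],
      sec = secs,
      rsd_pred_min = pmax(0, object$t_ref_min - secs / 60)
    )
  })
}

#' @rdname predict-statistical
#' @export
predict.rsd_step_inferred <- function(object, cohort, split = "test", ...) {
  ord <- object$canonical_order
  t_ref <- object$t_ref_min
  remaining_after <- rev(cumsum(rev(c(t_ref[as.character(ord)][-1], 0))))
  videos <- cohort_split(cohort, split)
  purrr::map_dfr(seq_len(nrow(videos)), function(i) {
    tl <- videos$timeline[[i]]
    T_sec <- timeline_duration(tl)
    secs <- seq_len(T_sec) - 1L
    labels <- step_at(tl, secs)
    # minutes already spent in the current label, before the current second
    tel_step_min <- (stats::ave(rep(1, T_sec), labels, FUN = cumsum) - 1) / 60
    pos <- match(labels, ord)
    # graceful fallback for steps unseen in training: carry the last known
    # canonical position and predict the remaining-steps sum after it
    known_pos <- pos
    last <- 0L
    for (j in seq_len(T_sec)) {
      if (is.na(known_pos[j])) known_pos[j] <- last else last <- known_pos[j]
    }
    pred <- ifelse(
      is.na(pos),
      ifelse(known_pos == 0L, sum(t_ref), remaining_after[pmax(known_pos, 1L)]),
      pmax(0, t_ref[as.character(labels)] - tel_step_min) +
        remaining_after[pmax(pos, 1L)]
    )
    tibble::tibble(
      video_id = videos$video_id[i],
      sec = secs,
      rsd_pred_min = unname(pred)
    )
  })
}

#' @rdname predict-statistical
#' @export
predict.rsd_seqmatch <- function(object, cohort, split = "test", ...) {
  videos <- cohort_split(cohort, split)
  hist_step_prefixes <- lapply(object$history, compressed_prefixes)
  hist_instr_prefixes <- if (object$use_instruments) {
    lapply(object$history, function(tl) compressed_prefixes(instrument_intervals(tl)))
  }
  hist_starts <- lapply(object$history, function(tl) tl$start_sec)
  hist_instr_starts <- if (object$use_instruments) {
    lapply(object$history, function(tl) instrument_intervals(tl)$start_sec)
  }
  purrr::map_dfr(seq_len(nrow(videos)), function(i) {
    tl <- videos$timeline[[i]]
    if (object$use_instruments && is.null(instrument_intervals(tl))) {
      abort(sprintf("query '%s' has no instrument annotations", videos$video_id[i]))
    }
    T_sec <- timeline_duration(tl)
    q_step_prefixes <- compressed_prefixes(tl)
    q_instr_prefixes <- if (object$use_instruments) {
      compressed_prefixes(instrument_intervals(tl))
    }
    q_starts <- tl$start_sec
    q_instr_starts <- if (object$use_instruments) instrument_intervals(tl)$start_sec

    # distances only change when a new interval starts in the query or in a
    # still-running history; evaluate T_ref on that event grid only
    events <- sort(unique(c(
      0L, q_starts, if (object$use_instruments) q_instr_starts,
      unlist(hist_starts, use.names = FALSE),
      if (object$use_instruments) unlist(hist_instr_starts, use.names = FALSE)
    )))
    events <- events[events >= 0L & events < T_sec]
    t_ref_sec <- vapply(events, function(t) {
      cutoff <- t + 1L  # frames 0..t observed
      q_seq <- q_step_prefixes[[sum(q_starts < cutoff)]]
      h_seqs <- lapply(seq_along(object$history), function(h) {
        cut_h <- min(cutoff, object$duration_sec[h])
        hist_step_prefixes[[h]][[sum(hist_starts[[h]] < cut_h)]]
      })
      d <- as.numeric(lev_dist_many_cpp(q_seq, h_seqs))
      if (object$use_instruments) {
        qi_seq <- q_instr_prefixes[[sum(q_instr_starts < cutoff)]]
        hi_seqs <- lapply(seq_along(object$history), function(h) {
          cut_h <- min(cutoff, object$duration_sec[h])
          hist_instr_prefixes[[h]][[sum(hist_instr_starts[[h]] < cut_h)]]
        })
        d <- d + as.numeric(lev_dist_many_cpp(qi_seq, hi_seqs))
      }
      seqmatch_t_ref_sec(d, object)
    }, numeric(1))
    secs <- seq_len(T_sec) - 1L
    seg <- findInterval(secs, events)
    tibble::tibble(
      video_id = videos$video_id[i],
      sec = secs,
      rsd_pred_min = pmax(0, t_ref_sec[seg] / 60 - secs / 60)
    )
  })
}

#' @export
print.rsd_model <- function(x, ...) {
  cls <- setdiff(class(x), "rsd_model")[1]
  cat(sprintf("<%s>\n", cls))
  switch(cls,
    rsd_naive = cat(sprintf(
      "  T_ref = %.2f min (mean of %d training surgeries)\n",
      x$t_ref_min, x$n_train
    )),
    rsd_step_inferred = cat(sprintf(
      "  %d canonical steps, total reference duration %.2f min\n",
      length(x$canonical_order), sum(x$t_ref_min)
    )),
    rsd_seqmatch = cat(sprintf(
      "  k = %d over %d historical surgeries%s\n",
      x$k, length(x$history),
      if (x$use_instruments) " (step + instrument distance)" else ""
    ))
  )
  invisible(x)
}
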