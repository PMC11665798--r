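#' Construct a workflow timeline
#'
#' A workflow timeline is the canonical in-memory form of one surgery's
#' per-second step annotations: a tibble of step intervals (columns `step`,
#' `start_sec`, `end_sec`) that are contiguous, non-overlapping and cover
#' `[0, T)` exactly, at a 1 Hz time base with half-open `[start, end)`
#' intervals. Total duration, video id and any instrument annotation stream
#' are carried as attributes.
#'
#' @param intervals A data frame with integer columns `step`, `start_sec`,
#'   `end_sec`. Adjacent intervals with the same step label are allowed and
#'   kept as given (use [as_timeline()] to build from per-second labels with
#'   run merging).
#' @param video_id Character scalar identifying the surgery.
#' @param instruments Optional data frame with the same shape over an
#'   instrument vocabulary (columns `step`, `start_sec`, `end_sec`, where
#'   `step` holds instrument codes).
#' @return A `workflow_timeline`: a tibble of intervals with attributes
#'   `video_id`, `duration_sec` and `instruments`.
#' @examples
#' tl <- workflow_timeline(
#'   data.frame(step = c(1L, 2L), start_sec = c(0L, 100L), end_sec = c(100L, 250L)),
#'   video_id = "demo"
#' )
#' timeline_duration(tl)
#' @export
workflow_timeline <- function(intervals, video_id = "video", instruments = NULL) {
  iv <- tibble::as_tibble(intervals)
  if (!all(c("step", "start_sec", "end_sec") %in% names(iv))) {
    abort("intervals must have columns step, start_sec, end_sec")
  }
  iv$step <- as.integer(iv$step)
  iv$start_sec <- as.integer(iv$start_sec)
  iv$end_sec <- as.integer(iv$end_sec)
  if (nrow(iv) == 0L) abort("a timeline needs at least one interval")
  if (any(iv$end_sec <= iv$start_sec)) {
    abort("every interval must satisfy end_sec > start_sec")
  }
  if (iv$start_sec[1] != 0L) abort("intervals must start at second 0")
  if (nrow(iv) > 1L && any(iv$start_sec[-1] != iv$end_sec[-nrow(iv)])) {
    bad <- which(iv$start_sec[-1] != iv$end_sec[-nrow(iv)])[1]
    abort(sprintf(
      "intervals must be contiguous: gap or overlap at second %d",
      iv$end_sec[bad]
    ))
  }
  if (!is.null(instruments)) {
    instruments <- tibble::as_tibble(instruments)
    instruments$step <- as.integer(instruments$step)
    instruments$start_sec <- as.integer(instruments$start_sec)
    instruments$end_sec <- as.integer(instruments$end_sec)
  }
  structure(
    iv,
    video_id = as.character(video_id),
    duration_sec = iv$end_sec[nrow(iv)],
    instruments = instruments,
    class = c("workflow_timeline", class(tibble::tibble()))
  )
}

#' @rdname workflow_timeline
#' @param x A `workflow_timeline`.
#' @export
timeline_duration <- function(x) {
  stopifnot(inherits(x, "workflow_timeline"))
  attr(x, "duration_sec")
}

#' @rdname workflow_timeline
#' @export
video_id <- function(x) attr(x, "video_id")

#' @rdname workflow_timeline
#' @export
instrument_intervals <- function(x) attr(x, "instruments")

#' @export
print.workflow_timeline <- function(x, ...) {
  cat(sprintf(
    "<workflow_timeline '%s': %d intervals, T = %d s (%.1f min)%s>\n",
    video_id(x), nrow(x), timeline_duration(x), timeline_duration(x) / 60,
    if (is.null(instrument_intervals(x))) "" else ", with instruments"
  ))
  NextMethod()
}

#' Build a timeline from per-second labels
#'
#' Collapses a per-second annotation stream (one row per second, 0-based,
#' contiguous) into run-length intervals. Rows must cover `0..n-1` with no
#' gap, overlap or disorder.
#'
#' @param data A data frame with columns `sec` and `step` (and optionally
#'   `instrument`).
#' @param video_id Character scalar.
#' @param vocabulary Optional step vocabulary tibble; labels outside
#'   `vocabulary$code` raise an error.
#' @param merge_label Optional step code (e.g. an "out of patient" marker)
#'   whose runs are reassigned to the preceding step before interval
#'   construction; a leading run takes the following step's label.
#' @return A [workflow_timeline()].
#' @export
as_timeline <- function(data, video_id = "video", vocabulary = NULL,
                        merge_label = NULL) {
  df <- tibble::as_tibble(data)
  if (nrow(df) == 0L) abort("empty annotation: no per-second rows")
  if (!all(c("sec", "step") %in% names(df))) {
    abort("per-second annotations need columns 'sec' and 'step'")
  }
  sec <- as.integer(df$sec)
  step <- as.integer(df$step)
  expected <- seq_len(length(sec)) - 1L
  if (!identical(sec, expected)) {
    bad <- which(sec != expected)[1]
    abort(sprintf(
      "malformed annotation: expected second %d but found %d (gap, overlap or disorder)",
      expected[bad], sec[bad]
    ))
  }
  if (!is.null(merge_label)) {
    step <- merge_into_previous(step, as.integer(merge_label))
  }
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(step), vocabulary$code)
    if (length(unknown) > 0L) {
      abort(sprintf(
        "unknown step label(s) not in vocabulary: %s",
        paste(sort(unknown), collapse = ", ")
      ))
    }
  }
  iv <- runs_to_intervals(step)
  instruments <- NULL
  if ("instrument" %in% names(df)) {
    instruments <- runs_to_intervals(as.integer(df$instrument))
  }
  workflow_timeline(iv, video_id = video_id, instruments = instruments)
}

runs_to_intervals <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  tibble::tibble(
    step = r$values,
    start_sec = as.integer(c(0L, end[-length(end)])),
    end_sec = as.integer(end)
  )
}

merge_into_previous <- function(step, label) {
  if (all(step == label)) {
    abort("cannot merge label into previous step: annotation contains only that label")
  }
  keep <- step != label
  # leading run of `label` takes the first real step's label
  first_real <- step[which(keep)[1]]
  out <- step
  out[1] <- ifelse(keep[1], step[1], first_real)
  for (i in seq_along(out)[-1]) {
    if (!keep[i]) out[i] <- out[i - 1]
  }
  out
}

#' Read and write per-second annotation CSV files
#'
#' The file format is a CSV with header `sec,step` (optionally
#' `sec,step,instrument`), one row per second, 0-based contiguous seconds.
#' `read_timeline()` merges adjacent identical labels into intervals and
#' validates contiguity and vocabulary membership; `write_timeline()` expands
#' a timeline back to per-second rows so that read-after-write is the
#' identity.
#'
#' @param path CSV file path.
#' @param vocabulary Optional step vocabulary tibble (see [pituitary_steps()]).
#' @param merge_label Optional label to merge into the preceding step, see
#'   [as_timeline()].
#' @param video_id Video id; defaults to the file name without extension.
#' @return `read_timeline()` returns a [workflow_timeline()];
#'   `write_timeline()` returns `path` invisibly.
#' @export
read_timeline <- function(path, vocabulary = NULL, merge_label = NULL,
                          video_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such annotation file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) abort(sprintf("empty annotation file: %s", path))
  as_timeline(
    df,
    video_id = video_id %||% sub("\\.[^.]*$", "", basename(path)),
    vocabulary = vocabulary,
    merge_label = merge_label
  )
}

#' @rdname read_timeline
#' @param timeline A [workflow_timeline()].
#' @export
write_timeline <- function(timeline, path) {
  df <- data.frame(
    sec = seq_len(timeline_duration(timeline)) - 1L,
    step = step_at(timeline, seq_len(timeline_duration(timeline)) - 1L)
  )
  instr <- instrument_intervals(timeline)
  if (!is.null(instr)) {
    df$instrument <- labels_at(instr, df$sec)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

labels_at <- function(intervals, t_sec) {
  idx <- findInterval(t_sec, intervals$start_sec)
  intervals$step[idx]
}

#' Per-second queries on a timeline
#'
#' `step_at()` returns the step label of the interval containing each second
#' `t`; `true_rsd()` the ground-truth remaining surgery duration
#' `(T - t) / 60` in minutes; `progress_at()` the progress fraction `t / T`.
#'
#' @param timeline A [workflow_timeline()].
#' @param t_sec Integer second(s); `step_at` requires `0 <= t < T`, the other
#'   two allow `0 <= t <= T`.
#' @return Numeric/integer vector the length of `t_sec`.
#' @examples
#' tl <- workflow_timeline(data.frame(step = 1L, start_sec = 0L, end_sec = 3600L))
#' true_rsd(tl, 900)  # 45 minutes
#' @export
true_rsd <- function(timeline, t_sec) {
  T_sec <- timeline_duration(timeline)
  if (any(t_sec < 0 | t_sec > T_sec)) {
    abort(sprintf("t_sec must lie in [0, %d]", T_sec))
  }
  (T_sec - t_sec) / 60
}

#' @rdname true_rsd
#' @export
progress_at <- function(timeline, t_sec) {
  T_sec <- timeline_duration(timeline)
  if (any(t_sec < 0 | t_sec > T_sec)) {
    abort(sprintf("t_sec must lie in [0, %d]", T_sec))
  }
  t_sec / T_sec
}

#' @rdname true_rsd
#' @export
step_at <- function(timeline, t_sec) {
  T_sec <- timeline_duration(timeline)
  if (any(t_sec < 0 | t_sec >= T_sec)) {
    abort(sprintf("t_sec must lie in [0, %d)", T_sec))
  }
  labels_at(timeline, t_sec)
}

#' Elapsed step sequence and run-length compression
#'
#' `elapsed_steps()` returns the ordered labels of all intervals that have
#' started by second `t_sec` (`start_sec <= t_sec`, so the half-open
#' interval containing `t_sec` is included, truncated); repeated
#' non-adjacent occurrences are preserved.
#' `compress_steps()` collapses maximal runs of identical labels to a single
#' occurrence (the sequence-compression step of the sequence-matching
#' estimator); it is idempotent.
#'
#' @param timeline A [workflow_timeline()].
#' @param t_sec A single second in `(0, T]`.
#' @param stream `"step"` or `"instrument"`.
#' @return An integer label vector.
#' @export
elapsed_steps <- function(timeline, t_sec, stream = c("step", "instrument")) {
  stream <- match.arg(stream)
  if (length(t_sec) != 1L || t_sec <= 0) abort("t_sec must be a single second > 0")
  iv <- if (stream == "step") timeline else instrument_intervals(timeline)
  if (is.null(iv)) abort("timeline has no instrument annotations")
  iv$step[iv$start_sec <= t_sec]
}

#' @rdname elapsed_steps
#' @param x An integer label vector.
#' @export
compress_steps <- function(x) {
  if (length(x) == 0L) return(integer(0))
  rle(as.integer(x))$values
}
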