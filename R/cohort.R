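#' Cohorts of surgical workflows
#'
#' A cohort is a tibble with one row per surgery: columns `video_id`,
#' `split` (`"train"`, `"val"` or `"test"`), `timeline` (list of
#' [workflow_timeline()]) and `duration_min`. Frame-feature tracks, when
#' present, live in a `track` list-column (see [sample_frame_embeddings()]).
#'
#' @param timelines A list of [workflow_timeline()] objects.
#' @param split Character vector of split assignments, recycled if scalar.
#' @return A cohort tibble.
#' @export
as_cohort <- function(timelines, split = "train") {
  stopifnot(length(timelines) > 0L)
  ids <- vapply(timelines, video_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate video_id in cohort")
  tibble::tibble(
    video_id = ids,
    split = rep_len(as.character(split), length(timelines)),
    timeline = unname(timelines),
    duration_min = vapply(timelines, timeline_duration, numeric(1)) / 60
  )
}

#' @rdname as_cohort
#' @param cohort A cohort tibble.
#' @param which One or more split names.
#' @export
cohort_split <- function(cohort, which) {
  dplyr::filter(cohort, .data$split %in% which)
}

#' @rdname as_cohort
#' @export
cohort_timelines <- function(cohort, which = NULL) {
  if (!is.null(which)) cohort <- cohort_split(cohort, which)
  setNames(cohort$timeline, cohort$video_id)
}

#' Write or read a cohort directory
#'
#' The on-disk layout mirrors the package's external interface: one
#' per-second annotation CSV per surgery under `annotations/`, a JSON split
#' manifest `split.json` (`{"train": [...], "val": [...], "test": [...]}`),
#' the step vocabulary as `vocabulary.json`, optional per-video feature
#' matrices under `features/` (CSV, one row per second, columns `f1..fD`),
#' and a `stats.json` cohort-duration summary (median, IQR, mean, sd of
#' total duration in minutes).
#'
#' @param cohort A cohort tibble.
#' @param dir Directory path (created if needed).
#' @param vocabulary Step vocabulary to store alongside the annotations.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort tibble.
#' @export
write_cohort <- function(cohort, dir, vocabulary = pituitary_steps()) {
  ann_dir <- file.path(dir, "annotations")
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    write_timeline(
      cohort$timeline[[i]],
      file.path(ann_dir, paste0(cohort$video_id[i], ".csv"))
    )
  }
  split_list <- lapply(
    c(train = "train", val = "val", test = "test"),
    function(s) cohort$video_id[cohort$split == s]
  )
  jsonlite::write_json(split_list, file.path(dir, "split.json"))
  write_vocabulary(vocabulary, file.path(dir, "vocabulary.json"))
  if ("track" %in% names(cohort)) {
    ft_dir <- file.path(dir, "features")
    dir.create(ft_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      tr <- cohort$track[[i]]
      if (is.null(tr)) next
      m <- as.data.frame(tr$features)
      names(m) <- paste0("f", seq_len(ncol(m)))
      readr::write_csv(m, file.path(ft_dir, paste0(cohort$video_id[i], ".csv")),
                       progress = FALSE)
    }
  }
  dur <- cohort$duration_min
  stats <- list(
    n = nrow(cohort),
    median_min = median(dur),
    q1_min = unname(quantile(dur, 0.25)),
    q3_min = unname(quantile(dur, 0.75)),
    mean_min = mean(dur),
    sd_min = if (nrow(cohort) > 1) sd(dur) else 0
  )
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param with_features Read feature matrices from `features/` when present.
#' @param merge_label Passed to [read_timeline()].
#' @export
read_cohort <- function(dir, with_features = TRUE, merge_label = NULL) {
  split_path <- file.path(dir, "split.json")
  if (!file.exists(split_path)) abort(sprintf("no split manifest at %s", split_path))
  split_list <- jsonlite::fromJSON(split_path, simplifyVector = TRUE)
  vocab_path <- file.path(dir, "vocabulary.json")
  vocabulary <- if (file.exists(vocab_path)) read_vocabulary(vocab_path) else NULL
  ids <- unlist(split_list, use.names = FALSE)
  splits <- rep(names(split_list), vapply(split_list, length, integer(1)))
  timelines <- lapply(seq_along(ids), function(i) {
    read_timeline(
      file.path(dir, "annotations", paste0(ids[i], ".csv")),
      vocabulary = vocabulary, merge_label = merge_label, video_id = ids[i]
    )
  })
  cohort <- as_cohort(timelines, split = splits)
  ft_dir <- file.path(dir, "features")
  if (with_features && dir.exists(ft_dir)) {
    cohort$track <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- file.path(ft_dir, paste0(cohort$video_id[i], ".csv"))
      if (!file.exists(p)) return(NULL)
      m <- as.matrix(readr::read_csv(p, show_col_types = FALSE, progress = FALSE))
      dimnames(m) <- NULL
      frame_track(m, video_id = cohort$video_id[i])
    })
  }
  cohort
}

#' Frame-feature tracks
#'
#' A frame-feature track carries one encoder feature vector per second of a
#' surgery (a pluggable stand-in for any frozen per-frame image encoder),
#' plus the elapsed second of each frame.
#'
#' @param features Numeric matrix, one row per second, `D` columns.
#' @param video_id Character scalar.
#' @return A `frame_track` object (list with `video_id`, `features`,
#'   `elapsed_sec`).
#' @export
frame_track <- function(features, video_id = "video") {
  features <- as.matrix(features)
  structure(
    list(
      video_id = as.character(video_id),
      features = features,
      elapsed_sec = seq_len(nrow(features)) - 1L
    ),
    class = "frame_track"
  )
}

#' @export
print.frame_track <- function(x, ...) {
  cat(sprintf(
    "<frame_track '%s': %d s x %d dims>\n",
    x$video_id, nrow(x$features), ncol(x$features)
  ))
  invisible(x)
}
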