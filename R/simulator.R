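#' Simulator configuration for synthetic surgical workflows
#'
#' The simulator emulates the structure of endoscopic pituitary surgery
#' workflows: 8 core steps that always occur, 6 optional steps included at
#' random, a repeatable haemostasis-like step that can be inserted after any
#' step, mild order variability via adjacent-core transpositions, per-step
#' log-normal durations, and a 2-component duration-scale mixture that
#' creates short/long surgery archetypes with a long-tailed total-duration
#' distribution. One optional step (the "marker", by default
#' turbinate lateralisation, placed early in the canonical order) can be
#' linked to the archetype so that sequence-aware predictors have an early
#' observable signal of a long surgery.
#'
#' Default per-step mean durations are calibrated so that total duration has
#' median close to 64 min with inter-quartile range close to 53--84 min.
#'
#' @param vocabulary Step vocabulary tibble (default [pituitary_steps()]).
#' @param optional_inclusion_prob Probability that each non-marker optional
#'   step is included.
#' @param order_swap_prob Probability of transposing each adjacent pair of
#'   core steps in the canonical order.
#' @param repeat_step_code Label of the repeatable step (haemostasis).
#' @param repeat_prob_per_step Probability that an extra instance of the
#'   repeatable step is inserted after each step (one instance after tumour
#'   excision is always present, making the step core).
#' @param mean_sec Named numeric vector of per-step mean durations (seconds),
#'   names are step codes.
#' @param sdlog Log-scale standard deviation of the per-step log-normal
#'   durations.
#' @param duration_scale Global multiplier applied to all mean durations.
#' @param archetype_multipliers,archetype_weights The duration-scale mixture:
#'   each surgery draws one multiplier with the given weights.
#' @param marker_step Optional step code linked to the archetype; `NA`
#'   disables the linkage (the marker is then treated as an ordinary
#'   optional step).
#' @param marker_prob_long,marker_prob_short Inclusion probability of the
#'   marker step given the long (largest-multiplier) or short archetype.
#' @param simulate_instruments Also emit per-second instrument annotations.
#' @param instrument_vocabulary Instrument vocabulary tibble.
#' @param instrument_dwell_sec Mean dwell time of one instrument segment.
#' @param seed Default seed used by [sample_cohort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(vocabulary = pituitary_steps(),
                       optional_inclusion_prob = 0.5,
                       order_swap_prob = 0.1,
                       repeat_step_code = 8L,
                       repeat_prob_per_step = 0.12,
                       mean_sec = NULL,
                       sdlog = 0.55,
                       duration_scale = 0.90,
                       archetype_multipliers = c(1.0, 1.6),
                       archetype_weights = c(0.75, 0.25),
                       marker_step = 9L,
                       marker_prob_long = 0.9,
                       marker_prob_short = 0.15,
                       simulate_instruments = FALSE,
                       instrument_vocabulary = pituitary_instruments(),
                       instrument_dwell_sec = 60,
                       seed = 1L) {
  if (is.null(mean_sec)) {
    mean_sec <- c(
      "1" = 480, "2" = 420, "3" = 300, "4" = 330, "5" = 420, "6" = 180,
      "7" = 900, "8" = 200, "9" = 280, "10" = 220, "11" = 220, "12" = 180,
      "13" = 240, "14" = 200
    )
  }
  stopifnot(
    all(optional_inclusion_prob >= 0 & optional_inclusion_prob <= 1),
    order_swap_prob >= 0, order_swap_prob <= 1,
    repeat_prob_per_step >= 0, repeat_prob_per_step <= 1,
    sdlog >= 0, duration_scale > 0,
    length(archetype_multipliers) == length(archetype_weights),
    all(archetype_weights >= 0), sum(archetype_weights) > 0
  )
  missing_steps <- setdiff(as.character(vocabulary$code), names(mean_sec))
  if (length(missing_steps) > 0L) {
    abort(sprintf("mean_sec missing step(s): %s", paste(missing_steps, collapse = ", ")))
  }
  structure(
    list(
      vocabulary = vocabulary,
      optional_inclusion_prob = optional_inclusion_prob,
      order_swap_prob = order_swap_prob,
      repeat_step_code = as.integer(repeat_step_code),
      repeat_prob_per_step = repeat_prob_per_step,
      mean_sec = mean_sec,
      sdlog = sdlog,
      duration_scale = duration_scale,
      archetype_multipliers = archetype_multipliers,
      archetype_weights = archetype_weights / sum(archetype_weights),
      marker_step = if (is.na(marker_step)) NA_integer_ else as.integer(marker_step),
      marker_prob_long = marker_prob_long,
      marker_prob_short = marker_prob_short,
      simulate_instruments = simulate_instruments,
      instrument_vocabulary = instrument_vocabulary,
      instrument_dwell_sec = instrument_dwell_sec,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# canonical step order: core steps in surgical order with the marker-style
# optional early (after corridor creation) and closure optionals at the end;
# the repeatable step is inserted separately.
canonical_step_order <- function(config) {
  vocab <- config$vocabulary
  core <- setdiff(vocab$code[vocab$core], config$repeat_step_code)
  optional <- vocab$code[!vocab$core]
  early_opt <- if (is.na(config$marker_step %||% NA_integer_)) {
    integer(0)
  } else {
    optional[optional == config$marker_step]
  }
  late_opt <- setdiff(optional, early_opt)
  if (length(core) >= 1L) {
    c(core[1], early_opt, core[-1], late_opt)
  } else {
    c(early_opt, late_opt)
  }
}

#' Sample one synthetic surgical workflow
#'
#' Draws a step sequence (core steps always present, optional steps by
#' inclusion probability, adjacent-core transpositions, repeatable-step
#' insertions) and per-interval log-normal durations scaled by one archetype
#' multiplier, and assembles a contiguous [workflow_timeline()].
#'
#' @param config A [sim_config()].
#' @param video_id Character scalar.
#' @param seed Optional integer; when given, sampling is a deterministic
#'   function of `(config, seed)` and the caller's RNG state is untouched.
#' @return A [workflow_timeline()], with attribute `archetype` (the sampled
#'   duration multiplier).
#' @export
sample_workflow <- function(config, video_id = "sim", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, sample_workflow(config, video_id)))
  }
  vocab <- config$vocabulary
  mult <- sample(
    config$archetype_multipliers, 1L,
    prob = config$archetype_weights
  )
  is_long <- mult == max(config$archetype_multipliers)

  order0 <- canonical_step_order(config)
  keep <- vapply(order0, function(s) {
    if (vocab$core[match(s, vocab$code)]) return(TRUE)
    p <- if (!is.na(config$marker_step) && s == config$marker_step) {
      if (is_long) config$marker_prob_long else config$marker_prob_short
    } else {
      config$optional_inclusion_prob
    }
    runif(1) < p
  }, logical(1))
  seq_steps <- order0[keep]

  # transpose adjacent core pairs
  core_codes <- vocab$code[vocab$core]
  if (length(seq_steps) > 1L && config$order_swap_prob > 0) {
    i <- 1L
    while (i < length(seq_steps)) {
      if (seq_steps[i] %in% core_codes && seq_steps[i + 1L] %in% core_codes &&
          runif(1) < config$order_swap_prob) {
        seq_steps[c(i, i + 1L)] <- seq_steps[c(i + 1L, i)]
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }

  # repeatable-step insertion: guaranteed once after tumour excision (or the
  # last core step present), plus independent insertions after each step
  rep_code <- config$repeat_step_code
  anchor <- max(which(seq_steps %in% core_codes))
  with_rep <- integer(0)
  for (j in seq_along(seq_steps)) {
    with_rep <- c(with_rep, seq_steps[j])
    insert <- (j == anchor) ||
      (config$repeat_prob_per_step > 0 && runif(1) < config$repeat_prob_per_step)
    if (insert) with_rep <- c(with_rep, rep_code)
  }
  seq_steps <- with_rep

  mean_sec <- config$mean_sec[as.character(seq_steps)] * config$duration_scale
  meanlog <- log(mean_sec) - config$sdlog^2 / 2
  dur <- rlnorm(length(seq_steps), meanlog = meanlog, sdlog = config$sdlog)
  dur <- pmax(1L, as.integer(round(dur * mult)))

  end <- cumsum(dur)
  iv <- tibble::tibble(
    step = as.integer(seq_steps),
    start_sec = as.integer(c(0L, end[-length(end)])),
    end_sec = as.integer(end)
  )
  instruments <- if (config$simulate_instruments) {
    sample_instrument_intervals(iv, config)
  } else {
    NULL
  }
  tl <- workflow_timeline(iv, video_id = video_id, instruments = instruments)
  attr(tl, "archetype") <- mult
  tl
}

# per-step instrument emissions: each step has a small preferred instrument
# set; the interval is filled with exponential-dwell segments
sample_instrument_intervals <- function(iv, config) {
  n_instr <- nrow(config$instrument_vocabulary)
  seg_step <- integer(0)
  seg_len <- integer(0)
  for (j in seq_len(nrow(iv))) {
    s <- iv$step[j]
    pool <- ((s - 1L) * 3L + 0:2) %% n_instr + 1L
    remaining <- iv$end_sec[j] - iv$start_sec[j]
    while (remaining > 0L) {
      len <- min(remaining, max(1L, as.integer(round(rexp(1, 1 / config$instrument_dwell_sec)))))
      seg_step <- c(seg_step, sample(pool, 1L))
      seg_len <- c(seg_len, len)
      remaining <- remaining - len
    }
  }
  end <- cumsum(seg_len)
  runs_to_intervals(rep(seg_step, seg_len))
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sample a cohort of synthetic workflows
#'
#' Draws `n_train + n_val + n_test` independent workflows from `config` and
#' assigns them to splits; reproducible given `seed`.
#'
#' @param config A [sim_config()].
#' @param n_train,n_val,n_test Split sizes (defaults mirror an 88-video
#'   cohort with a 70/8/10 split).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param id_prefix Prefix for generated video ids.
#' @return A cohort tibble (see [as_cohort()]) with an `archetype` column.
#' @export
sample_cohort <- function(config, n_train = 70L, n_val = 8L, n_test = 10L,
                          seed = config$seed, id_prefix = "sim") {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0, n_train + n_val + n_test > 0)
  n <- n_train + n_val + n_test
  with_preserved_seed(seed, {
    ids <- sprintf("%s_%03d", id_prefix, seq_len(n))
    timelines <- lapply(seq_len(n), function(i) sample_workflow(config, ids[i]))
    splits <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    cohort <- as_cohort(timelines, split = splits)
    cohort$archetype <- vapply(timelines, function(tl) attr(tl, "archetype"), numeric(1))
    cohort
  })
}

#' Multiply all interval durations of a timeline
#'
#' Rescales every step (and instrument) interval of a timeline by `scale`
#' (each rounded to at least 1 s), producing an atypically short or long
#' version of the same workflow — an outlier generator for robustness
#' experiments.
#'
#' @param timeline A [workflow_timeline()].
#' @param scale Positive multiplier.
#' @return A [workflow_timeline()].
#' @export
inject_outlier <- function(timeline, scale) {
  stopifnot(scale > 0)
  dur <- pmax(1L, as.integer(round((timeline$end_sec - timeline$start_sec) * scale)))
  end <- cumsum(dur)
  iv <- tibble::tibble(
    step = timeline$step,
    start_sec = as.integer(c(0L, end[-length(end)])),
    end_sec = as.integer(end)
  )
  instr <- instrument_intervals(timeline)
  new_instr <- NULL
  if (!is.null(instr)) {
    old_T <- timeline_duration(timeline)
    new_T <- end[length(end)]
    old_sec <- pmin(old_T - 1L, as.integer(floor((seq_len(new_T) - 1L) * old_T / new_T)))
    new_instr <- runs_to_intervals(labels_at(instr, old_sec))
  }
  workflow_timeline(iv, video_id = video_id(timeline), instruments = new_instr)
}

#' Synthetic frame-embedding configuration
#'
#' Stands in for a frozen per-frame image encoder: every step label has a
#' fixed centroid vector in `D` dimensions and each second's feature is the
#' centroid of the step active at that second plus isotropic Gaussian noise.
#'
#' @param vocabulary Step vocabulary tibble.
#' @param dim Embedding dimensionality `D`.
#' @param noise_sd Standard deviation of the isotropic noise.
#' @param alias_groups Optional list of step-code vectors; the steps within
#'   a group share one centroid, emulating visually indistinguishable phases
#'   whose identity is only resolvable from workflow history (e.g. repeated
#'   drilling or closure steps that look alike on camera).
#' @param seed Seed used to draw the centroids (centroids are a
#'   deterministic function of `(vocabulary, dim, alias_groups, seed)`).
#' @return An `embedding_config` with a `centroids` matrix (one row per
#'   vocabulary code, rownames are codes).
#' @export
embedding_config <- function(vocabulary = pituitary_steps(), dim = 16L,
                             noise_sd = 0.1, alias_groups = NULL, seed = 1L) {
  stopifnot(dim >= 1L, noise_sd >= 0)
  centroids <- with_preserved_seed(seed, {
    m <- matrix(rnorm(nrow(vocabulary) * dim), nrow = nrow(vocabulary))
    m / sqrt(dim)
  })
  rownames(centroids) <- as.character(vocabulary$code)
  for (grp in alias_groups) {
    grp <- as.character(grp)
    if (!all(grp %in% rownames(centroids))) {
      abort("alias_groups refers to step codes outside the vocabulary")
    }
    for (g in grp[-1]) centroids[g, ] <- centroids[grp[1], ]
  }
  structure(
    list(dim = as.integer(dim), noise_sd = noise_sd,
         centroids = centroids, seed = as.integer(seed)),
    class = "embedding_config"
  )
}

#' Sample per-second frame embeddings for a timeline
#'
#' @param timeline A [workflow_timeline()].
#' @param config An [embedding_config()]; every step label appearing in the
#'   timeline must have a centroid.
#' @param seed Optional integer for deterministic sampling.
#' @return A [frame_track()].
#' @export
sample_frame_embeddings <- function(timeline, config, seed = NULL) {
  stopifnot(inherits(config, "embedding_config"))
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, sample_frame_embeddings(timeline, config)))
  }
  T_sec <- timeline_duration(timeline)
  labels <- step_at(timeline, seq_len(T_sec) - 1L)
  missing <- setdiff(as.character(unique(labels)), rownames(config$centroids))
  if (length(missing) > 0L) {
    abort(sprintf("no centroid for step label(s): %s", paste(missing, collapse = ", ")))
  }
  features <- config$centroids[as.character(labels), , drop = FALSE]
  if (config$noise_sd > 0) {
    features <- features + matrix(
      rnorm(length(features), sd = config$noise_sd),
      nrow = nrow(features)
    )
  }
  dimnames(features) <- NULL
  frame_track(features, video_id = video_id(timeline))
}

#' @rdname sample_frame_embeddings
#' @param cohort A cohort tibble.
#' @export
sample_cohort_features <- function(cohort, config, seed = 1L) {
  with_preserved_seed(seed, {
    cohort$track <- lapply(cohort$timeline, sample_frame_embeddings, config = config)
    cohort
  })
}
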