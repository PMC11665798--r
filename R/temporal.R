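#' Configuration of the multi-task temporal RSD network
#'
#' A two-layer LSTM over per-second frame features with up to three output
#' heads: surgical step classification (weighted cross-entropy), instrument
#' classification (weighted cross-entropy, optional) and normalized RSD
#' regression (Smooth L1). The input at second `t` concatenates the frame
#' feature, the elapsed time (seconds / 3600), and — when prior-step context
#' is enabled — the previous second's step-probability vector plus the mean
#' step probabilities over the last `context_window` seconds, both uniform
#' at cold start.
#'
#' The four published ablation variants map onto flags:
#' `"rsd"` (RSD head only), `"s_rsd"` (+ step head), `"si_rsd"`
#' (+ step and instrument heads), `"full"` (step head + prior-step context,
#' plus the instrument head when `n_instruments > 0`).
#'
#' @param feature_dim Frame-feature dimensionality `D`.
#' @param n_steps Number of step classes `S`.
#' @param variant One of `"rsd"`, `"s_rsd"`, `"si_rsd"`, `"full"`, or
#'   `"custom"` to set the three `use_*` flags directly.
#' @param n_instruments Number of instrument classes (0 disables the head).
#' @param hidden_size Hidden units per LSTM layer.
#' @param use_step_head,use_instrument_head,use_prior_context Head/context
#'   flags (only honoured with `variant = "custom"`). Prior context requires
#'   the step head.
#' @param context_window Context window `t_hat` in seconds.
#' @param rsd_norm_factor RSD targets and predictions are divided by this
#'   constant (in minutes) during training; default 10.
#' @param smooth_l1_beta Transition point of the Smooth L1 loss.
#' @param epochs Training epochs.
#' @param lr_schedule Data frame with columns `epochs` and `lr`, consumed in
#'   order; the default follows the published schedule scaled to `epochs`
#'   (first half at 1e-3, second half at 1e-4).
#' @param loss_weights Named multipliers for the per-task losses
#'   (`step`, `instrument`, `rsd`); the default is an unweighted sum.
#' @param tbptt_window Truncated-backprop window in seconds.
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return A `temporal_config` list.
#' @export
temporal_config <- function(feature_dim, n_steps,
                            variant = c("s_rsd", "rsd", "si_rsd", "full", "custom"),
                            n_instruments = 0L,
                            hidden_size = 128L,
                            use_step_head = TRUE,
                            use_instrument_head = FALSE,
                            use_prior_context = FALSE,
                            context_window = 30L,
                            rsd_norm_factor = 10,
                            smooth_l1_beta = 1,
                            epochs = 40L,
                            lr_schedule = NULL,
                            loss_weights = c(step = 1, instrument = 1, rsd = 1),
                            tbptt_window = 512L,
                            seed = 1L) {
  variant <- match.arg(variant)
  flags <- switch(variant,
    rsd = list(step = FALSE, instr = FALSE, ctx = FALSE),
    s_rsd = list(step = TRUE, instr = FALSE, ctx = FALSE),
    si_rsd = list(step = TRUE, instr = TRUE, ctx = FALSE),
    full = list(step = TRUE, instr = n_instruments > 0L, ctx = TRUE),
    custom = list(step = use_step_head, instr = use_instrument_head,
                  ctx = use_prior_context)
  )
  if (flags$ctx && !flags$step) {
    abort("prior-step context requires the step head")
  }
  if (flags$instr && n_instruments < 1L) {
    abort("instrument head requires n_instruments >= 1")
  }
  stopifnot(
    feature_dim >= 1L, n_steps >= 1L, hidden_size >= 1L,
    context_window >= 1L, rsd_norm_factor > 0, smooth_l1_beta > 0,
    epochs >= 1L, tbptt_window >= 1L
  )
  if (is.null(lr_schedule)) {
    first <- ceiling(epochs / 2)
    lr_schedule <- data.frame(
      epochs = c(first, epochs - first),
      lr = c(1e-3, 1e-4)
    )
    lr_schedule <- lr_schedule[lr_schedule$epochs > 0, ]
  }
  lw <- c(step = 1, instrument = 1, rsd = 1)
  lw[names(loss_weights)] <- loss_weights
  structure(
    list(
      feature_dim = as.integer(feature_dim),
      n_steps = as.integer(n_steps),
      n_instruments = as.integer(n_instruments),
      hidden_size = as.integer(hidden_size),
      n_recurrent_layers = 2L,
      variant = variant,
      use_step_head = flags$step,
      use_instrument_head = flags$instr,
      use_prior_context = flags$ctx,
      context_window = as.integer(context_window),
      rsd_norm_factor = rsd_norm_factor,
      smooth_l1_beta = smooth_l1_beta,
      epochs = as.integer(epochs),
      lr_schedule = lr_schedule,
      loss_weights = lw,
      tbptt_window = as.integer(tbptt_window),
      seed = as.integer(seed)
    ),
    class = "temporal_config"
  )
}

input_dim <- function(config) {
  config$feature_dim + 1L +
    if (config$use_prior_context) 2L * config$n_steps else 0L
}

cpp_config <- function(config) {
  list(
    D = config$feature_dim,
    S = config$n_steps,
    n_instruments = max(1L, config$n_instruments),
    H = config$hidden_size,
    use_step = config$use_step_head || config$use_prior_context,
    use_instr = config$use_instrument_head,
    use_context = config$use_prior_context,
    t_hat = config$context_window,
    beta = config$smooth_l1_beta,
    lw_step = if (config$use_step_head) unname(config$loss_weights["step"]) else 0,
    lw_instr = if (config$use_instrument_head) unname(config$loss_weights["instrument"]) else 0,
    lw_rsd = unname(config$loss_weights["rsd"]),
    tbptt = config$tbptt_window
  )
}

#' RSD normalization
#'
#' Divides RSD values (minutes) by a constant factor to bring the regression
#' target to the same order of magnitude as the classification losses;
#' `denormalize_rsd()` is the exact inverse.
#'
#' @param rsd_min RSD in minutes (vectorized).
#' @param x Normalized RSD.
#' @param factor Positive normalization constant (default 10).
#' @return Numeric vector.
#' @examples
#' normalize_rsd(45)      # 4.5
#' denormalize_rsd(4.5)   # 45
#' @export
normalize_rsd <- function(rsd_min, factor = 10) {
  stopifnot(factor > 0)
  rsd_min / factor
}

#' @rdname normalize_rsd
#' @export
denormalize_rsd <- function(x, factor = 10) {
  stopifnot(factor > 0)
  x * factor
}

#' Inverse-frequency class weights
#'
#' Weights used by the weighted cross-entropy losses to counter class
#' imbalance: `w_c = N / (S_present * n_c)` for classes observed in the
#' training labels (so balanced classes get weight 1), and 0 for unobserved
#' classes, which are thereby excluded from the loss.
#'
#' @param labels Integer class labels (1-based codes).
#' @param n_classes Total number of classes.
#' @return A numeric weight vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) abort("cannot derive class weights from empty labels")
  if (any(labels < 1L | labels > n_classes)) {
    abort("labels must be codes in 1..n_classes")
  }
  counts <- tabulate(labels, nbins = n_classes)
  present <- counts > 0L
  w <- numeric(n_classes)
  w[present] <- length(labels) / (sum(present) * counts[present])
  w
}

#' Smooth L1 loss
#'
#' `0.5 r^2 / beta` for `|r| < beta`, `|r| - beta/2` otherwise.
#'
#' @param residual Numeric vector of residuals.
#' @param beta Transition point.
#' @return Elementwise loss values.
#' @export
smooth_l1 <- function(residual, beta = 1) {
  stopifnot(beta > 0)
  ifelse(abs(residual) < beta,
         0.5 * residual^2 / beta,
         abs(residual) - 0.5 * beta)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Joint multi-task training loss
#'
#' The sum (with configurable per-task multipliers, by default an unweighted
#' sum) of weighted cross-entropy step loss, weighted cross-entropy
#' instrument loss (when enabled) and Smooth L1 loss on normalized RSD,
#' averaged over time.
#'
#' @param step_logits `T x S` matrix of step logits (or `NULL`).
#' @param step_true Integer step codes (1-based), length `T`.
#' @param instr_logits,instr_true Optional instrument logits/codes.
#' @param rsd_pred_norm,rsd_true_norm Normalized RSD predictions and targets.
#' @param step_weights,instr_weights Per-class weights (see
#'   [class_weights()]).
#' @param loss_weights Named per-task multipliers.
#' @param beta Smooth L1 transition point.
#' @return A list with `total`, `step`, `instrument`, `rsd` mean losses.
#' @export
multitask_loss <- function(step_logits = NULL, step_true = NULL,
                           instr_logits = NULL, instr_true = NULL,
                           rsd_pred_norm, rsd_true_norm,
                           step_weights = NULL, instr_weights = NULL,
                           loss_weights = c(step = 1, instrument = 1, rsd = 1),
                           beta = 1) {
  if (anyNA(rsd_pred_norm) || anyNA(rsd_true_norm)) {
    abort("NaN/NA in RSD inputs")
  }
  weighted_ce <- function(logits, true, w) {
    if (anyNA(logits)) abort("NaN/NA in logits")
    p <- softmax_rows(logits)
    if (is.null(w)) w <- rep(1, ncol(logits))
    idx <- cbind(seq_along(true), true)
    mean(w[true] * -log(pmax(p[idx], 1e-12)))
  }
  l_step <- if (!is.null(step_logits)) weighted_ce(step_logits, step_true, step_weights) else 0
  l_instr <- if (!is.null(instr_logits)) weighted_ce(instr_logits, instr_true, instr_weights) else 0
  l_rsd <- mean(smooth_l1(rsd_pred_norm - rsd_true_norm, beta))
  lw <- c(step = 1, instrument = 1, rsd = 1)
  lw[names(loss_weights)] <- loss_weights
  list(
    total = unname(lw["step"] * l_step + lw["instrument"] * l_instr + lw["rsd"] * l_rsd),
    step = l_step, instrument = l_instr, rsd = l_rsd
  )
}

#' Prior-step-context state and input construction
#'
#' `context_state()` creates the running state (previous step probabilities
#' and a FIFO of the last `t_hat` probability vectors); `update_context()`
#' pushes a new probability vector; `build_context_feature()` assembles the
#' network input for one second: `[frame feature, elapsed/3600,
#' previous-step probabilities, mean probabilities over the buffer]`, the
#' probability blocks being uniform at cold start and omitted entirely when
#' prior context is disabled.
#'
#' @param config A [temporal_config()].
#' @param state A context state.
#' @param probs A step-probability vector of length `n_steps`.
#' @param frame_feature Numeric feature vector of length `feature_dim`.
#' @param elapsed_sec Elapsed time in seconds.
#' @return `build_context_feature()` returns a numeric vector of length
#'   `feature_dim + 1 + 2 * n_steps` (context on) or `feature_dim + 1`.
#' @export
context_state <- function(config) {
  S <- config$n_steps
  list(last = rep(1 / S, S), buffer = list())
}

#' @rdname context_state
#' @export
update_context <- function(state, probs, config) {
  stopifnot(length(probs) == config$n_steps)
  if (abs(sum(probs) - 1) > 1e-6 || any(probs < 0)) {
    abort("probs must be a probability vector")
  }
  buffer <- c(state$buffer, list(probs))
  if (length(buffer) > config$context_window) {
    buffer <- buffer[-1]
  }
  list(last = probs, buffer = buffer)
}

#' @rdname context_state
#' @export
build_context_feature <- function(frame_feature, elapsed_sec, state, config) {
  if (length(frame_feature) != config$feature_dim) {
    abort(sprintf(
      "frame feature has length %d, expected %d",
      length(frame_feature), config$feature_dim
    ))
  }
  base <- c(as.numeric(frame_feature), elapsed_sec / 3600)
  if (!config$use_prior_context) return(base)
  S <- config$n_steps
  mean_block <- if (length(state$buffer) == 0L) {
    rep(1 / S, S)
  } else {
    Reduce(`+`, state$buffer) / length(state$buffer)
  }
  c(base, state$last, mean_block)
}

init_params <- function(config) {
  H <- config$hidden_size
  F_dim <- input_dim(config)
  S <- config$n_steps
  nI <- max(1L, config$n_instruments)
  u <- function(nr, nc) {
    r <- 1 / sqrt(H)
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  forget_bias <- function() {
    b <- runif(4 * H, -1 / sqrt(H), 1 / sqrt(H))
    b[(H + 1):(2 * H)] <- 1  # open forget gates at init
    b
  }
  list(
    W1 = u(4 * H, F_dim), U1 = u(4 * H, H), b1 = forget_bias(),
    W2 = u(4 * H, H), U2 = u(4 * H, H), b2 = forget_bias(),
    Ws = u(S, H), bs = numeric(S),
    Wi = u(nI, H), bi = numeric(nI),
    Wr = runif(H, -1 / sqrt(H), 1 / sqrt(H)), br = 0
  )
}

video_targets <- function(timeline, config) {
  T_sec <- timeline_duration(timeline)
  secs <- seq_len(T_sec) - 1L
  y_step <- as.integer(step_at(timeline, secs)) - 1L
  instr <- instrument_intervals(timeline)
  y_instr <- if (!is.null(instr)) as.integer(labels_at(instr, secs)) - 1L else rep(-1L, T_sec)
  rsd_norm <- normalize_rsd(true_rsd(timeline, secs), config$rsd_norm_factor)
  list(y_step = y_step, y_instr = y_instr, rsd_norm = rsd_norm)
}

#' Fit the multi-task temporal RSD network
#'
#' Trains the two-layer LSTM on the training split's frame-feature tracks
#' and per-second annotations with Adam, one surgery per update, unrolling
#' each video online so that prior-step-context inputs are built from the
#' model's own running step predictions (gradients do not flow through the
#' context path). The learning rate follows `config$lr_schedule`; the
#' checkpoint with the best validation full-duration RSD MAE is kept (the
#' final weights when the cohort has no validation split).
#'
#' @param cohort A cohort tibble with a `track` list-column (see
#'   [sample_cohort_features()]) and timelines aligned per second.
#' @param config A [temporal_config()].
#' @param quiet Suppress the per-epoch progress line.
#' @return An `rsd_temporal` model with fields `params`, `config` and a
#'   per-epoch training `log` tibble.
#' @export
fit_rsd_temporal <- function(cohort, config, quiet = TRUE) {
  stopifnot(inherits(config, "temporal_config"))
  if (!"track" %in% names(cohort)) {
    abort("cohort has no 'track' feature column; run sample_cohort_features() or read features")
  }
  train <- cohort_split(cohort, "train")
  val <- cohort_split(cohort, "val")
  if (nrow(train) == 0L) abort("cannot train on an empty training split")
  for (i in seq_len(nrow(train))) {
    tr <- train$track[[i]]
    tl <- train$timeline[[i]]
    if (is.null(tr) || nrow(tr$features) != timeline_duration(tl)) {
      abort(sprintf("track and timeline misaligned for '%s'", train$video_id[i]))
    }
    if (ncol(tr$features) != config$feature_dim) {
      abort(sprintf("track dimension mismatch for '%s'", train$video_id[i]))
    }
  }

  all_steps <- unlist(lapply(train$timeline, function(tl) {
    step_at(tl, seq_len(timeline_duration(tl)) - 1L)
  }))
  w_step <- class_weights(all_steps, config$n_steps)
  w_instr <- rep(1, max(1L, config$n_instruments))
  if (config$use_instrument_head) {
    all_instr <- unlist(lapply(train$timeline, function(tl) {
      iv <- instrument_intervals(tl)
      if (is.null(iv)) abort("instrument head requires instrument annotations")
      labels_at(iv, seq_len(timeline_duration(tl)) - 1L)
    }))
    w_instr <- class_weights(all_instr, config$n_instruments)
  }

  targets <- lapply(train$timeline, video_targets, config = config)
  feats <- lapply(train$track, function(tr) t(tr$features))
  cfg <- cpp_config(config)
  lr_per_epoch <- rep(config$lr_schedule$lr, config$lr_schedule$epochs)
  lr_per_epoch <- rep_len(lr_per_epoch, config$epochs)

  with_preserved_seed(config$seed, {
    params <- init_params(config)
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    adam_t <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(params = params, val_mae = Inf, epoch = 0L)
    log <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      lr <- lr_per_epoch[epoch]
      order_idx <- sample(nrow(train))
      ep_loss <- c(total = 0, step = 0, instrument = 0, rsd = 0)
      for (i in order_idx) {
        tg <- targets[[i]]
        out <- lstm_grad_video_cpp(
          params, feats[[i]], as.numeric(seq_len(ncol(feats[[i]])) - 1L),
          tg$y_step, tg$y_instr, tg$rsd_norm, w_step, w_instr, cfg
        )
        adam_t <- adam_t + 1L
        for (nm in names(params)) {
          g <- out$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]] / (1 - b1^adam_t)
          vhat <- adam_v[[nm]] / (1 - b2^adam_t)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + c(out$loss, out$loss_step, out$loss_instr, out$loss_rsd)
      }
      ep_loss <- ep_loss / nrow(train)
      val_mae <- NA_real_
      if (nrow(val) > 0L) {
        val_mae <- mean(vapply(seq_len(nrow(val)), function(j) {
          pr <- predict_track_rsd(params, val$track[[j]], config)
          mean(abs(pr - true_rsd(val$timeline[[j]], seq_len(length(pr)) - 1L)))
        }, numeric(1)))
        if (val_mae < best$val_mae) {
          best <- list(params = params, val_mae = val_mae, epoch = epoch)
        }
      }
      log[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        loss = ep_loss[["total"]], loss_step = ep_loss[["step"]],
        loss_instrument = ep_loss[["instrument"]], loss_rsd = ep_loss[["rsd"]],
        # realized classification:regression loss magnitude ratio (diagnostic)
        cls_rsd_ratio = (ep_loss[["step"]] + ep_loss[["instrument"]]) /
          max(ep_loss[["rsd"]], 1e-12),
        val_mae_min = val_mae
      )
      if (!quiet) {
        message(sprintf(
          "epoch %d/%d lr %.4g loss %.4f val MAE %.2f min",
          epoch, config$epochs, lr, ep_loss[["total"]], val_mae
        ))
      }
    }
    if (nrow(val) == 0L) best <- list(params = params, val_mae = NA_real_, epoch = config$epochs)
    structure(
      list(
        params = best$params,
        config = config,
        class_weights = list(step = w_step, instrument = w_instr),
        log = dplyr::bind_rows(log),
        best_epoch = best$epoch,
        val_mae_min = best$val_mae
      ),
      class = c("rsd_temporal", "rsd_model")
    )
  })
}

predict_track_rsd <- function(params, track, config) {
  out <- lstm_predict_video_cpp(
    params, t(track$features), as.numeric(track$elapsed_sec),
    cpp_config(config), FALSE
  )
  pmax(0, denormalize_rsd(as.numeric(out$rsd_norm), config$rsd_norm_factor))
}

#' Online prediction with the temporal model
#'
#' Runs strictly causal inference over each surgery's frame-feature track:
#' the output at second `t` depends only on frames `0..t`. RSD predictions
#' are denormalized to minutes (clamped at 0) and the step head's argmax is
#' reported per second.
#'
#' @param object A fitted `rsd_temporal`.
#' @param cohort A cohort tibble with a `track` list-column.
#' @param split Which split to predict on.
#' @param ... Unused.
#' @return A tibble with columns `video_id`, `sec`, `rsd_pred_min` and,
#'   when the step head is enabled, `step_pred`.
#' @export
predict.rsd_temporal <- function(object, cohort, split = "test", ...) {
  videos <- cohort_split(cohort, split)
  config <- object$config
  purrr::map_dfr(seq_len(nrow(videos)), function(i) {
    track <- videos$track[[i]]
    if (is.null(track)) abort(sprintf("no track for '%s'", videos$video_id[i]))
    if (nrow(track$features) == 0L) {
      return(tibble::tibble(
        video_id = character(0), sec = integer(0), rsd_pred_min = numeric(0)
      ))
    }
    out <- lstm_predict_video_cpp(
      object$params, t(track$features), as.numeric(track$elapsed_sec),
      cpp_config(config), FALSE
    )
    res <- tibble::tibble(
      video_id = videos$video_id[i],
      sec = track$elapsed_sec,
      rsd_pred_min = pmax(0, denormalize_rsd(as.numeric(out$rsd_norm),
                                             config$rsd_norm_factor))
    )
    if (config$use_step_head) {
      res$step_pred <- as.integer(apply(out$step_probs, 2, which.max))
    }
    res
  })
}

#' @rdname predict.rsd_temporal
#' @param track A [frame_track()].
#' @return `predict_step_probs()` returns a `T x n_steps` matrix of
#'   per-second step probabilities for one track.
#' @export
predict_step_probs <- function(object, track) {
  stopifnot(inherits(object, "rsd_temporal"))
  out <- lstm_predict_video_cpp(
    object$params, t(track$features), as.numeric(track$elapsed_sec),
    cpp_config(object$config), FALSE
  )
  t(out$step_probs)
}

#' @export
print.rsd_temporal <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rsd_temporal variant '%s': D=%d, S=%d, H=%d x %d layers%s%s>\n",
    cfg$variant, cfg$feature_dim, cfg$n_steps, cfg$hidden_size,
    cfg$n_recurrent_layers,
    if (cfg$use_prior_context) ", prior context" else "",
    if (cfg$use_instrument_head) ", instrument head" else ""
  ))
  if (!is.na(x$val_mae_min)) {
    cat(sprintf("  best epoch %d, val MAE %.2f min\n", x$best_epoch, x$val_mae_min))
  }
  invisible(x)
}
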