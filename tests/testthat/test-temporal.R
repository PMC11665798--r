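tiny_config <- function(...) {
  temporal_config(feature_dim = 4, n_steps = 3, variant = "custom",
                  use_step_head = TRUE, hidden_size = 5, epochs = 2,
                  tbptt_window = 64, seed = 3, ...)
}

test_that("context feature is [feature, elapsed, prev probs, mean probs] with uniform cold start", {
  cfg <- temporal_config(768, 14, variant = "full", hidden_size = 4)
  st <- context_state(cfg)
  x <- build_context_feature(rnorm(768), 0, st, cfg)
  expect_length(x, 797)
  expect_equal(x[770:783], rep(1 / 14, 14))
  expect_equal(x[784:797], rep(1 / 14, 14))

  cfg_off <- temporal_config(768, 14, variant = "s_rsd")
  expect_length(build_context_feature(rnorm(768), 30, context_state(cfg_off), cfg_off), 769)
  expect_equal(build_context_feature(rep(0, 768), 1800, context_state(cfg_off), cfg_off)[769], 0.5)
  expect_error(build_context_feature(rnorm(3), 0, st, cfg), "length")

  # FIFO: mean block averages at most t_hat recent probability vectors
  cfg2 <- temporal_config(2, 2, variant = "full", context_window = 2)
  st2 <- context_state(cfg2)
  st2 <- update_context(st2, c(1, 0), cfg2)
  st2 <- update_context(st2, c(0, 1), cfg2)
  st2 <- update_context(st2, c(0, 1), cfg2)
  x2 <- build_context_feature(c(0, 0), 0, st2, cfg2)
  expect_equal(x2[4:5], c(0, 1))        # previous-frame probabilities
  expect_equal(x2[6:7], c(0, 1))        # mean over the last 2 only
  expect_error(update_context(st2, c(0.2, 0.2), cfg2), "probability")
})

test_that("RSD normalization by the factor of 10 is exactly invertible", {
  expect_equal(normalize_rsd(45), 4.5)
  expect_equal(normalize_rsd(0), 0)
  x <- runif(50, 0, 180)
  expect_identical(denormalize_rsd(normalize_rsd(x, 10), 10), x)
  expect_equal(denormalize_rsd(normalize_rsd(x, 7.3), 7.3), x, tolerance = 1e-14)
})

test_that("class weights are inverse-frequency with absent classes zeroed", {
  w <- class_weights(c(1, 1, 1, 2), 2)
  expect_equal(w, c(4 / 6, 2))
  expect_equal(class_weights(rep(1:3, 5), 3), rep(1, 3))
  expect_equal(class_weights(rep(2, 4), 3), c(0, 1, 0))
  expect_error(class_weights(integer(), 3), "empty")
  expect_error(class_weights(5, 3), "1..n_classes")
})

test_that("multitask loss vanishes for perfect predictions and follows Smooth L1 branches", {
  expect_equal(smooth_l1(0.5, 1), 0.125)
  expect_equal(smooth_l1(2, 1), 1.5)
  expect_equal(smooth_l1(-2, 1), 1.5)

  onehot <- matrix(-1e3, nrow = 4, ncol = 3)
  truth <- c(1L, 3L, 2L, 1L)
  onehot[cbind(1:4, truth)] <- 1e3
  l <- multitask_loss(step_logits = onehot, step_true = truth,
                      rsd_pred_norm = c(1, 2, 3, 4), rsd_true_norm = c(1, 2, 3, 4))
  expect_equal(l$total, 0, tolerance = 1e-10)

  l2 <- multitask_loss(rsd_pred_norm = 0.5, rsd_true_norm = 0)
  expect_equal(l2$total, 0.125)
  expect_error(multitask_loss(rsd_pred_norm = NaN, rsd_true_norm = 0), "NaN")
})

test_that("analytic BPTT gradients match finite differences", {
  cfg <- tiny_config()
  ccfg <- surgrsd:::cpp_config(cfg)
  with_seed(7, {
    p <- surgrsd:::init_params(cfg)
    Tn <- 9
    feat <- matrix(rnorm(4 * Tn), 4, Tn)
    y <- sample(0:2, Tn, TRUE)
    rsdn <- runif(Tn)
    w <- c(0.5, 1, 1.5)
    args <- list(feat, as.numeric(0:(Tn - 1)), as.integer(y), rep(-1L, Tn),
                 rsdn, w, 1, ccfg)
    g <- do.call(surgrsd:::lstm_grad_video_cpp, c(list(p), args))
    loss_at <- function(pp) do.call(surgrsd:::lstm_grad_video_cpp, c(list(pp), args))$loss
    eps <- 1e-6
    for (nm in c("W1", "U1", "b1", "U2", "Ws", "Wr", "br")) {
      for (i in seq_len(min(4, length(p[[nm]])))) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        ana <- if (nm == "br") g$grads[[nm]] else g$grads[[nm]][i]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  })
})

test_that("zeroed task weights silence the corresponding head gradients", {
  with_seed(9, {
    Tn <- 6
    feat <- matrix(rnorm(4 * Tn), 4, Tn)
    y <- sample(0:2, Tn, TRUE)
    rsdn <- runif(Tn)
    grads_for <- function(lw) {
      cfg <- tiny_config(loss_weights = lw)
      p <- surgrsd:::init_params(cfg)
      surgrsd:::lstm_grad_video_cpp(
        p, feat, as.numeric(0:(Tn - 1)), as.integer(y), rep(-1L, Tn),
        rsdn, rep(1, 3), 1, surgrsd:::cpp_config(cfg)
      )$grads
    }
    g_step_only <- grads_for(c(step = 1, rsd = 0))
    expect_identical(as.numeric(g_step_only$Wr), rep(0, 5))
    expect_identical(g_step_only$br, 0)
    expect_gt(sum(abs(g_step_only$Ws)), 0)
    g_rsd_only <- grads_for(c(step = 0, rsd = 1))
    expect_identical(unname(as.vector(g_rsd_only$Ws)), rep(0, 15))
    expect_gt(sum(abs(g_rsd_only$Wr)), 0)
  })
})

small_tracked_cohort <- function(seed = 11, n = c(6, 2, 2), noise = 0.05) {
  co <- sample_cohort(benchmark5_sim_config(), n[1], n[2], n[3], seed = seed)
  ec <- embedding_config(vocab5(), dim = 8, noise_sd = noise, seed = 2)
  sample_cohort_features(co, ec, seed = seed + 1)
}

test_that("online prediction is strictly causal and deterministic", {
  co <- small_tracked_cohort()
  cfg <- temporal_config(8, 5, variant = "full", hidden_size = 8, epochs = 1,
                         tbptt_window = 64, seed = 4)
  m <- fit_rsd_temporal(co, cfg)
  track <- co$track[[which(co$split == "test")[1]]]
  base <- predict(m, co, split = "test")
  base1 <- base[base$video_id == track$video_id, ]
  probs <- predict_step_probs(m, track)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  with_seed(15, {
    for (trial in 1:10) {
      t_cut <- sample(50:(nrow(track$features) - 10), 1)
      pert <- track
      idx <- (t_cut + 2):nrow(pert$features)  # seconds > t_cut (0-based)
      pert$features[idx, ] <- pert$features[idx, ] +
        matrix(rnorm(length(idx) * 8, sd = 3), length(idx), 8)
      co2 <- co
      co2$track[[which(co$split == "test")[1]]] <- pert
      out <- predict(m, co2, split = "test")
      out1 <- out[out$video_id == track$video_id, ]
      expect_identical(out1$rsd_pred_min[out1$sec <= t_cut],
                       base1$rsd_pred_min[base1$sec <= t_cut])
      expect_identical(out1$step_pred[out1$sec <= t_cut],
                       base1$step_pred[base1$sec <= t_cut])
    }
  })
  # same config and seed refit twice gives identical weights
  m2 <- fit_rsd_temporal(co, cfg)
  expect_identical(m$params, m2$params)
})

test_that("context inputs realized during inference match the R-side constructor", {
  co <- small_tracked_cohort(seed = 21, n = c(3, 0, 1))
  cfg <- temporal_config(8, 5, variant = "full", hidden_size = 8, epochs = 1,
                         context_window = 4, seed = 6)
  m <- fit_rsd_temporal(co, cfg)
  track <- co$track[[which(co$split == "test")[1]]]
  out <- surgrsd:::lstm_predict_video_cpp(
    m$params, t(track$features), as.numeric(track$elapsed_sec),
    surgrsd:::cpp_config(cfg), TRUE
  )
  st <- context_state(cfg)
  for (t in seq_len(min(40, nrow(track$features)))) {
    x_r <- build_context_feature(track$features[t, ], track$elapsed_sec[t], st, cfg)
    expect_equal(as.numeric(out$inputs[, t]), x_r, tolerance = 1e-12)
    st <- update_context(st, as.numeric(out$step_probs[, t]), cfg)
  }
})

test_that("training rejects misaligned or missing tracks and empty tracks predict empty", {
  co <- small_tracked_cohort(seed = 31, n = c(3, 1, 1))
  cfg <- temporal_config(8, 5, variant = "s_rsd", hidden_size = 8, epochs = 1, seed = 2)
  broken <- co
  broken$track[[1]] <- frame_track(broken$track[[1]]$features[-1, , drop = FALSE],
                                   video_id = broken$video_id[1])
  expect_error(fit_rsd_temporal(broken, cfg), "misaligned")
  no_track <- co[, setdiff(names(co), "track")]
  expect_error(fit_rsd_temporal(no_track, cfg), "track")

  m <- fit_rsd_temporal(co, cfg)
  co_empty <- co
  co_empty$track[[which(co$split == "test")[1]]] <-
    frame_track(matrix(numeric(0), 0, 8), video_id = "empty")
  pred <- predict(m, co_empty, split = "test")
  expect_equal(nrow(pred), 0)
})

test_that("ablation variants wire the heads as configured", {
  expect_false(temporal_config(8, 5, variant = "rsd")$use_step_head)
  cfg_s <- temporal_config(8, 5, variant = "s_rsd")
  expect_true(cfg_s$use_step_head)
  expect_false(cfg_s$use_prior_context)
  cfg_si <- temporal_config(8, 5, variant = "si_rsd", n_instruments = 18)
  expect_true(cfg_si$use_instrument_head)
  cfg_full <- temporal_config(8, 5, variant = "full")
  expect_true(cfg_full$use_prior_context)
  expect_error(
    temporal_config(8, 5, variant = "custom", use_step_head = FALSE,
                    use_prior_context = TRUE),
    "requires the step head"
  )
  expect_error(temporal_config(8, 5, variant = "si_rsd"), "n_instruments")

  # rsd-only variant trains and predicts without a step column
  co <- small_tracked_cohort(seed = 41, n = c(3, 1, 1))
  m <- fit_rsd_temporal(co, temporal_config(8, 5, variant = "rsd", hidden_size = 8,
                                            epochs = 1, seed = 2))
  pred <- predict(m, co, split = "test")
  expect_false("step_pred" %in% names(pred))
  expect_true(all(pred$rsd_pred_min >= 0))
})

test_that("the default learning-rate schedule halves at the published breakpoint", {
  cfg <- temporal_config(8, 5, epochs = 40)
  expect_equal(cfg$lr_schedule$epochs, c(20, 20))
  expect_equal(cfg$lr_schedule$lr, c(1e-3, 1e-4))
  expect_equal(cfg$rsd_norm_factor, 10)
  expect_equal(cfg$n_recurrent_layers, 2L)
})
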