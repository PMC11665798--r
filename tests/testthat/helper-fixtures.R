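with_seed <- withr::with_seed

# Interval columns only, independent of carried attributes.
intervals_of <- function(tl) {
  tibble::tibble(step = tl$step, start_sec = tl$start_sec, end_sec = tl$end_sec)
}

# Build a timeline from parallel step/duration vectors.
make_timeline <- function(steps, dur_sec, video_id = "tl", instruments = NULL,
                          instr_dur = NULL) {
  end <- cumsum(dur_sec)
  iv <- data.frame(
    step = as.integer(steps),
    start_sec = as.integer(c(0L, end[-length(end)])),
    end_sec = as.integer(end)
  )
  instr <- NULL
  if (!is.null(instruments)) {
    iend <- cumsum(instr_dur)
    instr <- data.frame(
      step = as.integer(instruments),
      start_sec = as.integer(c(0L, iend[-length(iend)])),
      end_sec = as.integer(iend)
    )
  }
  workflow_timeline(iv, video_id = video_id, instruments = instr)
}

# A deterministic simulator config with all randomness disabled: fixed core
# order, no optionals, no extra haemostasis, point-mass durations.
degenerate_sim_config <- function() {
  sim_config(
    optional_inclusion_prob = 0, order_swap_prob = 0,
    repeat_prob_per_step = 0, sdlog = 0, duration_scale = 1,
    archetype_multipliers = 1, archetype_weights = 1, marker_step = NA
  )
}

# Small five-step all-core vocabulary used by the temporal benchmarks.
vocab5 <- function() {
  v <- pituitary_steps()[1:5, ]
  v$core <- TRUE
  v
}

benchmark5_sim_config <- function() {
  sim_config(
    vocabulary = vocab5(),
    mean_sec = c("1" = 60, "2" = 80, "3" = 100, "4" = 80, "5" = 60),
    repeat_step_code = 5L, repeat_prob_per_step = 0.1, order_swap_prob = 0.1,
    marker_step = NA, duration_scale = 1,
    archetype_multipliers = c(1, 1.6), archetype_weights = c(0.75, 0.25)
  )
}

# Naive exponential-recursion edit-distance oracle (memoised on suffix
# pairs); independent of the package's dynamic-programming implementation.
lev_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- min(
      rec(i + 1L, j + 1L) + (a[i] != b[j]),
      rec(i + 1L, j) + 1L,
      rec(i, j + 1L) + 1L
    )
    memo[[key]] <- res
    res
  }
  rec(1L, 1L)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments over the observed ranks (zeros already dropped).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
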