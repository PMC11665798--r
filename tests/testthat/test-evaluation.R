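pred_tibble <- function(id, values) {
  tibble::tibble(video_id = id, sec = seq_along(values) - 1L, rsd_pred_min = values)
}

test_that("per-video MAE matches hand-computed values on toy series", {
  tl <- make_timeline(1, 3, video_id = "toy")  # gt (in min): 3/60, 2/60, 1/60... use offsets
  co <- as_cohort(list(tl), split = "test")
  gt <- true_rsd(tl, 0:2)
  expect_equal(
    mae_by_video(pred_tibble("toy", c(10, 8, 5)), co, "full")$mae_min,
    mean(abs(c(10, 8, 5) - gt))
  )
  # the canonical 3-second fixture: |pred - gt| = (1, 0, 2) -> MAE 1.0
  expect_equal(
    mae_by_video(pred_tibble("toy", gt + c(1, 0, -2)), co, "full")$mae_min,
    1.0
  )
  expect_equal(mae_by_video(pred_tibble("toy", gt), co, "full")$mae_min, 0)
  expect_equal(
    mae_by_video(pred_tibble("toy", gt + 2), co,
                 c("full", "last20", "last10"))$mae_min,
    rep(2, 3)
  )
  expect_error(
    mae_by_video(pred_tibble("toy", c(1, 2)), co, "full"),
    "cover"
  )
})

test_that("last-K windows select exactly the last 60K seconds", {
  tl <- make_timeline(1, 1500, video_id = "w")
  co <- as_cohort(list(tl), split = "test")
  gt <- true_rsd(tl, 0:1499)
  err <- rep(0, 1500); err[901:1500] <- 5  # nonzero only in the last 600 s
  pv <- mae_by_video(pred_tibble("w", gt + err), co, c("full", "last20", "last10"))
  expect_equal(pv$mae_min[pv$window == "last10"], 5)
  expect_equal(pv$mae_min[pv$window == "full"], 5 * 600 / 1500)
  expect_equal(pv$mae_min[pv$window == "last20"], 5 * 600 / 1200)
  # videos shorter than the window fall back to the full duration
  short <- make_timeline(1, 300, video_id = "s")
  co2 <- as_cohort(list(short), split = "test")
  pv2 <- mae_by_video(pred_tibble("s", true_rsd(short, 0:299) + 1), co2,
                      c("full", "last10"))
  expect_equal(pv2$mae_min, c(1, 1))
})

test_that("full-window MAE is the duration-weighted combination of a partition", {
  tl <- make_timeline(c(1, 2), c(700, 800), video_id = "p")
  co <- as_cohort(list(tl), split = "test")
  with_seed(5, {
    pred <- pred_tibble("p", true_rsd(tl, 0:1499) + rnorm(1500))
  })
  full <- mae_by_video(pred, co, "full")$mae_min
  err <- abs(pred$rsd_pred_min - true_rsd(tl, pred$sec))
  parts <- split(err, rep(1:3, c(500, 400, 600)))
  expect_equal(full, sum(vapply(parts, sum, numeric(1))) / 1500)
})

test_that("cohort MAE averages per video with sample sd", {
  pv <- tibble::tibble(video_id = c("a", "b"), window = "full", mae_min = c(2, 4))
  s <- cohort_mae(pv)
  expect_equal(s$mean_mae_min, 3)
  expect_equal(s$sd_mae_min, sd(c(2, 4)))
  one <- cohort_mae(tibble::tibble(video_id = "a", window = "full", mae_min = 5))
  expect_equal(one$mean_mae_min, 5)
  expect_equal(one$sd_mae_min, 0)
  expect_error(cohort_mae(pv[0, ]), "no per-video")
})

test_that("paired Wilcoxon matches enumeration and reference implementations", {
  res <- wilcoxon_paired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.25)
  expect_equal(res$method, "exact")

  expect_equal(wilcoxon_paired(c(1, 2), c(1, 2))$p_value, 1)
  expect_true(wilcoxon_paired(c(1, 2), c(1, 2))$degenerate)

  with_seed(33, {
    for (i in 1:15) {
      n <- sample(3:8, 1)
      a <- round(runif(n, 0, 10), 1)
      b <- round(runif(n, 0, 10), 1)
      if (all(a == b)) next
      res <- wilcoxon_paired(a, b)
      expect_equal(res$p_value, wilcoxon_enum_oracle(a - b), tolerance = 1e-12)
      expect_equal(res$p_value, wilcoxon_paired(b, a)$p_value)
    }
    # no ties, no zeros: agrees with stats::wilcox.test exact p
    a <- c(1.3, 5.2, 0.4, 7.7, 2.9, 9.1, 4.4)
    b <- c(2.1, 3.3, 6.5, 0.2, 8.8, 1.7, 5.5)
    expect_equal(
      wilcoxon_paired(a, b)$p_value,
      stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    )
    # large-n normal approximation agrees with the uncorrected reference
    a2 <- rnorm(40); b2 <- rnorm(40)
    expect_equal(
      wilcoxon_paired(a2, b2)$p_value,
      stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                         correct = FALSE)$p.value,
      tolerance = 1e-10
    )
  })
})

test_that("macro-F1 follows the per-class definition and ignores truth-absent classes", {
  expect_equal(macro_f1(c(1, 2, 1, 3), c(1, 2, 1, 3)), 1)
  expect_equal(macro_f1(c("A", "A", "B"), c("A", "A", "A")), 0.4)
  expect_equal(macro_f1(c(1, 1, 2, 2), c(1, 1, 1, 1)), 1 / 3)
  # classes absent from truth are excluded even if predicted
  expect_equal(macro_f1(c(1, 1), c(1, 2), classes = 1:5), 2 / 3)
  # invariant under relabeling permutations
  with_seed(41, {
    truth <- sample(1:4, 60, TRUE)
    pred <- sample(1:4, 60, TRUE)
    perm <- sample(4)
    expect_equal(macro_f1(perm[truth], perm[pred]), macro_f1(truth, pred))
  })
  expect_error(macro_f1(1:3, 1:4), "equal length")
})

test_that("evaluate_rsd assembles summary, macro-F1 and paired comparisons", {
  tls <- list(make_timeline(1, 120, video_id = "a"),
              make_timeline(c(1, 2), c(60, 90), video_id = "b"))
  co <- as_cohort(tls, split = "test")
  good <- dplyr::bind_rows(
    pred_tibble("a", true_rsd(tls[[1]], 0:119)),
    pred_tibble("b", true_rsd(tls[[2]], 0:149))
  )
  bad <- dplyr::mutate(good, rsd_pred_min = rsd_pred_min + 3)
  bad$step_pred <- 1L
  rep <- evaluate_rsd(list(good = good, bad = bad), co, windows = "full")
  expect_equal(
    rep$summary$mean_mae_min[rep$summary$method == "good"], 0
  )
  expect_equal(
    rep$summary$mean_mae_min[rep$summary$method == "bad"], 3
  )
  expect_equal(nrow(rep$comparisons), 1)
  expect_equal(rep$comparisons$wilcoxon_p, 0.5)  # n_eff = 2, all negative
  expect_equal(rep$macro_f1$method, "bad")
  # step truth for 'b' is 60 s of step 1 + 90 s of step 2; constant pred -> F1
  expect_equal(
    rep$macro_f1$macro_f1,
    macro_f1(c(rep(1, 120), rep(1, 60), rep(2, 90)), rep(1, 270))
  )
})
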