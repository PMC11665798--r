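cohort_from_durations <- function(dur_min, split = "train") {
  tls <- lapply(seq_along(dur_min), function(i) {
    make_timeline(1, dur_min[i] * 60, video_id = paste0("v", i))
  })
  as_cohort(tls, split = split)
}

test_that("naive estimator is the clamped mean training duration", {
  m <- fit_rsd_naive(cohort_from_durations(c(60, 70, 110)))
  expect_equal(m$t_ref_min, 80)
  expect_equal(predict_naive_rsd(m, 20), 60)
  expect_equal(predict_naive_rsd(m, 80.001), 0)
  expect_equal(predict_naive_rsd(m, 0), 80)

  single <- fit_rsd_naive(cohort_from_durations(50))
  expect_equal(single$t_ref_min, 50)
  expect_error(fit_rsd_naive(cohort_from_durations(50, split = "test")), "empty")

  # non-increasing in elapsed time, zero exactly at T_ref
  tel <- seq(0, 120, by = 0.25)
  pred <- predict_naive_rsd(m, tel)
  expect_true(all(diff(pred) <= 0))
  expect_equal(predict_naive_rsd(m, 80), 0)
  expect_true(all(pred >= 0))
})

test_that("step-inferred reference durations and canonical order come from training means", {
  one <- as_cohort(list(make_timeline(c(1, 2), c(600, 1200), "a")))
  m1 <- fit_rsd_step_inferred(one)
  expect_equal(m1$canonical_order, c(1L, 2L))
  expect_equal(unname(m1$t_ref_min[c("1", "2")]), c(10, 20))

  two <- as_cohort(list(
    make_timeline(c(1, 2), c(600, 600), "a"),
    make_timeline(c(1, 2), c(1200, 600), "b")
  ))
  expect_equal(unname(fit_rsd_step_inferred(two)$t_ref_min[["1"]]), 15)

  # a step absent from training is excluded from the canonical order
  expect_false(3L %in% fit_rsd_step_inferred(two)$canonical_order)

  # repeated occurrences pool into one total-time reference duration
  rep_cohort <- as_cohort(list(make_timeline(c(1, 8, 1, 8), c(60, 30, 60, 30), "a")))
  mr <- fit_rsd_step_inferred(rep_cohort)
  expect_equal(unname(mr$t_ref_min[["1"]]), 2)
  expect_equal(unname(mr$t_ref_min[["8"]]), 1)
})

test_that("step-inferred prediction is clamp-plus-remaining-steps", {
  m <- fit_rsd_step_inferred(as_cohort(list(
    make_timeline(c(1, 2), c(600, 1200), "a")
  )))
  expect_equal(predict_step_rsd(m, 1, 5), 25)
  expect_equal(predict_step_rsd(m, 2, 25), 0)
  expect_equal(predict_step_rsd(m, 1, 0), 30)
  expect_error(predict_step_rsd(m, 7, 0), "canonical order")
})

test_that("per-second step-inferred series falls back gracefully on unseen steps", {
  train <- as_cohort(list(make_timeline(c(1, 2), c(600, 1200), "a")))
  m <- fit_rsd_step_inferred(train)
  test <- as_cohort(list(make_timeline(c(1, 9, 2), c(60, 30, 60), "q")), split = "test")
  pred <- predict(m, test)
  expect_equal(nrow(pred), 150)
  expect_true(all(pred$rsd_pred_min >= 0))
  # during the unseen step 9, prediction = remaining after last known step (1)
  expect_equal(unique(pred$rsd_pred_min[pred$sec %in% 60:89]), 20)
})

test_that("levenshtein distance matches utils::adist and satisfies metric axioms", {
  expect_equal(levenshtein(utf8ToInt("kitten"), utf8ToInt("sitting")), 3)
  expect_equal(levenshtein(integer(), 1:3), 3)
  expect_equal(levenshtein(1:4, 1:4), 0)
  with_seed(21, {
    seqs <- replicate(40, sample(1:4, sample(0:7, 1), replace = TRUE), simplify = FALSE)
    for (i in 1:40) {
      a <- seqs[[sample(40, 1)]]; b <- seqs[[sample(40, 1)]]; c <- seqs[[sample(40, 1)]]
      d_ab <- levenshtein(a, b)
      # cross-check against base R's independent C implementation
      expect_equal(
        d_ab,
        as.integer(utils::adist(intToUtf8(a + 64), intToUtf8(b + 64)))
      )
      expect_identical(d_ab, levenshtein(b, a))
      expect_identical(d_ab == 0L, identical(as.integer(a), as.integer(b)))
      expect_lte(d_ab, levenshtein(a, c) + levenshtein(c, b))
    }
  })
})

test_that("sequence matching with k = |history| reproduces the naive predictor", {
  cohort <- sample_cohort(sim_config(), 12, 0, 4, seed = 31)
  naive <- fit_rsd_naive(cohort)
  sm <- fit_rsd_seqmatch(cohort, k = 12)
  expect_identical(
    predict(sm, cohort, split = "test")$rsd_pred_min,
    predict(naive, cohort, split = "test")$rsd_pred_min
  )
})

test_that("a query identical to a training video is recovered exactly with k = 1", {
  # distinct opening steps keep compressed prefixes unique at every second
  train <- as_cohort(list(
    make_timeline(c(1, 2, 3, 7), c(300, 400, 500, 600), "a"),
    make_timeline(c(2, 3, 1, 7), c(500, 300, 700, 400), "b"),
    make_timeline(c(3, 1, 2, 7), c(400, 600, 300, 900), "c")
  ))
  twin <- make_timeline(c(2, 3, 1, 7), c(500, 300, 700, 400), "twin")
  cohort <- dplyr::bind_rows(train, as_cohort(list(twin), split = "test"))
  sm <- fit_rsd_seqmatch(cohort, k = 1)
  pred <- predict(sm, cohort, split = "test")
  gt <- true_rsd(twin, pred$sec)
  expect_equal(max(abs(pred$rsd_pred_min - gt)), 0)
})

test_that("sequence matching clamps at zero once elapsed time exceeds every neighbour", {
  train <- as_cohort(list(make_timeline(c(1, 2), c(300, 300), "a")))
  long_q <- make_timeline(c(1, 2), c(600, 1200), "q")
  cohort <- dplyr::bind_rows(train, as_cohort(list(long_q), split = "test"))
  sm <- fit_rsd_seqmatch(cohort, k = 1)
  pred <- predict(sm, cohort, split = "test")
  expect_true(all(pred$rsd_pred_min[pred$sec >= 600] == 0))
  expect_true(all(pred$rsd_pred_min >= 0))
})

test_that("instrument-augmented distance changes neighbour selection", {
  # two histories with identical step sequences but different instruments
  h1 <- make_timeline(c(1, 2), c(300, 300), "h1",
                      instruments = c(1, 2), instr_dur = c(300, 300))
  h2 <- make_timeline(c(1, 2), c(1200, 1200), "h2",
                      instruments = c(3, 4), instr_dur = c(1200, 1200))
  q <- make_timeline(c(1, 2), c(400, 400), "q",
                     instruments = c(3, 4), instr_dur = c(400, 400))
  cohort <- dplyr::bind_rows(
    as_cohort(list(h1, h2)), as_cohort(list(q), split = "test")
  )
  with_instr <- predict(fit_rsd_seqmatch(cohort, k = 1, use_instruments = TRUE),
                        cohort, split = "test")
  # with instruments the query matches h2 (T = 40 min): RSD at t=0 is 40
  expect_equal(with_instr$rsd_pred_min[with_instr$sec == 0], 40)
  expect_error(fit_rsd_seqmatch(cohort, k = 5), "k must be")
})
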