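test_that("trial summary is the two-stage median over included data", {
  # all frames constant 5.0, all included
  m <- dplyr::bind_rows(fake_metrics(rep(100, 14), rep(5, 14), 1),
                        fake_metrics(rep(100, 14), rep(5, 14), 2))
  qc <- dplyr::bind_rows(apply_qc(m[m$elasto_index == 1, ]),
                         apply_qc(m[m$elasto_index == 2, ]))
  out <- trial_summary(m, qc)
  expect_equal(out$trial_swv, 5)
  expect_equal(out$inclusion_pct, 100)
  expect_true(out$valid)

  # row A medians 4.0, row B medians 6.0 -> median of 14 values = 5.0
  m2 <- fake_metrics(rep(100, 14), c(rep(4, 7), rep(6, 7)))
  out2 <- trial_summary(m2, apply_qc(m2))
  expect_equal(out2$trial_swv, 5)

  # every frame discarded -> invalid with a reason
  m3 <- fake_metrics(rep(10, 14))
  out3 <- trial_summary(m3, apply_qc(m3))
  expect_false(out3$valid)
  expect_true(is.na(out3$trial_swv))
  expect_match(out3$reason, "discarded")
  expect_error(trial_summary(m3[0, ], apply_qc(m3)), "empty")
})

test_that("discarded frames contribute nothing to per-square medians", {
  good <- fake_metrics(rep(100, 14), rep(4, 14), 1)
  bad <- fake_metrics(rep(10, 14), rep(9, 14), 2)   # discarded by QC
  m <- dplyr::bind_rows(good, bad)
  qc <- dplyr::bind_rows(apply_qc(good), apply_qc(bad))
  out <- trial_summary(m, qc)
  expect_equal(out$trial_swv, 4)
  expect_equal(out$frames_retained, 1L)
  expect_equal(out$inclusion_pct, 50)
})

test_that("summaries are invariant to frame and row order", {
  set.seed(5)
  frames <- lapply(1:4, function(i)
    fake_metrics(sample(c(30, 60, 100), 14, replace = TRUE),
                 round(runif(14, 3, 7), 2), i))
  m <- dplyr::bind_rows(frames)
  qc <- dplyr::bind_rows(lapply(frames, apply_qc))
  ref <- trial_summary(m, qc)$trial_swv
  perm <- sample(nrow(m))
  expect_equal(trial_summary(m[perm, ], qc[sample(nrow(qc)), ])$trial_swv,
               ref)
})

test_that("repetition collapse takes the median of valid trials", {
  expect_equal(collapse_repetitions(c(4.0, 4.2, 4.4)), 4.2)
  expect_equal(collapse_repetitions(4.1), 4.1)
  expect_equal(collapse_repetitions(c(4.0, NA, 4.4)), 4.2)
  expect_true(is.na(collapse_repetitions(c(NA_real_, NA_real_))))
  expect_equal(collapse_repetitions(c(4.0, 4.2, 4.7), method = "mean"),
               mean(c(4.0, 4.2, 4.7)))
})

test_that("both ratio measures are scale-free and propagate missingness", {
  expect_equal(lt_ratio(4.4, 4.0), 1.1)
  expect_equal(lt_ratio(3.3, 3.3), 1)
  expect_equal(lt_ratio(2 * 4.4, 2 * 4.0), lt_ratio(4.4, 4.0))
  expect_true(is.na(lt_ratio(NA, 4)))

  expect_equal(activation_ratio(6, 4), 1.5)
  expect_equal(activation_ratio(5, 5), 1)
  expect_equal(activation_ratio(6, 4, direction = "baseline_over_task"),
               1 / 1.5)
  expect_true(is.na(activation_ratio(6, NA)))

  c_scale <- 1.37
  expect_equal(activation_ratio(c_scale * 6, c_scale * 4),
               activation_ratio(6, 4))
})

test_that("scaling every decoded value scales trials, not ratios", {
  set.seed(9)
  medians <- round(runif(14, 3.5, 5.5), 3)
  m <- fake_metrics(rep(100, 14), medians)
  base <- trial_summary(m, apply_qc(m))$trial_swv
  c_scale <- 2.5
  m_scaled <- fake_metrics(rep(100, 14), c_scale * medians)
  scaled <- trial_summary(m_scaled, apply_qc(m_scaled))$trial_swv
  expect_equal(scaled, c_scale * base)
  expect_equal(lt_ratio(scaled, c_scale * 4), lt_ratio(base, 4))
})

test_that("cohort table collapses repetitions and attaches both ratios", {
  trials <- tidyr::expand_grid(
    participant_id = c("P1", "P2"), group = "knee_OA",
    muscle = "gastrocnemius_medialis",
    task = c("baseline", "single_leg_stance"),
    orientation = c("longitudinal", "transverse"),
    repetition = 1:3)
  trials <- trials[!(trials$task == "baseline" & trials$repetition > 1), ]
  trials$swv <- ifelse(trials$task == "baseline", 4, 6) +
    ifelse(trials$orientation == "transverse", -0.5, 0)

  q <- tibble::tibble(participant_id = c("P1", "P2"),
                      s6 = c(2, 1), s7 = c(1, 0), tsk = c(25, NA))
  tab <- build_cohort_table(trials, q)
  expect_equal(nrow(tab), 8L)    # 2 participants x 2 tasks x 2 orientations
  sls_long <- tab[tab$task == "single_leg_stance" &
                    tab$orientation == "longitudinal", ]
  expect_equal(unique(sls_long$swv), 6)
  expect_equal(unique(sls_long$lt_ratio), 6 / 5.5)
  expect_equal(unique(sls_long$activation_ratio), 6 / 4)
  expect_equal(tab$perceived_stiffness[tab$participant_id == "P1"][1], 3)
  expect_true(is.na(tab$tsk[tab$participant_id == "P2"][1]))
})

test_that("rank-2 muscles recorded only at stance pool per muscle", {
  trials <- dplyr::bind_rows(
    tidyr::expand_grid(participant_id = "P1", group = "knee_OA",
                       muscle = "gastrocnemius_medialis",
                       task = c("baseline", "lift_shank",
                                "double_leg_stance", "single_leg_stance"),
                       orientation = "longitudinal", repetition = 1L),
    tidyr::expand_grid(participant_id = "P1", group = "knee_OA",
                       muscle = "vastus_lateralis",
                       task = c("double_leg_stance", "single_leg_stance"),
                       orientation = "longitudinal", repetition = 1L))
  trials$swv <- 4.5
  tab <- build_cohort_table(trials)
  expect_equal(sum(tab$muscle == "gastrocnemius_medialis"), 4L)
  expect_equal(sum(tab$muscle == "vastus_lateralis"), 2L)
  expect_setequal(tab$task[tab$muscle == "vastus_lateralis"],
                  c("double_leg_stance", "single_leg_stance"))
})

test_that("duplicate trial keys are rejected with the offenders listed", {
  trials <- tibble::tibble(
    participant_id = "P1", group = "knee_OA",
    muscle = "gastrocnemius_medialis", task = "baseline",
    orientation = "longitudinal", repetition = c(1L, 1L), swv = c(4, 5))
  expect_error(build_cohort_table(trials), "duplicate.*P1")
})

test_that("noise-free cohorts are recovered exactly by the collapse", {
  tab <- simulate_cohort(cohort_spec(within_subject_sd = 0, seed = 21L))
  cohort <- build_cohort_table(tab[c("participant_id", "group", "muscle",
                                     "task", "orientation", "repetition",
                                     "swv")])
  joined <- dplyr::distinct(tab, participant_id, group, muscle, task,
                            orientation, true_value)
  m <- dplyr::left_join(cohort, joined,
                        by = c("participant_id", "group", "muscle",
                               "task", "orientation"))
  expect_equal(m$swv, m$true_value)
})
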