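test_that("simulators are pure functions of profile and seed", {
  prof <- group_profile("control")
  trial <- build_ghgt_protocol(arena_config(), seed = 1)$trials[[1]]
  expect_identical(serialize(simulate_nav_agent(prof, trial, seed = 9), NULL),
                   serialize(simulate_nav_agent(prof, trial, seed = 9), NULL))
  pp <- panel_profile(pattern = "mixed")
  expect_identical(simulate_expert_panel(pp, 3, seed = 4),
                   simulate_expert_panel(pp, 3, seed = 4))
  mp <- build_mrt_protocol(seed = 2)
  expect_identical(simulate_mrt_responses(prof, mp, seed = 5),
                   simulate_mrt_responses(prof, mp, seed = 5))
  cp <- build_corsi_protocol(seed = 2)
  expect_identical(simulate_corsi_responses(prof, cp, seed = 6),
                   simulate_corsi_responses(prof, cp, seed = 6))
  profs <- list(group_profile("a"), group_profile("b"))
  expect_identical(simulate_likert_cohort(profs, 5, seed = 7),
                   simulate_likert_cohort(profs, 5, seed = 7))
})

test_that("panel patterns force the downstream agreement indices", {
  top <- simulate_expert_panel(panel_profile(pattern = "unanimous_top"),
                               items = 2, seed = 1)
  expect_true(all(top == 4))
  cv <- content_validity(top)
  expect_equal(cv$aiken_v, c(1, 1))
  expect_equal(cv$kappa_star, c(1, 1))

  down <- simulate_expert_panel(panel_profile(pattern = "one_step_down"),
                                items = 2, seed = 1)
  expect_equal(aiken_v(down[, 1]), 23 / 24)
  expect_equal(sum(down == 3), 2)  # one rater, one step, both items
})

test_that("a noiseless direct agent walks straight to the goal with no flags", {
  prof <- group_profile(nav_noise_sd = 0, nav_path_wobble = 1)
  trial <- build_ghgt_protocol(arena_config(), seed = 3)$trials[[1]]
  resp <- simulate_nav_agent(prof, trial, seed = 1)
  s <- score_nav_trial(trial, resp)
  expect_equal(s$distance_error, 0, tolerance = 1e-9)
  expect_equal(s$efficiency, 1, tolerance = 1e-6)
  expect_length(detect_nav_anomalies(trial, resp)$flags, 0)
})

test_that("final-response scatter matches the isotropic closed form", {
  prof <- group_profile(nav_noise_sd = 0.1, nav_path_wobble = 1)
  trial <- build_ghgt_protocol(arena_config(), seed = 5)$trials[[1]]
  errs <- vapply(1:4000, function(i) {
    r <- simulate_nav_agent(prof, trial, seed = i)
    score_nav_trial(trial, r)$distance_error
  }, numeric(1))
  # 2-D isotropic scatter: mean radial error is sd * sqrt(pi / 2)
  expect_equal(mean(errs), 0.1 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("path wobble inflates path length as constructed and trips LONG_PATH", {
  trial <- build_ghgt_protocol(arena_config(), seed = 7)$trials[[1]]
  prof <- group_profile(nav_noise_sd = 0, nav_path_wobble = 4)
  flagged <- vapply(1:20, function(i) {
    resp <- simulate_nav_agent(prof, trial, seed = i)
    s <- score_nav_trial(trial, resp)
    expect_equal(s$path_length / s$ideal_length, 4, tolerance = 1e-6)
    "LONG_PATH" %in% detect_nav_anomalies(trial, resp)$flags
  }, logical(1))
  expect_true(all(flagged))
})

test_that("mental-rotation accuracy map is recovered, including angle ordering", {
  prof <- group_profile(mrt_accuracy_by_angle = c("0" = 0.95, "90" = 0.80,
                                                  "180" = 0.65))
  p <- build_mrt_protocol(seed = 31, trials_per_condition = 2000)
  acc <- score_mrt(p, simulate_mrt_responses(prof, p, seed = 32))$by_condition
  expect_equal(acc$accuracy, c(0.95, 0.80, 0.65), tolerance = 0.05)
  expect_true(all(diff(acc$accuracy) < 0))
  # perfect profile saturates
  perfect <- group_profile(mrt_accuracy_by_angle = c("0" = 1, "90" = 1,
                                                     "180" = 1))
  p2 <- build_mrt_protocol(seed = 33)
  expect_equal(score_mrt(p2, simulate_mrt_responses(perfect, p2, seed = 1))$
                 overall$accuracy, 1)
})

test_that("Corsi span parameters are recovered from simulated sessions", {
  p <- build_corsi_protocol(seed = 41)
  ceiling_prof <- group_profile(corsi_span_mean = 9, corsi_span_sd = 0)
  ceiling_spans <- vapply(1:50, function(i) {
    run_corsi_session(p, simulate_corsi_responses(ceiling_prof, p, seed = i,
                                                  backward_penalty = 0))$span_forward
  }, numeric(1))
  expect_equal(stats::median(ceiling_spans), 9)

  prof <- group_profile(corsi_span_mean = 4, corsi_span_sd = 0.5)
  spans <- vapply(1:300, function(i) {
    resp <- simulate_corsi_responses(prof, p, seed = i)
    res <- run_corsi_session(p, resp)
    c(res$span_forward, res$span_backward)
  }, numeric(2))
  expect_equal(mean(spans[1, ]), 4, tolerance = 0.3)
  # backward block simulated one unit lower
  expect_lt(mean(spans[2, ]), mean(spans[1, ]))
})

test_that("latent-shift cohorts: null pairs are small, a shifted group dominates", {
  null_profs <- lapply(c("a", "b", "c"), group_profile)
  coh <- simulate_likert_cohort(null_profs, n_per_group = 60, seed = 51)
  s <- score_csuq(coh)
  con <- summarize_groups(s, score_cols = "overall_pct",
                          ci_method = "normal")$contrasts
  expect_true(all(con$magnitude < 0.25))  # single-draw sanity bound

  shifted <- simulate_likert_cohort(
    list(group_profile("ok"), group_profile("low",
                                            latent_usability_shift = -3)),
    n_per_group = 30, seed = 52)
  s2 <- score_csuq(shifted)
  r <- rank_biserial(s2$overall_pct[s2$group == "ok"],
                     s2$overall_pct[s2$group == "low"])
  expect_gt(r$estimate, 0.95)  # near-separation limit

  expect_error(
    simulate_likert_cohort(null_profs, 10, thresholds = c(0, -1), seed = 1),
    "strictly increasing"
  )
})
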