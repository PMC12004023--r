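make_csuq_rows <- function(values) {
  # one respondent per row of `values` (a list of 15-vectors)
  tab <- data.frame(respondent_id = sprintf("r%02d", seq_along(values)),
                    group = "control", stringsAsFactors = FALSE)
  items <- do.call(rbind, values)
  colnames(items) <- paste0("item_", 1:15)
  cbind(tab, items)
}

test_that("usability factor scores hit the anchors under both percent rules", {
  resp <- make_csuq_rows(list(rep(7, 15), rep(1, 15),
                              rep(c(1, 7), length.out = 15)))
  s <- score_csuq(resp)  # default (mean - 1)/6 rule
  expect_equal(unname(unlist(s[1, c("system_usefulness_pct",
                                    "information_quality_pct",
                                    "interface_quality_pct",
                                    "overall_pct")])),
               rep(100, 4))
  expect_equal(s$overall_pct[2], 0)
  sp <- score_csuq(resp, transform = "proportional")
  expect_equal(sp$overall_pct[2], 1 / 7 * 100)
  # alternating 1/7 over six items averages 4 -> midpoint of the scale
  expect_equal(s$system_usefulness_pct[3], 50)
})

test_that("percent rules are monotone so raw and percent orderings agree", {
  set.seed(20)
  resp <- make_csuq_rows(replicate(10, sample(1:7, 15, replace = TRUE),
                                   simplify = FALSE))
  s <- score_csuq(resp)
  expect_equal(order(s$overall_raw), order(s$overall_pct))
  sp <- score_csuq(resp, transform = "proportional")
  expect_equal(order(sp$overall_raw), order(sp$overall_pct))
})

test_that("factors with most items missing score NA, never zero", {
  rows <- make_csuq_rows(list(rep(7, 15)))
  rows[paste0("item_", 13:15)] <- NA  # whole interface-quality factor gone
  s <- score_csuq(rows)
  expect_true(is.na(s$interface_quality_raw))
  expect_false(is.na(s$system_usefulness_raw))
  # half or more present: mean over observed
  rows2 <- make_csuq_rows(list(rep(6, 15)))
  rows2["item_13"] <- NA
  s2 <- score_csuq(rows2)
  expect_equal(s2$interface_quality_raw, 6)
})

test_that("ergonomics criterion scores use the score/7 percent anchor", {
  resp <- data.frame(
    respondent_id = "e1", rater_class = "expert", round = 1,
    criterion = rep(c("compatibility", "orientation"), each = 3),
    rating = c(7, 7, 7, 5, 5, 6)
  )
  s <- score_ergonomics(resp)
  expect_equal(s$compatibility_raw, 7)
  expect_equal(s$compatibility_pct, 100)
  expect_equal(s$orientation_raw, 16 / 3, tolerance = 1e-12)
  expect_equal(s$orientation_pct, 16 / 3 / 7 * 100, tolerance = 1e-12)
  expect_gt(s$orientation_pct, 75)  # 5.33 exceeds the 75% threshold
  # the threshold anchor itself: a criterion mean of 5.25 is exactly 75%
  expect_equal(5.25 / 7 * 100, 75)
  expect_error(
    score_ergonomics(data.frame(respondent_id = "e1", rater_class = "x",
                                round = 1, criterion = "sparkle", rating = 5)),
    "unknown ergonomic criteria"
  )
})

test_that("group summaries: medians, IQRs, and contrast degeneracies", {
  set.seed(31)
  vals <- replicate(20, sample(4:7, 15, replace = TRUE), simplify = FALSE)
  resp <- make_csuq_rows(vals)
  resp$group <- rep(c("g1", "g2"), each = 10)
  resp[resp$group == "g2", paste0("item_", 1:15)] <-
    resp[resp$group == "g1", paste0("item_", 1:15)]  # identical groups
  s <- score_csuq(resp)
  summ <- summarize_groups(s, n_boot = 200, seed = 2)
  expect_equal(summ$contrasts$r_rb, rep(0, nrow(summ$contrasts)))

  # a constant group has zero IQR
  resp2 <- make_csuq_rows(replicate(6, rep(6, 15), simplify = FALSE))
  resp2$group <- rep(c("flat", "flat", "flat", "vary", "vary", "vary"))
  resp2[4:6, "item_1"] <- c(1, 4, 7)
  s2 <- score_csuq(resp2)
  summ2 <- summarize_groups(s2, score_cols = "overall_pct",
                            n_boot = 200, seed = 2)
  expect_equal(summ2$summary$iqr[summ2$summary$group == "flat"], 0)

  # single group: summaries only
  s3 <- s2[s2$group == "flat", ]
  expect_null(summarize_groups(s3, score_cols = "overall_pct")$contrasts)
})

test_that("a lowered latent group produces the largest contrasts, flagged as focus", {
  profs <- list(group_profile("control"), group_profile("carrier"),
                group_profile("mci", latent_usability_shift = -1))
  cohort <- simulate_likert_cohort(profs, n_per_group = 40, seed = 77)
  s <- score_csuq(cohort)
  summ <- summarize_groups(s, score_cols = "overall_pct", focus_group = "mci",
                           n_boot = 200, seed = 3)
  con <- summ$contrasts
  mci_rows <- con$group_a == "mci" | con$group_b == "mci"
  expect_true(min(con$magnitude[mci_rows]) > max(con$magnitude[!mci_rows]))
  expect_true(all(con$focus_contrast[mci_rows]))
  # direction: mci scores lower
  mci_med <- summ$summary$median[summ$summary$group == "mci"]
  expect_true(all(mci_med < summ$summary$median[summ$summary$group != "mci"]))
})
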