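#' Default factor map for the 15-item usability questionnaire
#'
#' The videogame adaptation of the Computer System Usability Questionnaire
#' keeps the classic three-factor structure; by convention items 1-6 load
#' on system usefulness, 7-12 on information quality, and 13-15 on
#' interface quality, with the overall score over all 15 items. The map is
#' an argument everywhere it is used, so an instrument with a different
#' item assignment just supplies its own list.
#'
#' @return Named list of integer item-index vectors.
#' @export
csuq_factor_map <- function() {
  list(system_usefulness = 1:6,
       information_quality = 7:12,
       interface_quality = 13:15)
}

validate_factor_map <- function(map, n_items = 15L) {
  all_items <- sort(unlist(map, use.names = FALSE))
  if (anyDuplicated(all_items)) {
    stop_navcog("factor map assigns an item to more than one factor",
                class = "navcog_validation_error")
  }
  if (!identical(as.integer(all_items), seq_len(n_items))) {
    stop_navcog("factor map must cover items 1..", n_items, " exactly",
                class = "navcog_validation_error")
  }
  invisible(map)
}

# Mean over observed items if at least half are present, else NA.
masked_mean <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) * 2L < length(x)) return(NA_real_)
  mean(obs)
}

percent_transform <- function(raw_mean, rule = c("shifted", "proportional")) {
  rule <- match.arg(rule)
  switch(rule,
         shifted = (raw_mean - 1) / 6 * 100,
         proportional = raw_mean / 7 * 100)
}

#' Score usability questionnaire responses
#'
#' Computes, per respondent, the three factor scores and the overall score,
#' each as the raw mean on the 1-7 scale and as a percent-of-maximum.
#' Two percent rules are supported: `"shifted"` maps the scale anchors to
#' 0 and 100 via `(mean - 1) / 6 * 100` (the default), `"proportional"`
#' uses `mean / 7 * 100`. Factors whose items are more than half missing
#' score `NA`, never zero.
#'
#' @param responses Data frame with `respondent_id`, `group`, and columns
#'   `item_1` .. `item_15` holding integers 1-7 (NA for masked items).
#' @param map Factor map as from [csuq_factor_map()].
#' @param transform Percent rule, `"shifted"` or `"proportional"`.
#' @return Data frame of class `questionnaire_scores`: one row per
#'   respondent with `<factor>_raw` and `<factor>_pct` columns plus
#'   `overall_raw` / `overall_pct`.
#' @export
score_csuq <- function(responses, map = csuq_factor_map(),
                       transform = c("shifted", "proportional")) {
  transform <- match.arg(transform)
  validate_factor_map(map, 15L)
  item_cols <- paste0("item_", 1:15)
  if (!all(item_cols %in% names(responses))) {
    stop_navcog("responses must carry columns item_1 .. item_15",
                class = "navcog_validation_error")
  }
  items <- as.matrix(responses[, item_cols])
  if (any(items < 1 | items > 7, na.rm = TRUE)) {
    stop_navcog("usability ratings must lie in 1..7",
                class = "navcog_validation_error")
  }
  out <- data.frame(respondent_id = responses$respondent_id,
                    group = responses$group %||% NA_character_,
                    stringsAsFactors = FALSE)
  scales <- c(map, list(overall = 1:15))
  for (f in names(scales)) {
    raw <- apply(items[, scales[[f]], drop = FALSE], 1, masked_mean)
    out[[paste0(f, "_raw")]] <- raw
    out[[paste0(f, "_pct")]] <- percent_transform(raw, transform)
  }
  attr(out, "transform") <- transform
  class(out) <- c("questionnaire_scores", "data.frame")
  out
}

#' Default digital-ergonomics criteria labels
#'
#' Eight interface-design heuristics rated on 7-point scales: the seven
#' reported comparison criteria plus error management.
#'
#' @return Character vector of criterion labels.
#' @export
ergonomics_criteria <- function() {
  c("compatibility", "orientation", "load", "adaptability", "consistency",
    "codes_significance", "control", "error_management")
}

#' Score digital-ergonomics questionnaire responses
#'
#' Each criterion's score is the mean of its related items on the 1-7
#' scale; the percent scale is `score / 7 * 100`, so a score of 5.25 is
#' exactly 75%.
#'
#' @param responses Long-format data frame with columns `respondent_id`,
#'   `rater_class`, `round`, `criterion`, `rating` (one row per item
#'   response).
#' @param criteria Allowed criterion labels.
#' @return Data frame of class `questionnaire_scores`: one row per
#'   respondent x round with `<criterion>_raw` / `<criterion>_pct` columns.
#' @export
score_ergonomics <- function(responses, criteria = ergonomics_criteria()) {
  needed <- c("respondent_id", "criterion", "rating")
  if (!all(needed %in% names(responses))) {
    stop_navcog("responses must carry respondent_id, criterion, rating",
                class = "navcog_validation_error")
  }
  unknown <- setdiff(unique(responses$criterion), criteria)
  if (length(unknown) > 0) {
    stop_navcog("unknown ergonomic criteria: ",
                paste(unknown, collapse = ", "),
                class = "navcog_validation_error")
  }
  if (any(responses$rating < 1 | responses$rating > 7, na.rm = TRUE)) {
    stop_navcog("ergonomics ratings must lie in 1..7",
                class = "navcog_validation_error")
  }
  responses$round <- responses$round %||% 1L
  responses$rater_class <- responses$rater_class %||% NA_character_
  key <- interaction(responses$respondent_id, responses$round, drop = TRUE)
  rows <- lapply(split(responses, key), function(d) {
    out <- data.frame(respondent_id = d$respondent_id[1],
                      rater_class = d$rater_class[1],
                      round = d$round[1],
                      stringsAsFactors = FALSE)
    for (cr in intersect(criteria, unique(d$criterion))) {
      sc <- mean(d$rating[d$criterion == cr], na.rm = TRUE)
      out[[paste0(cr, "_raw")]] <- sc
      out[[paste0(cr, "_pct")]] <- sc / 7 * 100
    }
    out
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("questionnaire_scores", "data.frame")
  out
}

#' Summarize questionnaire scores by group with pairwise effect sizes
#'
#' Produces the median (IQR) table per group for each score column and,
#' when at least two groups are present, the pairwise unsigned
#' rank-biserial contrast for every score with a confidence interval,
#' labelling explicitly which contrasts involve the group named in
#' `focus_group` (e.g. the MCI group versus every other group).
#'
#' @param scores A `questionnaire_scores` data frame (or any data frame).
#' @param group_col Name of the grouping column.
#' @param score_cols Score columns to summarize; defaults to every
#'   `_pct` column.
#' @param focus_group Optional group label to flag in the contrast table.
#' @param confidence Confidence level for contrast intervals.
#' @param ci_method Interval method passed to [rank_biserial_ci()].
#' @param n_boot,seed Bootstrap controls for the interval.
#' @return A list of class `group_summary` with `summary` (one row per
#'   group x score: `median`, `iqr`, `n`) and `contrasts` (NULL with a
#'   single group).
#' @export
summarize_groups <- function(scores, group_col = "group",
                             score_cols = NULL, focus_group = NULL,
                             confidence = 0.95,
                             ci_method = c("bootstrap", "normal"),
                             n_boot = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (!group_col %in% names(scores)) {
    stop_navcog("grouping column `", group_col, "` not found",
                class = "navcog_validation_error")
  }
  if (is.null(score_cols)) {
    score_cols <- grep("_pct$", names(scores), value = TRUE)
  }
  groups <- unique(as.character(scores[[group_col]]))
  summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- scores[scores[[group_col]] == g, , drop = FALSE]
    do.call(rbind, lapply(score_cols, function(sc) {
      v <- sub[[sc]][!is.na(sub[[sc]])]
      data.frame(group = g, score = sc, n = length(v),
                 median = stats::median(v),
                 iqr = unname(stats::quantile(v, 0.75) - stats::quantile(v, 0.25)),
                 stringsAsFactors = FALSE)
    }))
  }))
  contrasts <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    contrasts <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(score_cols, function(sc) {
        a <- scores[[sc]][scores[[group_col]] == pr[1]]
        b <- scores[[sc]][scores[[group_col]] == pr[2]]
        a <- a[!is.na(a)]
        b <- b[!is.na(b)]
        es <- rank_biserial(a, b)
        ci <- rank_biserial_ci(a, b, confidence, method = ci_method,
                               n_boot = n_boot, seed = seed)
        data.frame(group_a = pr[1], group_b = pr[2], score = sc,
                   r_rb = es$estimate, magnitude = es$magnitude,
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   focus_contrast = !is.null(focus_group) &&
                     focus_group %in% pr,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(contrasts) <- NULL
  }
  structure(list(summary = summary, contrasts = contrasts,
                 focus_group = focus_group),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summaries: median (IQR)\n")
  disp <- x$summary
  disp$`median (IQR)` <- sprintf("%.1f (%.1f)", disp$median, disp$iqr)
  print(disp[, c("group", "score", "n", "median (IQR)")], row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise rank-biserial contrasts",
        if (!is.null(x$focus_group)) paste0(" (focus: ", x$focus_group, ")"),
        "\n", sep = "")
    disp2 <- x$contrasts
    disp2$`|r_rb| (CI)` <- sprintf("%.2f (%.2f to %.2f)",
                                   disp2$magnitude, disp2$lower, disp2$upper)
    print(disp2[, c("group_a", "group_b", "score", "|r_rb| (CI)",
                    "focus_contrast")],
          row.names = FALSE)
  }
  invisible(x)
}
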