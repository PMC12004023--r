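#' Ability profile of a simulated participant group
#'
#' Ground-truth parameters for the cohort simulator: navigation scatter and
#' path wobble, mental-rotation accuracy by angular condition, Corsi span
#' distribution, and a latent shift governing questionnaire responses. The
#' defaults are illustrative fixtures for pipeline testing; they are not
#' estimates from any clinical cohort (no trial-level data is published for
#' the populations they are named after).
#'
#' @param group Group label.
#' @param nav_noise_sd Isotropic scatter (length units) of the final
#'   navigation response around the goal.
#' @param nav_path_wobble Excess-path factor >= 1; 1 walks straight.
#' @param mrt_accuracy_by_angle Named probabilities for conditions
#'   `"0"`, `"90"`, `"180"`.
#' @param corsi_span_mean,corsi_span_sd Latent span distribution.
#' @param latent_usability_shift Shift (latent SD units) of questionnaire
#'   responses; negative means lower perceived usability.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group = "control",
                          nav_noise_sd = 0.05,
                          nav_path_wobble = 1.1,
                          mrt_accuracy_by_angle = c("0" = 0.95, "90" = 0.85,
                                                    "180" = 0.70),
                          corsi_span_mean = 6,
                          corsi_span_sd = 1,
                          latent_usability_shift = 0) {
  assert_scalar_number(nav_noise_sd, "nav_noise_sd", lower = 0)
  assert_scalar_number(nav_path_wobble, "nav_path_wobble", lower = 1)
  if (any(mrt_accuracy_by_angle < 0 | mrt_accuracy_by_angle > 1)) {
    stop_navcog("accuracies must be probabilities",
                class = "navcog_validation_error")
  }
  assert_scalar_number(corsi_span_sd, "corsi_span_sd", lower = 0)
  structure(list(group = group, nav_noise_sd = nav_noise_sd,
                 nav_path_wobble = nav_path_wobble,
                 mrt_accuracy_by_angle = mrt_accuracy_by_angle,
                 corsi_span_mean = corsi_span_mean,
                 corsi_span_sd = corsi_span_sd,
                 latent_usability_shift = latent_usability_shift),
            class = "group_profile")
}

#' Expert panel profile for simulated rating matrices
#'
#' @param n_raters Panel size (>= 2).
#' @param n_categories Ordinal categories of the rating scale.
#' @param category_floor Lowest category value.
#' @param pattern `"unanimous_top"` (every rater gives the top category),
#'   `"one_step_down"` (as unanimous, except one rater rates designated
#'   items one category lower), or `"mixed"` (ratings drawn from
#'   `mixed_probs`).
#' @param mixed_probs Category probabilities for the `"mixed"` pattern.
#' @return An object of class `panel_profile`.
#' @export
panel_profile <- function(n_raters = 8L, n_categories = 4L,
                          category_floor = 1L,
                          pattern = c("unanimous_top", "one_step_down",
                                      "mixed"),
                          mixed_probs = NULL) {
  pattern <- match.arg(pattern)
  n_raters <- assert_count(n_raters, "n_raters", lower = 2L)
  n_categories <- assert_count(n_categories, "n_categories", lower = 2L)
  if (pattern == "mixed") {
    if (is.null(mixed_probs)) mixed_probs <- rep(1 / n_categories, n_categories)
    if (length(mixed_probs) != n_categories || any(mixed_probs < 0)) {
      stop_navcog("mixed_probs must be ", n_categories,
                  " non-negative weights", class = "navcog_validation_error")
    }
  }
  structure(list(n_raters = n_raters, n_categories = n_categories,
                 category_floor = category_floor, pattern = pattern,
                 mixed_probs = mixed_probs),
            class = "panel_profile")
}

#' Simulate an expert rating panel
#'
#' @param profile A [panel_profile()].
#' @param items Item labels (character) or item count.
#' @param seed Integer seed.
#' @param step_down_items For the `"one_step_down"` pattern, which items
#'   (indices) the deviating rater scores one category lower; defaults to
#'   all items.
#' @param dimension,round Passed through to [rating_matrix()].
#' @return A [rating_matrix()].
#' @export
#' @examples
#' m <- simulate_expert_panel(panel_profile(pattern = "one_step_down"),
#'                            items = "task_relevance", seed = 1)
#' aiken_v(m[, 1])  # 23/24
simulate_expert_panel <- function(profile, items, seed,
                                  step_down_items = NULL,
                                  dimension = "relevance", round = 1L) {
  stopifnot(inherits(profile, "panel_profile"))
  if (is.numeric(items)) items <- paste0("item_", seq_len(items))
  n_items <- length(items)
  top <- profile$category_floor + profile$n_categories - 1L
  m <- with_seed(seed, {
    switch(profile$pattern,
      unanimous_top = matrix(top, profile$n_raters, n_items),
      one_step_down = {
        m <- matrix(top, profile$n_raters, n_items)
        down <- step_down_items %||% seq_len(n_items)
        deviating <- sample.int(profile$n_raters, 1L)
        m[deviating, down] <- top - 1L
        m
      },
      mixed = matrix(
        sample(profile$category_floor + seq_len(profile$n_categories) - 1L,
               profile$n_raters * n_items, replace = TRUE,
               prob = profile$mixed_probs),
        profile$n_raters, n_items)
    )
  })
  dimnames(m) <- list(paste0("rater_", seq_len(profile$n_raters)), items)
  rating_matrix(m, profile$n_categories, profile$category_floor,
                dimension = dimension, round = round)
}

#' Simulate a navigation agent's trajectory for one trial
#'
#' The agent walks from the trial start toward a noisy estimate of the goal
#' (isotropic Gaussian scatter with SD `nav_noise_sd`). Path wobble is
#' produced by a perpendicular zig-zag whose amplitude is chosen so the
#' generated path length is `nav_path_wobble` times the straight-line
#' distance. Sampling is piecewise linear at a nominal 10 samples/second;
#' timing carries no semantic load in scoring.
#'
#' @param profile A [group_profile()].
#' @param trial A trial from [build_ghgt_protocol()].
#' @param seed Integer seed.
#' @param speed Nominal walking speed (length units per second).
#' @return A [nav_response()].
#' @export
simulate_nav_agent <- function(profile, trial, seed, speed = 0.5) {
  stopifnot(inherits(profile, "group_profile"))
  with_seed(seed, {
    target <- trial$goal + stats::rnorm(2, 0, profile$nav_noise_sd)
    d <- vnorm(target - trial$start)
    w <- profile$nav_path_wobble
    n_teeth <- 4L
    pts <- if (d < 1e-12 || w <= 1 + 1e-12) {
      rbind(trial$start, target)
    } else {
      # 2*n_teeth equal segments; amplitude a makes total length w*d exactly
      a <- d * sqrt(w^2 - 1) / (2 * n_teeth)
      dir <- (target - trial$start) / d
      perp <- c(-dir[2], dir[1])
      k <- seq_len(2L * n_teeth - 1L)
      mids <- t(sapply(k, function(i) {
        trial$start + dir * (d * i / (2 * n_teeth)) +
          perp * a * (i %% 2L)
      }))
      rbind(trial$start, mids, target)
    }
    seg <- diff(pts)
    lens <- sqrt(rowSums(seg^2))
    times <- c(0, cumsum(lens) / speed)
    # resample to ~10 Hz along the piecewise-linear path, keeping the
    # zig-zag vertices so the generated path length is preserved exactly
    t_grid <- sort(unique(c(seq(0, max(times), by = 0.1), times)))
    x <- stats::approx(times, pts[, 1], xout = t_grid)$y
    y <- stats::approx(times, pts[, 2], xout = t_grid)$y
    nav_response(t_grid, cbind(x, y))
  })
}

#' Simulate forced-choice mental-rotation responses
#'
#' Each trial is answered correctly with the profile's per-condition
#' probability; errors pick uniformly among the three foil slots. Reaction
#' times are lognormal with a condition-dependent location (slower at
#' larger angles).
#'
#' @param profile A [group_profile()].
#' @param protocol An `mrt_protocol`.
#' @param seed Integer seed.
#' @return Data frame with `chosen_index` and `rt`, one row per trial.
#' @export
simulate_mrt_responses <- function(profile, protocol, seed) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(protocol, "mrt_protocol"))
  tab <- protocol$trials
  acc <- profile$mrt_accuracy_by_angle
  with_seed(seed, {
    p <- acc[as.character(tab$condition)]
    if (anyNA(p)) {
      stop_navcog("profile lacks an accuracy for some condition",
                  class = "navcog_validation_error")
    }
    hit <- stats::runif(nrow(tab)) < p
    chosen <- integer(nrow(tab))
    chosen[hit] <- tab$correct_index[hit]
    if (any(!hit)) {
      chosen[!hit] <- vapply(which(!hit), function(i) {
        sample(setdiff(0:3, tab$correct_index[i]), 1L)
      }, integer(1))
    }
    rt <- stats::rlnorm(nrow(tab),
                        meanlog = log(1.2) + tab$condition / 180 * 0.4,
                        sdlog = 0.3)
    data.frame(chosen_index = chosen, rt = rt)
  })
}

#' Simulate Corsi block-tapping responses
#'
#' A latent span is drawn per participant from
#' `Normal(corsi_span_mean, corsi_span_sd)` (backward trials use a span
#' lowered by `backward_penalty`). A trial of length `L` is answered
#' correctly with probability `pnorm((span - L + 0.5) / slope)`; incorrect
#' responses perturb one element of the expected sequence, so they never
#' match it.
#'
#' @param profile A [group_profile()].
#' @param protocol A `corsi_protocol`.
#' @param seed Integer seed.
#' @param slope Softness of the latent-span link (larger = noisier).
#' @param backward_penalty Span decrement for the backward block.
#' @return List with `$forward` and `$backward` response lists, suitable
#'   for [run_corsi_session()].
#' @export
simulate_corsi_responses <- function(profile, protocol, seed, slope = 0.5,
                                     backward_penalty = 1) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(protocol, "corsi_protocol"))
  with_seed(seed, {
    span <- stats::rnorm(1, profile$corsi_span_mean, profile$corsi_span_sd)
    answer_block <- function(trials, span_eff) {
      lapply(trials, function(tr) {
        expected <- as.integer(tr$expected_response)
        ok <- stats::runif(1) < stats::pnorm((span_eff - tr$length + 0.5) / slope)
        if (ok) {
          expected
        } else {
          i <- sample.int(length(expected), 1L)
          wrong <- expected
          wrong[i] <- sample(setdiff(1:9, expected[i]), 1L)
          wrong
        }
      })
    }
    list(forward = answer_block(protocol$forward, span),
         backward = answer_block(protocol$backward, span - backward_penalty))
  })
}

#' Simulate ordinal questionnaire responses for several groups
#'
#' Latent-threshold responder model: each rating discretizes a latent
#' `Normal(shift_group, 1)` draw through shared, strictly increasing
#' cutpoints (6 cutpoints for a 7-point scale). A positive group shift
#' pushes ratings toward the top of the scale.
#'
#' @param groups List of [group_profile()] objects.
#' @param n_per_group Respondents per group (scalar or one per group).
#' @param n_items Items per respondent.
#' @param thresholds Strictly increasing latent cutpoints, length
#'   `n_categories - 1`.
#' @param seed Integer seed.
#' @param n_categories Ordinal categories of the response scale.
#' @return Data frame with `respondent_id`, `group`, and `item_1..item_k`
#'   columns (wide format, compatible with [score_csuq()] when
#'   `n_items = 15`).
#' @export
simulate_likert_cohort <- function(groups, n_per_group, n_items = 15L,
                                   thresholds = NULL, seed = 1L,
                                   n_categories = 7L) {
  n_categories <- assert_count(n_categories, "n_categories", lower = 2L)
  if (is.null(thresholds)) {
    # anchored so an unshifted responder uses the upper half of the scale,
    # as usability data typically does
    thresholds <- stats::qnorm(seq_len(n_categories - 1L) / n_categories) - 1
  }
  if (length(thresholds) != n_categories - 1L || any(diff(thresholds) <= 0)) {
    stop_navcog("thresholds must be ", n_categories - 1L,
                " strictly increasing cutpoints",
                class = "navcog_validation_error")
  }
  if (length(n_per_group) == 1L) {
    n_per_group <- rep(n_per_group, length(groups))
  }
  stopifnot(length(n_per_group) == length(groups))
  with_seed(seed, {
    rows <- list()
    rid <- 0L
    for (gi in seq_along(groups)) {
      prof <- groups[[gi]]
      stopifnot(inherits(prof, "group_profile"))
      for (r in seq_len(n_per_group[gi])) {
        rid <- rid + 1L
        latent <- stats::rnorm(n_items, prof$latent_usability_shift, 1)
        rating <- findInterval(latent, thresholds) + 1L
        row <- as.list(rating)
        names(row) <- paste0("item_", seq_len(n_items))
        rows[[rid]] <- c(list(respondent_id = sprintf("resp_%04d", rid),
                              group = prof$group), row)
      }
    }
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  })
}
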