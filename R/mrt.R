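#' Build a mental-rotation task protocol
#'
#' The task presents a target stimulus to be mentally rotated by the trial's
#' angular condition (0, 90, or 180 degrees) and answered by a forced choice
#' among 4 options. When the original stimulus order is available as a
#' fixture table it is reproduced verbatim; otherwise a deterministic,
#' seeded default order is generated in which the position of the correct
#' option is balanced across the four answer slots (each slot correct
#' exactly `trials_per_condition / 4` times per condition).
#'
#' @param seed Integer seed for the default generation path.
#' @param order_fixture Optional data frame (or CSV path) with columns
#'   `condition, trial, stimulus_id, opt1, opt2, opt3, opt4, correct_index`
#'   carrying a fixed trial order.
#' @param trials_per_condition Trials per angular condition; must be a
#'   multiple of 4 so slot balance is possible.
#' @param conditions Rotation angles (degrees) defining the conditions.
#' @return An object of class `mrt_protocol` wrapping a trial table.
#' @export
#' @examples
#' p <- build_mrt_protocol(seed = 3)
#' table(p$trials$condition)
build_mrt_protocol <- function(seed = 1L, order_fixture = NULL,
                               trials_per_condition = 16L,
                               conditions = c(0, 90, 180)) {
  if (!is.null(order_fixture)) {
    tab <- if (is.character(order_fixture)) {
      read_mrt_fixture(order_fixture)
    } else {
      validate_mrt_table(as.data.frame(order_fixture))
    }
    return(structure(list(trials = tab, source = "fixture", seed = NULL),
                     class = "mrt_protocol"))
  }
  seed <- assert_count(seed, "seed")
  trials_per_condition <- assert_count(trials_per_condition,
                                       "trials_per_condition", lower = 4L)
  if (trials_per_condition %% 4L != 0L) {
    stop_navcog("trials_per_condition must be a multiple of 4 for slot balance",
                class = "navcog_validation_error")
  }
  pool <- sprintf("stim_%02d", seq_len(max(16L, trials_per_condition)))
  tab <- with_seed(seed, {
    do.call(rbind, lapply(conditions, function(cond) {
      correct <- sample(rep(0:3, trials_per_condition / 4L))
      stim <- sample(pool, trials_per_condition)
      opts <- t(vapply(seq_len(trials_per_condition), function(i) {
        foils <- sample(setdiff(pool, stim[i]), 3L)
        slots <- character(4)
        slots[correct[i] + 1L] <- stim[i]
        slots[slots == ""] <- foils
        slots
      }, character(4)))
      data.frame(condition = cond,
                 trial = seq_len(trials_per_condition) - 1L,
                 stimulus_id = stim,
                 opt1 = opts[, 1], opt2 = opts[, 2],
                 opt3 = opts[, 3], opt4 = opts[, 4],
                 correct_index = correct,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(tab) <- NULL
  structure(list(trials = validate_mrt_table(tab), source = "generated",
                 seed = seed),
            class = "mrt_protocol")
}

mrt_fixture_cols <- c("condition", "trial", "stimulus_id",
                      "opt1", "opt2", "opt3", "opt4", "correct_index")

validate_mrt_table <- function(tab) {
  missing <- setdiff(mrt_fixture_cols, names(tab))
  if (length(missing) > 0) {
    stop_navcog("mental-rotation order table lacks columns: ",
                paste(missing, collapse = ", "),
                class = "navcog_validation_error")
  }
  tab <- tab[, mrt_fixture_cols]
  for (col in c("condition", "trial", "correct_index")) {
    tab[[col]] <- as.integer(tab[[col]])
  }
  if (any(!tab$correct_index %in% 0:3)) {
    stop_navcog("correct_index must be in 0..3",
                class = "navcog_validation_error")
  }
  opts <- as.matrix(tab[, c("opt1", "opt2", "opt3", "opt4")])
  picked <- opts[cbind(seq_len(nrow(tab)), tab$correct_index + 1L)]
  if (any(picked != tab$stimulus_id)) {
    stop_navcog("the correct option slot must contain the target stimulus",
                class = "navcog_validation_error")
  }
  counts <- table(tab$condition)
  if (length(unique(counts)) > 1L) {
    stop_navcog("every condition must contain the same number of trials",
                class = "navcog_validation_error")
  }
  tab
}

#' Read or write a mental-rotation order fixture (CSV)
#'
#' @param path CSV file path.
#' @return `read_mrt_fixture()` returns the validated trial table;
#'   `write_mrt_fixture()` returns `path` invisibly.
#' @export
read_mrt_fixture <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mrt_table(tab)
}

#' @rdname read_mrt_fixture
#' @param protocol An `mrt_protocol`.
#' @export
write_mrt_fixture <- function(protocol, path) {
  stopifnot(inherits(protocol, "mrt_protocol"))
  utils::write.csv(protocol$trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mrt_protocol <- function(x, ...) {
  cat("Mental-rotation protocol (", x$source, "): ",
      nrow(x$trials), " trials, conditions ",
      paste(unique(x$trials$condition), collapse = "/"), " degrees\n", sep = "")
  invisible(x)
}

#' Score mental-rotation responses
#'
#' One response per trial, in protocol order. Accuracy is summarized per
#' angular condition together with the median reaction time over correct
#' trials; per-trial correct/incorrect feedback events mirror the
#' audiovisual feedback the game gives after each choice.
#'
#' @param protocol An `mrt_protocol`.
#' @param responses Data frame with columns `chosen_index` (0..3) and `rt`
#'   (seconds), one row per trial.
#' @return An object of class `mrt_score` with `by_condition` (n, n_correct,
#'   accuracy, median_rt_correct), `overall`, and `feedback`.
#' @export
score_mrt <- function(protocol, responses) {
  stopifnot(inherits(protocol, "mrt_protocol"))
  responses <- as.data.frame(responses)
  tab <- protocol$trials
  if (nrow(responses) != nrow(tab)) {
    stop_navcog(sprintf("expected %d responses, got %d",
                        nrow(tab), nrow(responses)),
                class = "navcog_validation_error")
  }
  if (!all(c("chosen_index", "rt") %in% names(responses))) {
    stop_navcog("responses need columns `chosen_index` and `rt`",
                class = "navcog_validation_error")
  }
  correct <- responses$chosen_index == tab$correct_index
  by_cond <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$condition),
    function(idx) {
      ok <- correct[idx]
      data.frame(condition = tab$condition[idx[1]],
                 n = length(idx),
                 n_correct = sum(ok),
                 accuracy = mean(ok),
                 median_rt_correct = if (any(ok)) {
                   stats::median(responses$rt[idx][ok])
                 } else NA_real_)
    }))
  by_cond <- by_cond[order(by_cond$condition), ]
  rownames(by_cond) <- NULL
  structure(
    list(by_condition = by_cond,
         overall = data.frame(n = nrow(tab), n_correct = sum(correct),
                              accuracy = mean(correct)),
         feedback = ifelse(correct, "correct", "incorrect")),
    class = "mrt_score"
  )
}

#' @export
print.mrt_score <- function(x, ...) {
  cat("Mental-rotation score\n")
  print(x$by_condition, row.names = FALSE)
  cat(sprintf("overall accuracy %.3f (%d/%d)\n", x$overall$accuracy,
              x$overall$n_correct, x$overall$n))
  invisible(x)
}
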