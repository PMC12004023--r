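#' Build a Corsi block-tapping protocol
#'
#' Generates the forward and backward blocks of a Corsi span session over the
#' standard 9 locations. For each direction, sequence lengths ascend from
#' `min_length` to `max_length` with `trials_per_length` trials per length.
#' Sequences are seeded pseudorandom draws from locations 1..9 with no
#' location immediately repeated. Each trial carries a `counter` equal to
#' the sequence length (the on-screen count of locations to visit).
#'
#' @param min_length,max_length Sequence length bounds, within 2..9.
#' @param trials_per_length Trials per length per direction.
#' @param seed Integer seed.
#' @return An object of class `corsi_protocol` with `$forward` and
#'   `$backward` trial lists. Each trial has `direction`, `length`,
#'   `sequence`, `expected_response` (the sequence, reversed for backward
#'   trials), and `counter`.
#' @export
#' @examples
#' p <- build_corsi_protocol(seed = 11)
#' length(p$forward)  # 16 trials: lengths 2..9, 2 trials each
build_corsi_protocol <- function(min_length = 2L, max_length = 9L,
                                 trials_per_length = 2L, seed = 1L) {
  min_length <- assert_count(min_length, "min_length", lower = 2L)
  max_length <- assert_count(max_length, "max_length", lower = min_length)
  if (max_length > 9L) {
    stop_navcog("max_length cannot exceed the 9 available locations",
                class = "navcog_validation_error")
  }
  trials_per_length <- assert_count(trials_per_length, "trials_per_length",
                                    lower = 1L)
  seed <- assert_count(seed, "seed")

  gen_sequence <- function(len) {
    s <- integer(len)
    s[1] <- sample.int(9L, 1L)
    for (i in seq_len(len - 1L) + 1L) {
      s[i] <- sample(setdiff(1:9, s[i - 1L]), 1L)
    }
    s
  }
  blocks <- with_seed(seed, {
    lapply(c(forward = "forward", backward = "backward"), function(dir) {
      trials <- list()
      for (len in min_length:max_length) {
        for (k in seq_len(trials_per_length)) {
          sq <- gen_sequence(len)
          trials[[length(trials) + 1L]] <- list(
            direction = dir,
            length = len,
            sequence = sq,
            expected_response = if (dir == "forward") sq else rev(sq),
            counter = len
          )
        }
      }
      trials
    })
  })
  structure(c(blocks,
              list(min_length = min_length, max_length = max_length,
                   trials_per_length = trials_per_length, seed = seed)),
            class = "corsi_protocol")
}

#' @export
print.corsi_protocol <- function(x, ...) {
  cat("Corsi block-tapping protocol: lengths ", x$min_length, "..",
      x$max_length, ", ", x$trials_per_length,
      " trials/length per direction, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

run_corsi_block <- function(trials, responses) {
  n_correct <- 0L
  correct_lengths <- integer(0)
  per_trial <- logical(0)
  stop_reason <- "exhausted"
  consec_fail <- 0L
  fail_len <- NA_integer_
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (i > length(responses)) {
      stop_navcog("responses exhausted before the stop rule was reached",
                  class = "navcog_validation_error")
    }
    resp <- as.integer(responses[[i]])
    if (length(resp) > 0 && any(!resp %in% 1:9)) {
      stop_navcog("response refers to a location outside 1..9",
                  class = "navcog_validation_error")
    }
    ok <- identical(resp, as.integer(tr$expected_response))
    per_trial <- c(per_trial, ok)
    if (ok) {
      n_correct <- n_correct + 1L
      correct_lengths <- c(correct_lengths, tr$length)
      consec_fail <- 0L
      fail_len <- NA_integer_
    } else {
      if (consec_fail >= 1L && !is.na(fail_len) && fail_len == tr$length) {
        stop_reason <- "two_consecutive_failures"
        break
      }
      consec_fail <- consec_fail + 1L
      fail_len <- tr$length
    }
  }
  span <- if (length(correct_lengths) > 0) max(correct_lengths) else 0L
  list(per_trial = per_trial,
       span = as.integer(span),
       n_correct = n_correct,
       product_score = as.integer(span) * n_correct,
       stop_reason = stop_reason,
       trials_administered = length(per_trial))
}

#' Run a Corsi session against recorded or simulated responses
#'
#' Replays responses against the protocol, applying the standard stop rule:
#' a direction's block ends after two consecutive failed attempts at
#' sequences of the same length; responses past the stop point are ignored.
#' A trial is correct only if the response reproduces the expected sequence
#' exactly. The span is the longest length with at least one correct trial
#' (0 if none); the product score is span times the number of correct trials
#' in that direction.
#'
#' @param protocol A [build_corsi_protocol()] result.
#' @param responses Either a flat list of integer vectors covering the
#'   forward block then the backward block, or a list with `$forward` and
#'   `$backward` components. Responses only need to reach each block's stop
#'   point.
#' @return An object of class `corsi_result` with per-direction details and
#'   `span_forward`, `span_backward`, `product_score_forward`,
#'   `product_score_backward`.
#' @export
run_corsi_session <- function(protocol, responses) {
  stopifnot(inherits(protocol, "corsi_protocol"))
  if (!is.null(responses$forward) || !is.null(responses$backward)) {
    fwd_resp <- responses$forward %||% list()
    bwd_resp <- responses$backward %||% list()
  } else {
    n_fwd <- length(protocol$forward)
    fwd_resp <- responses[seq_len(min(n_fwd, length(responses)))]
    bwd_resp <- if (length(responses) > n_fwd) {
      responses[(n_fwd + 1L):length(responses)]
    } else list()
  }
  fwd <- run_corsi_block(protocol$forward, fwd_resp)
  bwd <- run_corsi_block(protocol$backward, bwd_resp)
  structure(
    list(forward = fwd, backward = bwd,
         span_forward = fwd$span, span_backward = bwd$span,
         product_score_forward = fwd$product_score,
         product_score_backward = bwd$product_score),
    class = "corsi_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.corsi_result <- function(x, ...) {
  cat(sprintf("Corsi session: forward span %d (product %d, %s), backward span %d (product %d, %s)\n",
              x$span_forward, x$product_score_forward, x$forward$stop_reason,
              x$span_backward, x$product_score_backward, x$backward$stop_reason))
  invisible(x)
}
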