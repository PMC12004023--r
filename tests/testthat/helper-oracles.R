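# Independent oracles and small fixture builders used across the suite.

# Brute-force rank-biserial: favorable minus unfavorable pair proportion,
# ties counted as neither.
rb_brute_force <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}

# Independent step-by-step Corsi replay: vectorized over the full
# correctness vector, structured differently from the package scorer.
corsi_replay_oracle <- function(trials, responses) {
  lens <- vapply(trials, function(t) t$length, numeric(1))
  ok <- vapply(seq_along(trials), function(i) {
    identical(as.integer(responses[[i]]),
              as.integer(trials[[i]]$expected_response))
  }, logical(1))
  n_adm <- length(trials)
  stop_reason <- "exhausted"
  for (i in seq_along(trials)[-1]) {
    if (!ok[i] && !ok[i - 1] && lens[i] == lens[i - 1]) {
      n_adm <- i
      stop_reason <- "two_consecutive_failures"
      break
    }
  }
  ok <- ok[seq_len(n_adm)]
  lens <- lens[seq_len(n_adm)]
  span <- if (any(ok)) max(lens[ok]) else 0
  list(span = as.integer(span), n_correct = sum(ok),
       product_score = as.integer(span) * sum(ok),
       stop_reason = stop_reason, trials_administered = n_adm)
}

# Random Corsi response pattern: each trial independently correct with
# probability p, otherwise one element perturbed.
random_corsi_responses <- function(trials, p_correct = 0.5) {
  lapply(trials, function(tr) {
    expected <- as.integer(tr$expected_response)
    if (runif(1) < p_correct) return(expected)
    i <- sample.int(length(expected), 1)
    expected[i] <- sample(setdiff(1:9, expected[i]), 1)
    expected
  })
}

# Straight-line trajectory sampled at n points.
straight_response <- function(from, to, n = 20, t_end = 2) {
  s <- seq(0, 1, length.out = n)
  nav_response(s * t_end,
               cbind(from[1] + s * (to[1] - from[1]),
                     from[2] + s * (to[2] - from[2])))
}

# Zig-zag path from `from` to `to` with total length `ratio` times the
# straight distance (constructed, so the ratio is exact).
zigzag_response <- function(from, to, ratio, n_teeth = 5) {
  d <- sqrt(sum((to - from)^2))
  a <- d * sqrt(ratio^2 - 1) / (2 * n_teeth)
  dir <- (to - from) / d
  perp <- c(-dir[2], dir[1])
  k <- seq_len(2 * n_teeth - 1)
  pts <- rbind(from,
               t(sapply(k, function(i) {
                 from + dir * (d * i / (2 * n_teeth)) + perp * a * (i %% 2)
               })),
               to)
  nav_response(seq_len(nrow(pts)) - 1, pts)
}

# Grid search on the noncentrality parameter: smallest lambda (step `step`)
# with pchisq(chi2, df, ncp = lambda) <= target.
ncp_grid_search <- function(chi2, df, target_p, hi = 200, step = 1e-3) {
  grid <- seq(0, hi, by = 0.5)
  p <- pchisq(chi2, df, ncp = grid)
  j <- which(p <= target_p)[1]
  if (is.na(j)) stop("grid too short")
  if (j == 1) return(0)
  fine <- seq(grid[j - 1], grid[j], by = step)
  fine[which(pchisq(chi2, df, ncp = fine) <= target_p)[1]]
}

# Population rank-biserial of latent-shift groups (continuous latent scale).
true_rb_latent_shift <- function(delta) 2 * pnorm(delta / sqrt(2)) - 1

default_profiles <- function() {
  list(
    caregiver = group_profile("caregiver"),
    carrier = group_profile("carrier"),
    control = group_profile("control"),
    mci = group_profile("mci", nav_noise_sd = 0.15, nav_path_wobble = 1.4,
                        mrt_accuracy_by_angle = c("0" = 0.85, "90" = 0.7,
                                                  "180" = 0.55),
                        corsi_span_mean = 4.5,
                        latent_usability_shift = -0.6)
  )
}
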