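test_that("arena configuration rejects degenerate geometry", {
  expect_error(arena_config(canonical_goal = c(5, 5)), "outside the arena")
  expect_error(
    arena_config(canonical_landmarks = list(c(0.5, 0.5), c(0.5, 0.5))),
    "distinct"
  )
  expect_error(arena_config(n_trials = 0), "integer")
})

test_that("protocol geometry is rigid across trials and offsets cover 45-degree steps", {
  cfg <- arena_config()
  pair_dists <- function(tr) {
    pts <- rbind(tr$start, tr$landmark_a, tr$landmark_b, tr$goal)
    as.vector(dist(pts))
  }
  for (seed in c(1, 2, 17)) {
    p <- build_ghgt_protocol(cfg, seed = seed)
    expect_length(p$trials, 8)
    offsets <- vapply(p$trials, function(t) t$rotation_offset, numeric(1))
    expect_setequal(offsets, seq(0, 315, by = 45))
    ref <- pair_dists(p$trials[[1]])
    for (tr in p$trials[-1]) {
      expect_lt(max(abs(pair_dists(tr) - ref)), 1e-9)
    }
  }
})

test_that("zero rotation reproduces the canonical geometry exactly", {
  cfg <- arena_config()
  p <- build_ghgt_protocol(cfg, seed = 4)
  tr0 <- Filter(function(t) t$rotation_offset == 0, p$trials)[[1]]
  expect_equal(tr0$start, cfg$canonical_start)
  expect_equal(tr0$landmark_a, cfg$canonical_landmarks[[1]])
  expect_equal(tr0$goal, cfg$canonical_goal)
})

test_that("protocols are deterministic under a seed and differ across seeds", {
  cfg <- arena_config()
  expect_identical(
    serialize(build_ghgt_protocol(cfg, seed = 1), NULL),
    serialize(build_ghgt_protocol(cfg, seed = 1), NULL)
  )
  off <- function(p) vapply(p$trials, function(t) t$rotation_offset, numeric(1))
  p1 <- build_ghgt_protocol(cfg, seed = 1)
  p2 <- build_ghgt_protocol(cfg, seed = 2)
  expect_false(identical(off(p1), off(p2)))
  expect_setequal(off(p2), seq(0, 315, by = 45))
})

test_that("more than 8 trials needs the explicit repeat flag", {
  cfg <- arena_config(n_trials = 10)
  expect_error(build_ghgt_protocol(cfg, seed = 1), "allow_repeat")
  p <- build_ghgt_protocol(cfg, seed = 1, allow_repeat = TRUE)
  expect_length(p$trials, 10)
})

test_that("navigation scoring matches hand-computed metrics", {
  p <- build_ghgt_protocol(arena_config(), seed = 3)
  tr <- p$trials[[1]]

  s <- score_nav_trial(tr, straight_response(tr$start, tr$goal))
  expect_equal(s$distance_error, 0, tolerance = 1e-12)
  expect_equal(s$efficiency, 1.0)

  # start -> landmark_a -> goal: legs summed by hand from the coordinates
  pts <- rbind(tr$start, tr$landmark_a, tr$goal)
  legs <- sqrt(sum((pts[2, ] - pts[1, ])^2)) + sqrt(sum((pts[3, ] - pts[2, ])^2))
  s2 <- score_nav_trial(tr, nav_response(0:2, pts))
  expect_equal(s2$path_length, legs, tolerance = 1e-12)
  expect_gte(s2$path_length, s2$ideal_length - 1e-9)

  s3 <- score_nav_trial(tr, nav_response(0, matrix(tr$start, ncol = 2)))
  expect_equal(s3$path_length, 0)
  expect_equal(s3$distance_error, sqrt(sum((tr$start - tr$goal)^2)))

  expect_error(nav_response(numeric(0), matrix(numeric(0), ncol = 2)),
               "at least one sample")
  expect_error(nav_response(c(0, 0), rbind(c(0, 0), c(1, 1))),
               "strictly increasing")
})

test_that("anomaly detector flags the three patterns and nothing on ideal paths", {
  p <- build_ghgt_protocol(arena_config(), seed = 6)
  tr <- p$trials[[1]]
  th <- anomaly_thresholds()

  ideal <- detect_nav_anomalies(tr, straight_response(tr$start, tr$goal), th)
  expect_length(ideal$flags, 0)
  expect_false(ideal$repeat_tutorial)

  # walk straight to the nearest landmark and stop there
  d_a <- sqrt(sum((tr$landmark_a - tr$start)^2))
  d_b <- sqrt(sum((tr$landmark_b - tr$start)^2))
  lm <- if (d_a <= d_b) tr$landmark_a else tr$landmark_b
  to_lm <- detect_nav_anomalies(tr, straight_response(tr$start, lm), th)
  expect_setequal(to_lm$flags, c("TOWARD_LANDMARK", "EXTREME_DEVIATION"))

  # zig-zag of 4x the ideal length ending exactly on the goal
  zz <- detect_nav_anomalies(tr, zigzag_response(tr$start, tr$goal, 4), th)
  expect_identical(zz$flags, "LONG_PATH")

  tut <- detect_nav_anomalies(tr, straight_response(tr$start, lm), th,
                              tutorial = TRUE)
  expect_true(tut$repeat_tutorial)
})

test_that("relaxing path and deviation thresholds never adds flags", {
  p <- build_ghgt_protocol(arena_config(), seed = 8)
  tr <- p$trials[[2]]
  set.seed(42)
  for (i in 1:25) {
    endpoint <- tr$goal + rnorm(2, 0, 0.4)
    ratio <- runif(1, 1, 6)
    resp <- zigzag_response(tr$start, endpoint, ratio)
    base <- detect_nav_anomalies(tr, resp, anomaly_thresholds())$flags
    relaxed <- detect_nav_anomalies(
      tr, resp,
      anomaly_thresholds(path_ratio_max = 3 + runif(1, 0, 4),
                         deviation_fraction_max = min(1, 0.5 + runif(1, 0, 0.5)))
    )$flags
    expect_true(all(relaxed %in% base))
  }
})
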