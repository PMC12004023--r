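#' Arena configuration for the hidden-goal navigation task
#'
#' Defines the circular arena and the canonical trial geometry: a start
#' position, two distal landmarks, and a hidden goal that is visible for a
#' few seconds at the start of each trial. All trial geometries are rigid
#' rotations of this canonical layout about the arena center, so the mutual
#' spatial relationships among the four points are identical in every trial.
#'
#' Coordinates are Cartesian, y-up, centered on the arena; angles are in
#' degrees, counterclockwise positive.
#'
#' @param radius Arena radius in arbitrary length units.
#' @param canonical_start Numeric length-2 start position.
#' @param canonical_landmarks List of two numeric length-2 landmark positions.
#' @param canonical_goal Numeric length-2 hidden-goal position.
#' @param visibility_duration Seconds the goal is visible at trial onset.
#' @param n_trials Number of trials in a protocol.
#'
#' @return An object of class `arena_config`.
#' @export
#' @examples
#' cfg <- arena_config()
#' build_ghgt_protocol(cfg, seed = 1)
arena_config <- function(radius = 1.0,
                         canonical_start = c(0, -0.8),
                         canonical_landmarks = list(c(-0.6, 0.55), c(0.6, 0.55)),
                         canonical_goal = c(0.15, 0.1),
                         visibility_duration = 5.0,
                         n_trials = 8L) {
  assert_scalar_number(radius, "radius", lower = 1e-12)
  assert_scalar_number(visibility_duration, "visibility_duration", lower = 0)
  n_trials <- assert_count(n_trials, "n_trials", lower = 1L)
  pts <- c(list(start = canonical_start, goal = canonical_goal),
           stats::setNames(canonical_landmarks, c("landmark_a", "landmark_b")))
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || anyNA(p)) {
      stop_navcog("canonical point `", nm, "` must be a numeric length-2 vector",
                  class = "navcog_validation_error")
    }
    if (vnorm(p) > radius + 1e-9) {
      stop_navcog("canonical point `", nm, "` lies outside the arena",
                  class = "navcog_validation_error")
    }
  }
  if (vnorm(pts$landmark_a - pts$landmark_b) < 1e-9 ||
      vnorm(pts$landmark_a - pts$goal) < 1e-9 ||
      vnorm(pts$landmark_b - pts$goal) < 1e-9) {
    stop_navcog("landmarks must be distinct from each other and from the goal",
                class = "navcog_validation_error")
  }
  structure(
    list(radius = radius,
         canonical_start = as.numeric(canonical_start),
         canonical_landmarks = lapply(canonical_landmarks, as.numeric),
         canonical_goal = as.numeric(canonical_goal),
         visibility_duration = visibility_duration,
         n_trials = n_trials),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Hidden-goal arena (radius ", format(x$radius), ")\n", sep = "")
  cat("  start     (", paste(format(x$canonical_start), collapse = ", "), ")\n")
  cat("  landmarks (", paste(format(x$canonical_landmarks[[1]]), collapse = ", "),
      ") / (", paste(format(x$canonical_landmarks[[2]]), collapse = ", "), ")\n")
  cat("  goal      (", paste(format(x$canonical_goal), collapse = ", "), ")\n")
  cat("  ", x$n_trials, " trials, goal visible ", format(x$visibility_duration),
      " s\n", sep = "")
  invisible(x)
}

rotate2d <- function(p, degrees) {
  th <- degrees * pi / 180
  c(cos(th) * p[1] - sin(th) * p[2],
    sin(th) * p[1] + cos(th) * p[2])
}

#' Build a hidden-goal task protocol
#'
#' Generates the trial list for a navigation protocol. The canonical
#' configuration occupies one of 8 positions per trial: it is rotated about
#' the arena center by a multiple of 45 degrees, and the order of the 8
#' offsets is a seeded pseudorandom permutation. Rotation is a rigid motion,
#' so all six pairwise distances among start, landmarks, and goal are
#' preserved exactly across trials.
#'
#' @param config An [arena_config()].
#' @param seed Integer seed; the same seed always yields the same protocol.
#' @param allow_repeat Permit more than 8 trials by recycling offsets
#'   (sampled with replacement beyond the first 8).
#'
#' @return An object of class `ghgt_protocol`: a list of trials, each with
#'   `trial_index` (0-based), `rotation_offset` (degrees), and the rotated
#'   `start`, `landmark_a`, `landmark_b`, `goal` points.
#' @export
build_ghgt_protocol <- function(config = arena_config(), seed,
                                allow_repeat = FALSE) {
  stopifnot(inherits(config, "arena_config"))
  seed <- assert_count(seed, "seed")
  offsets <- seq(0, 315, by = 45)
  n <- config$n_trials
  if (n > length(offsets) && !allow_repeat) {
    stop_navcog("n_trials > 8 requires allow_repeat = TRUE",
                class = "navcog_protocol_error")
  }
  order <- with_seed(seed, {
    base <- sample(offsets)
    if (n > length(offsets)) {
      c(base, sample(offsets, n - length(offsets), replace = TRUE))
    } else {
      base[seq_len(n)]
    }
  })
  trials <- lapply(seq_len(n), function(i) {
    off <- order[i]
    list(trial_index = i - 1L,
         rotation_offset = off,
         start = rotate2d(config$canonical_start, off),
         landmark_a = rotate2d(config$canonical_landmarks[[1]], off),
         landmark_b = rotate2d(config$canonical_landmarks[[2]], off),
         goal = rotate2d(config$canonical_goal, off))
  })
  structure(list(config = config, seed = seed, trials = trials),
            class = "ghgt_protocol")
}

#' @export
print.ghgt_protocol <- function(x, ...) {
  cat("Hidden-goal task protocol:", length(x$trials), "trials, seed",
      x$seed, "\n")
  cat("  rotation offsets:",
      paste0(vapply(x$trials, function(t) t$rotation_offset, numeric(1)),
             "°", collapse = " "), "\n")
  invisible(x)
}

#' Construct a navigation response (trajectory)
#'
#' A timestamped 2-D trajectory plus the final response point. Times must be
#' strictly increasing; the final position is the last sample.
#'
#' @param times Numeric vector of sample times in seconds.
#' @param positions Numeric matrix with one `(x, y)` row per sample.
#' @return An object of class `nav_response`.
#' @export
nav_response <- function(times, positions) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (length(times) == 0L || nrow(positions) == 0L) {
    stop_navcog("trajectory must contain at least one sample",
                class = "navcog_validation_error")
  }
  if (length(times) != nrow(positions)) {
    stop_navcog("`times` and `positions` lengths differ",
                class = "navcog_validation_error")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_navcog("sample times must be strictly increasing",
                class = "navcog_validation_error")
  }
  structure(list(times = as.numeric(times), positions = positions,
                 final_position = positions[nrow(positions), ]),
            class = "nav_response")
}

path_segments <- function(response) {
  p <- response$positions
  if (nrow(p) < 2L) {
    return(list(lengths = numeric(0), directions = matrix(numeric(0), ncol = 2)))
  }
  d <- diff(p)
  lens <- sqrt(rowSums(d^2))
  list(lengths = lens, directions = d)
}

#' Score one hidden-goal navigation trial
#'
#' Computes the primary navigation metrics: the Euclidean distance from the
#' final response point to the hidden goal, the total path length, the ideal
#' (straight start-to-goal) length, and the path efficiency
#' `ideal / max(path, ideal)`. Anomaly detection is a separate step
#' ([detect_nav_anomalies()]).
#'
#' @param trial A trial from [build_ghgt_protocol()].
#' @param response A [nav_response()].
#' @return An object of class `nav_score`.
#' @export
score_nav_trial <- function(trial, response) {
  stopifnot(inherits(response, "nav_response"))
  segs <- path_segments(response)
  path_length <- sum(segs$lengths)
  ideal <- vnorm(trial$goal - trial$start)
  structure(
    list(distance_error = vnorm(response$final_position - trial$goal),
         path_length = path_length,
         ideal_length = ideal,
         efficiency = ideal / max(path_length, ideal)),
    class = "nav_score"
  )
}

#' @export
print.nav_score <- function(x, ...) {
  cat(sprintf("nav trial: distance error %.3f, path %.3f (ideal %.3f), efficiency %.3f\n",
              x$distance_error, x$path_length, x$ideal_length, x$efficiency))
  invisible(x)
}

#' Thresholds for the navigation anomaly detector
#'
#' @param landmark_heading_cos Cosine-similarity threshold between the early
#'   mean heading and the start-to-nearest-landmark direction (default
#'   `cos(20 degrees)`).
#' @param landmark_heading_fraction Fraction of the path length, from the
#'   start, over which the mean heading is taken.
#' @param path_ratio_max A path longer than this multiple of the straight
#'   start-to-goal distance is flagged as excessively long.
#' @param deviation_fraction_max A final-point error larger than this
#'   fraction of the arena radius is flagged as an extreme deviation.
#' @return An object of class `anomaly_thresholds`.
#' @export
anomaly_thresholds <- function(landmark_heading_cos = cos(20 * pi / 180),
                               landmark_heading_fraction = 0.25,
                               path_ratio_max = 3.0,
                               deviation_fraction_max = 0.5) {
  assert_scalar_number(landmark_heading_cos, "landmark_heading_cos",
                       lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(landmark_heading_fraction, "landmark_heading_fraction",
                       lower = 1e-12, upper = 1)
  assert_scalar_number(path_ratio_max, "path_ratio_max", lower = 1e-12)
  assert_scalar_number(deviation_fraction_max, "deviation_fraction_max",
                       lower = 1e-12, upper = 1)
  structure(list(landmark_heading_cos = landmark_heading_cos,
                 landmark_heading_fraction = landmark_heading_fraction,
                 path_ratio_max = path_ratio_max,
                 deviation_fraction_max = deviation_fraction_max),
            class = "anomaly_thresholds")
}

# Length-weighted mean unit heading over the first `fraction` of path length.
early_mean_heading <- function(response, fraction) {
  segs <- path_segments(response)
  if (length(segs$lengths) == 0L || sum(segs$lengths) == 0) return(NULL)
  total <- sum(segs$lengths)
  budget <- fraction * total
  cum <- cumsum(segs$lengths)
  used <- pmin(segs$lengths, pmax(0, budget - c(0, cum[-length(cum)])))
  keep <- used > 0
  if (!any(keep)) return(NULL)
  units <- segs$directions[keep, , drop = FALSE] /
    segs$lengths[keep]
  h <- colSums(units * used[keep])
  n <- vnorm(h)
  if (n == 0) NULL else h / n
}

#' Detect anomalous navigation behavior
#'
#' Flags the unusual performance patterns the task engine watches for during
#' the tutorial and test phases:
#' \describe{
#'   \item{TOWARD_LANDMARK}{the early mean heading points at the nearest
#'     landmark (cosine similarity at or above the threshold) and the final
#'     position ends up nearer that landmark than the goal;}
#'   \item{LONG_PATH}{the path exceeds `path_ratio_max` times the straight
#'     start-to-goal distance;}
#'   \item{EXTREME_DEVIATION}{the final point misses the goal by more than
#'     `deviation_fraction_max` of the arena radius.}
#' }
#' In the tutorial phase a non-empty flag set asks for the tutorial to be
#' repeated.
#'
#' @inheritParams score_nav_trial
#' @param thresholds An [anomaly_thresholds()] object.
#' @param radius Arena radius the deviation rule is relative to.
#' @param tutorial Logical; is the session in its tutorial phase?
#' @return An object of class `nav_anomalies` with elements `flags`
#'   (character vector, possibly empty) and `repeat_tutorial` (logical).
#' @export
detect_nav_anomalies <- function(trial, response,
                                 thresholds = anomaly_thresholds(),
                                 radius = 1.0, tutorial = FALSE) {
  stopifnot(inherits(thresholds, "anomaly_thresholds"),
            inherits(response, "nav_response"))
  score <- score_nav_trial(trial, response)
  flags <- character(0)

  landmarks <- list(landmark_a = trial$landmark_a, landmark_b = trial$landmark_b)
  d_start <- vapply(landmarks, function(l) vnorm(l - trial$start), numeric(1))
  nearest <- landmarks[[which.min(d_start)]]
  heading <- early_mean_heading(response, thresholds$landmark_heading_fraction)
  if (!is.null(heading) && min(d_start) > 0) {
    to_lm <- (nearest - trial$start) / min(d_start)
    cos_sim <- sum(heading * to_lm)
    final_nearer_lm <- vnorm(response$final_position - nearest) <
      vnorm(response$final_position - trial$goal)
    if (cos_sim >= thresholds$landmark_heading_cos && final_nearer_lm) {
      flags <- c(flags, "TOWARD_LANDMARK")
    }
  }
  if (score$path_length > thresholds$path_ratio_max * score$ideal_length) {
    flags <- c(flags, "LONG_PATH")
  }
  if (score$distance_error > thresholds$deviation_fraction_max * radius) {
    flags <- c(flags, "EXTREME_DEVIATION")
  }
  structure(list(flags = flags,
                 repeat_tutorial = tutorial && length(flags) > 0),
            class = "nav_anomalies")
}

#' @export
print.nav_anomalies <- function(x, ...) {
  if (length(x$flags) == 0) {
    cat("no navigation anomalies\n")
  } else {
    cat("anomalies:", paste(x$flags, collapse = ", "),
        if (x$repeat_tutorial) "(repeat tutorial)" else "", "\n")
  }
  invisible(x)
}
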