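# Builders that turn protocol/response objects into session-document task
# blocks, and the scorer that replays a document back through the engine.

ghgt_block <- function(protocol, responses) {
  stopifnot(inherits(protocol, "ghgt_protocol"))
  list(
    protocol = lapply(protocol$trials, function(tr) {
      list(trial_index = tr$trial_index, rotation_offset = tr$rotation_offset,
           start = tr$start, landmark_a = tr$landmark_a,
           landmark_b = tr$landmark_b, goal = tr$goal)
    }),
    responses = lapply(seq_along(responses), function(i) {
      r <- responses[[i]]
      list(trial_index = i - 1L,
           trajectory = lapply(seq_along(r$times), function(k) {
             c(r$times[k], r$positions[k, ])
           }))
    })
  )
}

gmrt_block <- function(protocol, responses) {
  stopifnot(inherits(protocol, "mrt_protocol"))
  list(
    protocol = lapply(seq_len(nrow(protocol$trials)), function(i) {
      as.list(protocol$trials[i, ])
    }),
    responses = lapply(seq_len(nrow(responses)), function(i) {
      list(trial_index = i - 1L,
           chosen_index = responses$chosen_index[i], rt = responses$rt[i])
    })
  )
}

gcorsi_block <- function(protocol, responses) {
  stopifnot(inherits(protocol, "corsi_protocol"))
  ser <- function(trials) lapply(trials, function(tr) {
    list(direction = tr$direction, length = tr$length,
         sequence = tr$sequence, expected_response = tr$expected_response,
         counter = tr$counter)
  })
  list(
    protocol = list(forward = ser(protocol$forward),
                    backward = ser(protocol$backward),
                    min_length = protocol$min_length,
                    max_length = protocol$max_length,
                    trials_per_length = protocol$trials_per_length,
                    seed = protocol$seed),
    responses = list(forward = responses$forward,
                     backward = responses$backward)
  )
}

ghgt_trial_from_json <- function(tr) {
  list(trial_index = tr$trial_index,
       rotation_offset = tr$rotation_offset,
       start = unlist(tr$start), landmark_a = unlist(tr$landmark_a),
       landmark_b = unlist(tr$landmark_b), goal = unlist(tr$goal))
}

mrt_protocol_from_json <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(condition = r$condition, trial = r$trial,
               stimulus_id = r$stimulus_id, opt1 = r$opt1, opt2 = r$opt2,
               opt3 = r$opt3, opt4 = r$opt4,
               correct_index = r$correct_index, stringsAsFactors = FALSE)
  }))
  structure(list(trials = validate_mrt_table(tab), source = "session",
                 seed = NULL),
            class = "mrt_protocol")
}

corsi_protocol_from_json <- function(p) {
  de <- function(trials) lapply(trials, function(tr) {
    list(direction = tr$direction, length = tr$length,
         sequence = as.integer(unlist(tr$sequence)),
         expected_response = as.integer(unlist(tr$expected_response)),
         counter = tr$counter)
  })
  structure(list(forward = de(p$forward), backward = de(p$backward),
                 min_length = p$min_length, max_length = p$max_length,
                 trials_per_length = p$trials_per_length, seed = p$seed),
            class = "corsi_protocol")
}

#' Score every task block of a session document
#'
#' Replays the document's stored protocols and responses through the task
#' scorers: per-trial navigation metrics and anomaly flags for the
#' hidden-goal block, per-condition accuracy for the mental-rotation block,
#' and spans/product scores for the Corsi block.
#'
#' @param doc A [session_document()] (e.g. from [read_session()]).
#' @param thresholds Anomaly thresholds for the navigation block.
#' @param radius Arena radius for the deviation rule.
#' @return Named list of per-task score summaries.
#' @export
score_session <- function(doc, thresholds = anomaly_thresholds(),
                          radius = 1.0) {
  out <- list()
  if (!is.null(doc$tasks$ghgt)) {
    blk <- doc$tasks$ghgt
    trials <- lapply(blk$protocol, ghgt_trial_from_json)
    idx <- vapply(trials, function(t) t$trial_index, numeric(1))
    out$ghgt <- do.call(rbind, lapply(blk$responses, function(resp) {
      tr <- trials[[which(idx == resp$trial_index)]]
      traj <- do.call(rbind, lapply(resp$trajectory, unlist))
      r <- nav_response(traj[, 1], traj[, 2:3])
      s <- score_nav_trial(tr, r)
      an <- detect_nav_anomalies(tr, r, thresholds, radius = radius)
      data.frame(trial_index = resp$trial_index,
                 distance_error = s$distance_error,
                 path_length = s$path_length,
                 efficiency = s$efficiency,
                 anomalies = paste(an$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(doc$tasks$gmrt)) {
    blk <- doc$tasks$gmrt
    prot <- mrt_protocol_from_json(blk$protocol)
    resp <- data.frame(
      chosen_index = vapply(blk$responses, function(r) as.integer(r$chosen_index),
                            integer(1)),
      rt = vapply(blk$responses, function(r) as.numeric(r$rt), numeric(1))
    )
    out$gmrt <- score_mrt(prot, resp)
  }
  if (!is.null(doc$tasks$gcorsi)) {
    blk <- doc$tasks$gcorsi
    prot <- corsi_protocol_from_json(blk$protocol)
    resp <- list(
      forward = lapply(blk$responses$forward, function(r) as.integer(unlist(r))),
      backward = lapply(blk$responses$backward, function(r) as.integer(unlist(r)))
    )
    out$gcorsi <- run_corsi_session(prot, resp)
  }
  out
}

#' Simulate a complete session for one participant
#'
#' Runs all three task simulators for one participant profile and packages
#' the results as a session document.
#'
#' @param profile A [group_profile()].
#' @param participant_id Identifier stored in the session metadata.
#' @param seed Integer seed (sub-seeds for the three tasks are derived
#'   from it deterministically).
#' @param config An [arena_config()] for the navigation task.
#' @return A [session_document()].
#' @export
simulate_session <- function(profile, participant_id, seed,
                             config = arena_config()) {
  seed <- assert_count(seed, "seed")
  ghgt_prot <- build_ghgt_protocol(config, seed = seed)
  nav_resp <- lapply(seq_along(ghgt_prot$trials), function(i) {
    simulate_nav_agent(profile, ghgt_prot$trials[[i]], seed = seed + i)
  })
  mrt_prot <- build_mrt_protocol(seed = seed)
  mrt_resp <- simulate_mrt_responses(profile, mrt_prot, seed = seed + 101L)
  corsi_prot <- build_corsi_protocol(seed = seed)
  corsi_resp <- simulate_corsi_responses(profile, corsi_prot,
                                         seed = seed + 211L)
  session_document(
    participant_id = participant_id, group = profile$group,
    device = "simulated",
    tasks = list(ghgt = ghgt_block(ghgt_prot, nav_resp),
                 gmrt = gmrt_block(mrt_prot, mrt_resp),
                 gcorsi = gcorsi_block(corsi_prot, corsi_resp)),
    timestamp = "1970-01-01T00:00:00"
  )
}
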