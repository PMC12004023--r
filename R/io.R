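SESSION_SCHEMA_VERSION <- "1.0"

#' Assemble a session document
#'
#' The on-disk unit of a participant session: schema version, session
#' metadata, and one block per task holding its protocol, responses, and
#' scores. Trajectories are stored as arrays of `[t, x, y]`. Unknown extra
#' fields survive a read/write round-trip untouched.
#'
#' @param participant_id,group,device Session metadata.
#' @param tasks Named list with any of `ghgt`, `gmrt`, `gcorsi` blocks.
#' @param timestamp Session timestamp string.
#' @return A list of class `session_document`.
#' @export
session_document <- function(participant_id, group = NA_character_,
                             device = "unknown", tasks = list(),
                             timestamp = format(Sys.time(),
                                                "%Y-%m-%dT%H:%M:%S")) {
  structure(
    list(schema_version = SESSION_SCHEMA_VERSION,
         session = list(participant_id = participant_id, group = group,
                        device = device, timestamp = timestamp),
         tasks = tasks),
    class = "session_document"
  )
}

validate_session <- function(doc) {
  problems <- character(0)
  if (is.null(doc$schema_version)) {
    problems <- c(problems, "$.schema_version: missing")
  } else if (!identical(as.character(doc$schema_version),
                        SESSION_SCHEMA_VERSION)) {
    stop_navcog("session schema version ", doc$schema_version,
                " needs upgrading (supported: ", SESSION_SCHEMA_VERSION, ")",
                class = "navcog_schema_version_error")
  }
  if (is.null(doc$session)) problems <- c(problems, "$.session: missing")
  if (is.null(doc$session$participant_id)) {
    problems <- c(problems, "$.session.participant_id: missing")
  }
  for (task in intersect(names(doc$tasks), c("ghgt", "gmrt", "gcorsi"))) {
    blk <- doc$tasks[[task]]
    n_prot <- length(blk$protocol)
    for (i in seq_along(blk$responses)) {
      tr <- blk$responses[[i]]$trial_index
      if (!is.null(tr) && (tr < 0 || tr >= n_prot)) {
        problems <- c(problems,
                      sprintf("$.tasks.%s.responses[%d].trial_index: no trial %s in protocol",
                              task, i, tr))
      }
    }
  }
  if (length(problems) > 0) {
    stop_navcog("session document is invalid:\n  ",
                paste(problems, collapse = "\n  "),
                class = "navcog_schema_error")
  }
  invisible(doc)
}

#' Read and write session documents (atomic JSON)
#'
#' `write_session()` serializes to a temporary file in the target directory
#' and renames it into place, so a partially written document can never be
#' observed — the contract protecting against data loss on interrupted
#' saves. `read_session()` parses, validates against the schema, and
#' reports every violation it finds (not just the first); unknown fields
#' are preserved verbatim.
#'
#' @param doc A [session_document()] (or compatible list).
#' @param path File path.
#' @return `read_session()` returns the validated `session_document`;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(doc, path) {
  tmp <- tempfile("session_", tmpdir = dirname(path), fileext = ".json.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(unclass(doc), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (!file.rename(tmp, path)) {
    stop_navcog("atomic rename onto ", path, " failed",
                class = "navcog_io_error")
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    stop_navcog("no such session file: ", path, class = "navcog_io_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_navcog("session file is not valid JSON: ", conditionMessage(e),
                  class = "navcog_parse_error")
    }
  )
  validate_session(doc)
  class(doc) <- "session_document"
  doc
}

#' Read an expert ratings table (CSV)
#'
#' Expects UTF-8 comma-separated data with columns `rater_id`, `item_id`,
#' `dimension`, `round`, `rating`. Ratings must parse as integers within
#' the declared scale; violations are reported with their row numbers.
#' Duplicate `(rater, item, dimension, round)` combinations are an error.
#'
#' @param path CSV path.
#' @param n_categories,category_floor Declared rating scale.
#' @return Long data frame of validated ratings. Use [ratings_to_matrix()]
#'   to pivot one dimension/round into a [rating_matrix()].
#' @export
read_ratings <- function(path, n_categories = 4L, category_floor = 1L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  needed <- c("rater_id", "item_id", "dimension", "round", "rating")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop_navcog("ratings file lacks columns: ", paste(missing, collapse = ", "),
                class = "navcog_validation_error")
  }
  if (nrow(tab) == 0L) {
    stop_navcog("ratings file is empty", class = "navcog_validation_error")
  }
  rating <- suppressWarnings(as.integer(tab$rating))
  bad_int <- which(is.na(rating) | tab$rating != as.character(rating))
  if (length(bad_int) > 0) {
    stop_navcog("non-integer rating at row(s) ",
                paste(bad_int, collapse = ", "), " (column `rating`)",
                class = "navcog_validation_error")
  }
  lo <- category_floor
  hi <- category_floor + n_categories - 1L
  bad <- which(rating < lo | rating > hi)
  if (length(bad) > 0) {
    stop_navcog(sprintf("rating outside declared scale %d..%d at row(s) %s (column `rating`)",
                        lo, hi, paste(bad, collapse = ", ")),
                class = "navcog_validation_error")
  }
  key <- paste(tab$rater_id, tab$item_id, tab$dimension, tab$round, sep = "\r")
  if (anyDuplicated(key)) {
    stop_navcog("duplicate (rater, item, dimension, round) at row(s) ",
                paste(which(duplicated(key)), collapse = ", "),
                class = "navcog_validation_error")
  }
  tab$rating <- rating
  tab$round <- as.integer(tab$round)
  attr(tab, "n_categories") <- n_categories
  attr(tab, "category_floor") <- category_floor
  tab
}

#' Pivot long ratings into a rating matrix
#'
#' @param ratings Long table from [read_ratings()].
#' @param dimension,round Which slice to pivot.
#' @return A [rating_matrix()].
#' @export
ratings_to_matrix <- function(ratings, dimension = "relevance", round = 1L) {
  sub <- ratings[ratings$dimension == dimension & ratings$round == round, ]
  if (nrow(sub) == 0L) {
    stop_navcog("no ratings for dimension `", dimension, "`, round ", round,
                class = "navcog_validation_error")
  }
  raters <- sort(unique(sub$rater_id))
  items <- unique(sub$item_id)
  m <- matrix(NA_integer_, length(raters), length(items),
              dimnames = list(raters, items))
  m[cbind(match(sub$rater_id, raters), match(sub$item_id, items))] <- sub$rating
  rating_matrix(m,
                n_categories = attr(ratings, "n_categories") %||% 4L,
                category_floor = attr(ratings, "category_floor") %||% 1L,
                dimension = dimension, round = round)
}

#' Read a questionnaire response table (CSV, wide or long)
#'
#' Wide format: `respondent_id, group, round, item_1..item_k`. Long format:
#' `respondent_id, group, round, item_id, rating` (plus optional
#' `criterion` and `rater_class` columns, kept for ergonomics scoring).
#' Long input is pivoted so both formats parse to the same wide table.
#'
#' @param path CSV path.
#' @param scale_max Largest admissible rating.
#' @return Wide data frame; long-only columns (`criterion`, `rater_class`)
#'   are carried in attribute `long` holding the original long table.
#' @export
read_questionnaire <- function(path, scale_max = 7L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(tab) == 0L) {
    stop_navcog("questionnaire file is empty",
                class = "navcog_validation_error")
  }
  is_long <- all(c("item_id", "rating") %in% names(tab))
  if (!is_long) {
    item_cols <- grep("^item_\\d+$", names(tab), value = TRUE)
    if (length(item_cols) == 0L) {
      stop_navcog("no item columns (item_1..) or long-format columns found",
                  class = "navcog_validation_error")
    }
    vals <- as.matrix(tab[, item_cols])
    bad <- which(vals < 1 | vals > scale_max, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_navcog(sprintf("rating outside 1..%d at row %d, column %s",
                          scale_max, bad[1, 1], item_cols[bad[1, 2]]),
                  class = "navcog_validation_error")
    }
    return(tab)
  }
  bad <- which(tab$rating < 1 | tab$rating > scale_max)
  if (length(bad) > 0) {
    stop_navcog(sprintf("rating outside 1..%d at row(s) %s (column `rating`)",
                        scale_max, paste(bad, collapse = ", ")),
                class = "navcog_validation_error")
  }
  key <- paste(tab$respondent_id, tab$item_id,
               tab$round %||% 1L, sep = "\r")
  if (anyDuplicated(key)) {
    stop_navcog("duplicate (respondent, item, round) at row(s) ",
                paste(which(duplicated(key)), collapse = ", "),
                class = "navcog_validation_error")
  }
  ids <- unique(tab$respondent_id)
  items <- sort(unique(as.integer(sub("^item_", "", tab$item_id))))
  wide <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (extra in c("group", "round", "rater_class")) {
    if (extra %in% names(tab)) {
      wide[[extra]] <- tab[[extra]][match(ids, tab$respondent_id)]
    }
  }
  for (it in items) {
    col <- paste0("item_", it)
    sel <- tab$item_id == col
    wide[[col]] <- tab$rating[sel][match(ids, tab$respondent_id[sel])]
  }
  attr(wide, "long") <- tab
  wide
}

#' Write a run manifest next to generated outputs
#'
#' Records the effective configuration, the seed, and the package version:
#' enough to regenerate the directory's contents exactly.
#'
#' @param dir Output directory.
#' @param config Named list of effective parameters.
#' @param seed Integer seed used.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed) {
  path <- file.path(dir, "manifest.json")
  payload <- list(
    tool = "navcog",
    version = as.character(utils::packageVersion("navcog")),
    seed = seed,
    config = config,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  tmp <- tempfile("manifest_", tmpdir = dir, fileext = ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
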