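#' CSV data layout for CANID trial and score files
#'
#' All battery files are UTF-8 comma-separated with a mandatory header row.
#' Missing values are empty fields; booleans are lowercase `true`/`false`.
#' One row per trial administration; `repeat_of` holds the `index` of an
#' earlier administration that this row replaces (a trial re-run after a
#' motivator trial following a no-choice / no-response).  Only the final
#' administration of a trial is scored.
#'
#' Expected columns:
#' * `dogs.csv`: dog_id, sex, neuter_status, weight_kg, breed_class
#' * `sessions.csv`: dog_id, timepoint, test_age_years, location,
#'   vision_pass, hearing_pass
#' * `sr_trials.csv`: dog_id, timepoint, index, phase, block_index,
#'   open_side, response, repeat_of
#' * `ds_trials.csv`: dog_id, timepoint, index, trial_type, baited_location,
#'   first_search, repeat_of
#' * `cyl_trials.csv`: dog_id, timepoint, index, responded,
#'   touched_exterior, repeat_of
#' * `scores.csv`: dog_id, timepoint, test_age_years, sex, location,
#'   sr_score, ds_score, cyl_score, overall_score, sr_imputed, ds_imputed,
#'   cyl_imputed
#'
#' @name canid-files
NULL

TRIAL_COLUMNS <- list(
  sr  = c("dog_id", "timepoint", "index", "phase", "block_index",
          "open_side", "response", "repeat_of"),
  ds  = c("dog_id", "timepoint", "index", "trial_type", "baited_location",
          "first_search", "repeat_of"),
  cyl = c("dog_id", "timepoint", "index", "responded", "touched_exterior",
          "repeat_of")
)

SCORE_COLUMNS <- c("dog_id", "timepoint", "test_age_years", "sex", "location",
                   "sr_score", "ds_score", "cyl_score", "overall_score",
                   "sr_imputed", "ds_imputed", "cyl_imputed")

parse_bool <- function(x, what, path) {
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% "true"] <- TRUE
  out[x %in% "false"] <- FALSE
  bad <- !is.na(x) & nzchar(x) & !(x %in% c("true", "false"))
  if (any(bad)) {
    format_error(sprintf("column '%s' in '%s' must be true/false, got: %s",
                         what, path, paste(unique(x[bad]), collapse = ", ")))
  }
  as.logical(out)
}

fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

read_canid_csv <- function(path, cols) {
  if (!file.exists(path)) format_error(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        check.names = FALSE)
  assert_cols(df, cols, path)
  df[, cols, drop = FALSE]
}

as_int <- function(x, what, path) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(out <- as.integer(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    format_error(sprintf("column '%s' in '%s' must be integer, got: %s",
                         what, path, paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

as_num <- function(x, what, path) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(out <- as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    format_error(sprintf("column '%s' in '%s' must be numeric, got: %s",
                         what, path, paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Read dog and session metadata
#'
#' @param path path to a `dogs.csv` / `sessions.csv` file (see
#'   [canid-files]).
#' @return a validated data frame.
#' @export
read_dogs <- function(path) {
  df <- read_canid_csv(path, c("dog_id", "sex", "neuter_status", "weight_kg",
                               "breed_class"))
  df$weight_kg <- as_num(df$weight_kg, "weight_kg", path)
  if (anyDuplicated(df$dog_id)) {
    validation_error(sprintf("duplicate dog_id in '%s': %s", path,
                             paste(unique(df$dog_id[duplicated(df$dog_id)]),
                                   collapse = ", ")))
  }
  assert_in(df$sex, c("female", "male"), "sex", path)
  assert_in(df$neuter_status, c("intact", "altered"), "neuter_status", path)
  assert_in(df$breed_class, c("mixed", "purebred"), "breed_class", path)
  if (any(!is.na(df$weight_kg) & df$weight_kg <= 0)) {
    validation_error(sprintf("non-positive weight_kg in '%s'", path))
  }
  df
}

#' @rdname read_dogs
#' @export
read_sessions <- function(path) {
  df <- read_canid_csv(path, c("dog_id", "timepoint", "test_age_years",
                               "location", "vision_pass", "hearing_pass"))
  df$test_age_years <- as_num(df$test_age_years, "test_age_years", path)
  df$vision_pass <- parse_bool(df$vision_pass, "vision_pass", path)
  df$hearing_pass <- parse_bool(df$hearing_pass, "hearing_pass", path)
  assert_in(df$timepoint, CANID_TIMEPOINTS, "timepoint", path)
  assert_in(df$location, CANID_LOCATIONS, "location", path)
  key <- paste(df$dog_id, df$timepoint)
  if (anyDuplicated(key)) {
    validation_error(sprintf("more than one session per (dog_id, timepoint) in '%s': %s",
                             path, key[duplicated(key)][1]))
  }
  # vision failure is an exclusion criterion: scored sessions must pass
  if (any(!df$vision_pass, na.rm = TRUE)) {
    validation_error(sprintf("'%s' contains sessions with vision_pass=false; %s",
                             path, "vision failure is an exclusion criterion"))
  }
  if (any(!is.na(df$test_age_years) & df$test_age_years <= 0)) {
    validation_error(sprintf("non-positive test_age_years in '%s'", path))
  }
  df
}

#' Read trial-level records for one task
#'
#' Reads and validates a trial CSV for the Spatial Reversal (`"sr"`),
#' Delayed Search (`"ds"`) or Cylinder (`"cyl"`) task.  All session-level
#' protocol invariants are enforced (block structure and side alternation
#' for Spatial Reversal; trial-type counts, reward-location balance, and the
#' no-consecutive-repeat rule for Delayed Search; the four-trial cap for
#' Cylinder).  Validation failures identify the offending
#' (dog_id, timepoint, index).
#'
#' @param path path to the trial CSV.
#' @param task one of `"sr"`, `"ds"`, `"cyl"`.
#' @return a validated data frame of trial administrations, ordered by
#'   (dog_id, timepoint, index).
#' @export
read_trials <- function(path, task = c("sr", "ds", "cyl")) {
  task <- match.arg(task)
  df <- read_canid_csv(path, TRIAL_COLUMNS[[task]])
  df$index <- as_int(df$index, "index", path)
  df$repeat_of <- as_int(df$repeat_of, "repeat_of", path)
  if (task == "sr") {
    df$block_index <- as_int(df$block_index, "block_index", path)
    assert_in(df$phase, c("baseline", "reversal"), "phase", path)
    assert_in(df$open_side, c("left", "right"), "open_side", path)
    assert_in(df$response, c("open", "closed", "no_choice"), "response", path)
  } else if (task == "ds") {
    df$baited_location <- as_int(df$baited_location, "baited_location", path)
    assert_in(df$trial_type, DS_TRIAL_TYPES, "trial_type", path)
    assert_in(df$first_search, c("1", "2", "3", "4", "no_choice"),
              "first_search", path)
  } else {
    df$responded <- parse_bool(df$responded, "responded", path)
    df$touched_exterior <- parse_bool(df$touched_exterior, "touched_exterior", path)
  }
  df <- df[order(df$dog_id, df$timepoint, df$index), , drop = FALSE]
  rownames(df) <- NULL
  for (key in unique(paste(df$dog_id, df$timepoint, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$dog_id == parts[1] & df$timepoint == parts[2], , drop = FALSE]
    validate_session_trials(sub, task, parts[1], parts[2])
  }
  df
}

where_msg <- function(dog, tp, idx) sprintf("(dog_id=%s, timepoint=%s, index=%s)", dog, tp, idx)

validate_session_trials <- function(sub, task, dog, tp) {
  if (anyDuplicated(sub$index)) {
    validation_error(sprintf("duplicate trial index %s",
                             where_msg(dog, tp, sub$index[duplicated(sub$index)][1])))
  }
  bad_rep <- !is.na(sub$repeat_of) &
    (!(sub$repeat_of %in% sub$index) | sub$repeat_of >= sub$index)
  if (any(bad_rep)) {
    validation_error(sprintf("repeat_of must reference an earlier trial index %s",
                             where_msg(dog, tp, sub$index[bad_rep][1])))
  }
  fin <- final_administrations(sub)
  switch(task,
    sr  = validate_sr_session(fin, dog, tp),
    ds  = validate_ds_session(fin, dog, tp),
    cyl = validate_cyl_session(fin, dog, tp))
  invisible(TRUE)
}

validate_sr_session <- function(fin, dog, tp) {
  bad <- (fin$phase == "baseline") != (fin$block_index == 0L)
  if (any(bad, na.rm = TRUE)) {
    validation_error(sprintf("block_index 0 must coincide with baseline phase %s",
                             where_msg(dog, tp, fin$index[bad][1])))
  }
  if (any(fin$block_index > 3L, na.rm = TRUE)) {
    validation_error(sprintf("block_index beyond 3 %s",
                             where_msg(dog, tp, fin$index[fin$block_index > 3L][1])))
  }
  blocks <- unique(fin$block_index)
  side_of <- vapply(blocks, function(b) {
    sides <- unique(fin$open_side[fin$block_index == b])
    if (length(sides) > 1L) {
      validation_error(sprintf("open_side not constant within block %d %s",
                               b, where_msg(dog, tp, fin$index[fin$block_index == b][1])))
    }
    sides
  }, character(1))
  blocks_sorted <- sort(blocks)
  if (length(blocks_sorted) > 1L) {
    s <- side_of[match(blocks_sorted, blocks)]
    if (any(s[-1] == s[-length(s)])) {
      b <- blocks_sorted[-1][which(s[-1] == s[-length(s)])[1]]
      validation_error(sprintf("open_side must alternate between consecutive blocks (block %d) %s",
                               b, where_msg(dog, tp, fin$index[fin$block_index == b][1])))
    }
  }
  # block indices appear in administration order
  if (is.unsorted(fin$block_index)) {
    validation_error(sprintf("block_index must be nondecreasing over trials %s",
                             where_msg(dog, tp, fin$index[1])))
  }
}

validate_ds_session <- function(fin, dog, tp) {
  counts <- table(factor(fin$trial_type, levels = DS_TRIAL_TYPES))
  over <- counts > DS_TYPE_COUNTS[DS_TRIAL_TYPES]
  if (any(over)) {
    validation_error(sprintf("too many scored '%s' trials (%d > %d) %s",
                             DS_TRIAL_TYPES[over][1], counts[over][1],
                             DS_TYPE_COUNTS[DS_TRIAL_TYPES][over][1],
                             where_msg(dog, tp, fin$index[1])))
  }
  if (any(!is.na(fin$baited_location) & !(fin$baited_location %in% 1:4))) {
    validation_error(sprintf("baited_location must be 1..4 %s", where_msg(dog, tp, fin$index[1])))
  }
  loc <- fin$baited_location
  if (length(loc) > 1L) {
    same <- loc[-1] == loc[-length(loc)]
    if (any(same, na.rm = TRUE)) {
      validation_error(sprintf("baited_location equal on consecutive scored trials %s",
                               where_msg(dog, tp, fin$index[-1][which(same)[1]])))
    }
  }
  if (nrow(fin) == 12L) {
    tab <- table(factor(loc, levels = 1:4))
    if (any(tab != 3L)) {
      validation_error(sprintf("complete session must bait each location exactly 3 times %s",
                               where_msg(dog, tp, fin$index[1])))
    }
  }
}

validate_cyl_session <- function(fin, dog, tp) {
  if (nrow(fin) > 4L) {
    validation_error(sprintf("more than 4 scored Cylinder trials %s",
                             where_msg(dog, tp, fin$index[5])))
  }
  bad <- !is.na(fin$responded) & !fin$responded & !is.na(fin$touched_exterior)
  if (any(bad)) {
    validation_error(sprintf("touched_exterior defined on a non-responded trial %s",
                             where_msg(dog, tp, fin$index[bad][1])))
  }
}

#' Keep only the final administration of each trial
#'
#' Administrations superseded by a later repeat (rows whose `index` appears
#' in another row's `repeat_of`) are dropped; only the last administration of
#' each trial is scored.
#'
#' @param trials trial data frame for a single session, ordered by index.
#' @return the scored subset, in administration order.
#' @export
final_administrations <- function(trials) {
  if (!nrow(trials)) return(trials)
  superseded <- trials$index %in% trials$repeat_of[!is.na(trials$repeat_of)]
  out <- trials[!superseded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write long-format score tables
#'
#' `write_scores()` serializes a dog-by-timepoint score table using the
#' battery CSV dialect (empty fields for missing values, lowercase booleans,
#' full-precision numerics) so that `read_scores()` recovers the table
#' exactly.  Score columns are expected to be baseline-standardized; a
#' column whose spread is statistically incompatible with unit standard
#' deviation triggers a warning but is still written.
#'
#' @param path file path.
#' @param table a score table with the columns of `scores.csv` (see
#'   [canid-files]).
#' @return `read_scores()` returns the validated table; `write_scores()`
#'   returns `invisible(path)`.
#' @export
read_scores <- function(path) {
  df <- read_canid_csv(path, SCORE_COLUMNS)
  for (col in c("test_age_years", "sr_score", "ds_score", "cyl_score", "overall_score")) {
    df[[col]] <- as_num(df[[col]], col, path)
  }
  for (col in c("sr_imputed", "ds_imputed", "cyl_imputed")) {
    df[[col]] <- parse_bool(df[[col]], col, path)
  }
  assert_in(df$timepoint, CANID_TIMEPOINTS, "timepoint", path)
  assert_in(df$location, CANID_LOCATIONS, "location", path)
  assert_in(df$sex, c("female", "male"), "sex", path)
  n_obs <- rowSums(!is.na(df[, c("sr_score", "ds_score", "cyl_score")]))
  bad <- !is.na(df$overall_score) & n_obs < 2L
  if (any(bad)) {
    validation_error(sprintf(
      "overall_score present with more than one task score missing (dog_id=%s, timepoint=%s)",
      df$dog_id[bad][1], df$timepoint[bad][1]))
  }
  df
}

#' @rdname read_scores
#' @export
write_scores <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(SCORE_COLUMNS, names(table))
  if (length(missing)) {
    validation_error(sprintf("score table is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  for (col in c("sr_score", "ds_score", "cyl_score", "overall_score")) {
    x <- table[[col]][!is.na(table[[col]])]
    n <- length(x)
    if (n >= 10L) {
      s <- stats::sd(x)
      lim <- sqrt(stats::qchisq(c(5e-4, 1 - 5e-4), n - 1) / (n - 1))
      if (s < lim[1] || s > lim[2]) {
        warning(sprintf("column '%s' has SD %.3f, far from 1 for n=%d; writing anyway",
                        col, s, n), call. = FALSE)
      }
    }
  }
  out <- table[, SCORE_COLUMNS, drop = FALSE]
  for (col in c("test_age_years", "sr_score", "ds_score", "cyl_score", "overall_score")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  for (col in c("sr_imputed", "ds_imputed", "cyl_imputed")) {
    out[[col]] <- fmt_bool(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write trial-level records
#'
#' Inverse of [read_trials()]: serializes a trial data frame in the battery
#' CSV dialect so that `read_trials()` recovers it exactly.
#'
#' @inheritParams read_trials
#' @param trials a trial data frame with the columns for `task`.
#' @return `invisible(path)`.
#' @export
write_trials <- function(trials, path, task = c("sr", "ds", "cyl")) {
  task <- match.arg(task)
  cols <- TRIAL_COLUMNS[[task]]
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    validation_error(sprintf("trial table is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  out <- trials[, cols, drop = FALSE]
  out$repeat_of <- ifelse(is.na(out$repeat_of), "", as.character(out$repeat_of))
  if (task == "cyl") {
    out$responded <- fmt_bool(out$responded)
    out$touched_exterior <- fmt_bool(out$touched_exterior)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_dogs
#' @param dogs,sessions data frames in the layout of `dogs.csv` /
#'   `sessions.csv`.
#' @export
write_dogs <- function(dogs, path) {
  out <- dogs[, c("dog_id", "sex", "neuter_status", "weight_kg", "breed_class")]
  out$weight_kg <- fmt_num(out$weight_kg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_dogs
#' @export
write_sessions <- function(sessions, path) {
  out <- sessions[, c("dog_id", "timepoint", "test_age_years", "location",
                      "vision_pass", "hearing_pass")]
  out$test_age_years <- fmt_num(out$test_age_years)
  out$vision_pass <- fmt_bool(out$vision_pass)
  out$hearing_pass <- fmt_bool(out$hearing_pass)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
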