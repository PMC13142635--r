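#' First trial at which a sliding-window criterion is met
#'
#' The Spatial Reversal task advances to the next block once the dog first
#' approaches the open path on at least `required` of `window` consecutive
#' scored trials.  This helper scans an ordered outcome sequence and returns
#' the earliest trial position `t >= window` whose trailing window of
#' `window` outcomes contains at least `required` successes.
#'
#' @param outcomes logical vector of per-trial successes, in order.
#' @param window window length in trials (default 4).
#' @param required successes required within the window (default 3).
#' @return the 1-based position of the criterion-meeting trial, or `NA_integer_`
#'   if the criterion is never met.
#' @examples
#' criterion_met(c(TRUE, TRUE, TRUE, FALSE))   # 4
#' criterion_met(rep(FALSE, 5))                # NA
#' @export
criterion_met <- function(outcomes, window = 4L, required = 3L) {
  stopifnot(length(outcomes) >= 1L, window >= required, required >= 1L)
  outcomes <- as.logical(outcomes)
  if (anyNA(outcomes)) validation_error("criterion outcomes must be TRUE/FALSE")
  n <- length(outcomes)
  if (n < window) return(NA_integer_)
  cs <- cumsum(outcomes)
  hits <- cs[window:n] - c(0, cs)[(window:n) - window + 1L]
  t <- which(hits >= required)
  if (!length(t)) NA_integer_ else as.integer(t[1] + window - 1L)
}

#' Score a Spatial Reversal trial sequence
#'
#' Computes the task's three dependent measures from one session's ordered
#' trial administrations:
#'
#' * `blocks_completed` -- blocks in which the 3-of-4 criterion was met
#'   (baseline block plus up to 3 reversal blocks; range 0--4, lower = worse),
#' * `longest_block` -- trials in the single longest block entered, baseline
#'   included (range 4--20, higher = worse),
#' * `trials_remaining` -- unused reversal trials out of the 20 allotted
#'   (lower = worse).
#'
#' Only final administrations are scored (no-choice trials and their
#' motivator repeats are replaced by the repeated administration and do not
#' consume trials from the caps).  A dog that never meets the baseline
#' criterion within 20 scored baseline trials does not enter the reversal
#' phase and receives the worst possible score: 0 blocks, longest block 20,
#' 0 trials remaining.  The reversal phase ends after 3 completed reversal
#' blocks or 20 scored reversal trials, whichever comes first; a block cut
#' short by the cap counts toward `longest_block` (it was entered) but not
#' toward `blocks_completed`.
#'
#' A sequence that stops before the protocol resolves (criterion unmet and
#' cap unreached, e.g. testing aborted because the dog became fearful) yields
#' `aborted = TRUE` with all measures `NA`.
#'
#' @param trials data frame of one session's `sr_trials.csv` rows (see
#'   [canid-files]), ordered by `index`.
#' @return a list of class `sr_measures`: `blocks_completed`,
#'   `longest_block`, `trials_remaining`, `baseline_failed`, `aborted`.
#' @export
score_spatial_reversal <- function(trials) {
  empty <- list(blocks_completed = NA_integer_, longest_block = NA_integer_,
                trials_remaining = NA_integer_, baseline_failed = NA,
                aborted = TRUE)
  class(empty) <- "sr_measures"
  if (is.null(trials) || !nrow(trials)) return(empty)

  fin <- final_administrations(trials)
  fin <- fin[fin$response != "no_choice", , drop = FALSE]  # terminal no-choices unscored
  if (!nrow(fin)) return(empty)

  base <- fin[fin$phase == "baseline", , drop = FALSE]
  rev  <- fin[fin$phase == "reversal", , drop = FALSE]
  if (nrow(base) > 20L) {
    validation_error("more than 20 scored baseline trials in Spatial Reversal")
  }
  if (nrow(rev) > 20L) {
    validation_error("more than 20 scored reversal trials in Spatial Reversal")
  }

  base_ok <- base$response == "open"
  base_crit <- if (nrow(base)) criterion_met(base_ok) else NA_integer_

  if (is.na(base_crit)) {
    if (nrow(base) < 20L || nrow(rev) > 0L) return(empty)  # stopped mid-protocol
    out <- list(blocks_completed = 0L, longest_block = 20L,
                trials_remaining = 0L, baseline_failed = TRUE, aborted = FALSE)
    class(out) <- "sr_measures"
    return(out)
  }
  if (base_crit < nrow(base)) {
    validation_error("baseline trials continue past the criterion-meeting trial")
  }

  block_lengths <- base_crit          # baseline block length
  blocks_completed <- 1L
  rev_used <- 0L

  if (nrow(rev)) {
    for (b in sort(unique(rev$block_index))) {
      blk <- rev[rev$block_index == b, , drop = FALSE]
      ok <- blk$response == "open"
      crit <- criterion_met(ok)
      if (!is.na(crit)) {
        if (crit < nrow(blk)) {
          validation_error(sprintf("reversal block %d continues past its criterion-meeting trial", b))
        }
        blocks_completed <- blocks_completed + 1L
        block_lengths <- c(block_lengths, crit)
        rev_used <- rev_used + crit
      } else {
        # entered but not completed: legal only if the 20-trial cap ended it
        block_lengths <- c(block_lengths, nrow(blk))
        rev_used <- rev_used + nrow(blk)
        if (rev_used < 20L) return(empty)  # stopped mid-protocol
      }
    }
  }
  reversals_done <- blocks_completed - 1L
  if (reversals_done < 3L && rev_used < 20L) return(empty)  # protocol unresolved

  out <- list(blocks_completed = blocks_completed,
              longest_block = max(block_lengths),
              trials_remaining = 20L - rev_used,
              baseline_failed = FALSE, aborted = FALSE)
  class(out) <- "sr_measures"
  out
}

#' Score a Delayed Search trial set
#'
#' Computes the proportion of correct first searches within each of the five
#' trial types (no delay; 10 s; 10 s, 20 s, 40 s with distraction).  A trial
#' is correct when the first location searched equals the baited location;
#' terminal no-choice trials (no search even after the permitted motivator
#' repeat) are unscored and leave their trial type's denominator reduced.  A
#' trial type with no scored trials yields `NA` (imputed downstream).  The
#' task is flagged discontinued when four or more no-choices accumulated.
#'
#' @param trials data frame of one session's `ds_trials.csv` rows.
#' @return a list of class `ds_measures`: `prop_by_type` (named length-5
#'   numeric), `n_no_choice`, `discontinued`.
#' @export
score_delayed_search <- function(trials) {
  if (is.null(trials)) trials <- data.frame()
  n_nc <- if (nrow(trials)) sum(trials$first_search == "no_choice") else 0L
  fin <- if (nrow(trials)) final_administrations(trials) else trials
  prop <- setNames(rep(NA_real_, 5L), DS_TRIAL_TYPES)
  if (nrow(trials)) {
    scored <- fin[fin$first_search != "no_choice", , drop = FALSE]
    for (ty in DS_TRIAL_TYPES) {
      sub <- scored[scored$trial_type == ty, , drop = FALSE]
      if (nrow(sub) > DS_TYPE_COUNTS[[ty]]) {
        validation_error(sprintf("more than %d scored '%s' trials",
                                 DS_TYPE_COUNTS[[ty]], ty))
      }
      if (nrow(sub)) {
        prop[[ty]] <- sum(as.integer(sub$first_search) == sub$baited_location) / nrow(sub)
      }
    }
  }
  out <- list(prop_by_type = prop, n_no_choice = as.integer(n_nc),
              discontinued = n_nc >= 4L)
  class(out) <- "ds_measures"
  out
}

#' Score a Cylinder trial set
#'
#' The dependent measure is the proportion of the four inhibitory-control
#' trials on which the dog obtained the reward without first touching the
#' exterior of the transparent cylinder.  Dogs responding on three or fewer
#' trials are excluded (measure `NA`).
#'
#' @param trials data frame of one session's `cyl_trials.csv` rows.
#' @return a list of class `cyl_measure`: `prop_success` (NA when excluded),
#'   `n_responded`, `excluded`.
#' @export
score_cylinder <- function(trials) {
  if (is.null(trials)) trials <- data.frame()
  fin <- if (nrow(trials)) final_administrations(trials) else trials
  if (nrow(fin) > 4L) validation_error("more than 4 scored Cylinder trials")
  n_resp <- if (nrow(fin)) sum(fin$responded, na.rm = TRUE) else 0L
  excluded <- n_resp <= 3L
  prop <- NA_real_
  if (!excluded) {
    success <- fin$responded & !fin$touched_exterior
    prop <- sum(success, na.rm = TRUE) / 4
  }
  out <- list(prop_success = prop, n_responded = as.integer(n_resp),
              excluded = excluded)
  class(out) <- "cyl_measure"
  out
}

#' Build a measures table from trial data
#'
#' Applies the three task scorers to every session present in the trial data
#' and returns one row per (dog_id, timepoint) with the raw dependent
#' measures.  Sessions listed in `sessions` but absent from a task's trial
#' data (e.g. task aborted for fear) get `NA` measures for that task.
#'
#' @param sessions session metadata (see [read_sessions()]).
#' @param sr_trials,ds_trials,cyl_trials trial data frames as returned by
#'   [read_trials()]; any may be `NULL`.
#' @return a data frame with columns dog_id, timepoint, sr_blocks,
#'   sr_longest, sr_remaining, sr_available, ds_p_* (5 columns),
#'   ds_discontinued, ds_available, cyl_prop, cyl_available.
#' @export
score_sessions <- function(sessions, sr_trials = NULL, ds_trials = NULL,
                           cyl_trials = NULL) {
  out <- sessions[, c("dog_id", "timepoint"), drop = FALSE]
  n <- nrow(out)
  out$sr_blocks <- out$sr_longest <- out$sr_remaining <- rep(NA_real_, n)
  ds_cols <- paste0("ds_p_", c("nodelay", "d10", "d10x", "d20x", "d40x"))
  for (col in ds_cols) out[[col]] <- rep(NA_real_, n)
  out$ds_discontinued <- rep(FALSE, n)
  out$cyl_prop <- rep(NA_real_, n)

  session_trials <- function(trials, i) {
    if (is.null(trials) || !nrow(trials)) return(NULL)
    sub <- trials[trials$dog_id == out$dog_id[i] &
                  trials$timepoint == out$timepoint[i], , drop = FALSE]
    if (!nrow(sub)) NULL else sub
  }
  for (i in seq_len(n)) {
    st <- session_trials(sr_trials, i)
    if (!is.null(st)) {
      m <- score_spatial_reversal(st)
      if (!m$aborted) {
        out$sr_blocks[i] <- m$blocks_completed
        out$sr_longest[i] <- m$longest_block
        out$sr_remaining[i] <- m$trials_remaining
      }
    }
    dt <- session_trials(ds_trials, i)
    if (!is.null(dt)) {
      m <- score_delayed_search(dt)
      out[i, ds_cols] <- as.list(unname(m$prop_by_type))
      out$ds_discontinued[i] <- m$discontinued
    }
    ct <- session_trials(cyl_trials, i)
    if (!is.null(ct)) {
      m <- score_cylinder(ct)
      out$cyl_prop[i] <- m$prop_success
    }
  }
  out$sr_available <- !is.na(out$sr_blocks)
  out$ds_available <- rowSums(!is.na(out[, ds_cols])) > 0
  out$cyl_available <- !is.na(out$cyl_prop)
  out
}

#' @export
print.sr_measures <- function(x, ...) {
  if (isTRUE(x$aborted)) {
    cat("Spatial Reversal: aborted (measures missing)\n")
  } else {
    cat(sprintf("Spatial Reversal: blocks=%d, longest=%d, remaining=%d%s\n",
                x$blocks_completed, x$longest_block, x$trials_remaining,
                if (isTRUE(x$baseline_failed)) " (baseline failed: worst score)" else ""))
  }
  invisible(x)
}

#' @export
print.ds_measures <- function(x, ...) {
  cat("Delayed Search proportions correct:\n")
  print(round(x$prop_by_type, 3))
  if (x$discontinued) cat(sprintf("discontinued after %d no-choices\n", x$n_no_choice))
  invisible(x)
}

#' @export
print.cyl_measure <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("Cylinder: excluded (%d of 4 trials responded)\n", x$n_responded))
  } else {
    cat(sprintf("Cylinder: proportion success = %.2f\n", x$prop_success))
  }
  invisible(x)
}
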