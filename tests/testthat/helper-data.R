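# small builders for hand-constructed trial frames and score tables

sr_frame <- function(responses, phase, block_index, open_side = NULL,
                     dog = "d1", tp = "baseline") {
  n <- length(responses)
  if (is.null(open_side)) {
    sides <- c("left", "right")
    open_side <- sides[1 + (block_index %% 2)]
  }
  data.frame(dog_id = dog, timepoint = tp, index = seq_len(n),
             phase = phase, block_index = block_index, open_side = open_side,
             response = responses, repeat_of = NA_integer_,
             stringsAsFactors = FALSE)
}

# a full SR session frame from per-block outcome vectors (TRUE = open)
sr_session <- function(baseline_ok, rev_blocks = list(), dog = "d1", tp = "baseline") {
  parts <- list(sr_frame(ifelse(baseline_ok, "open", "closed"),
                         "baseline", 0L, "left", dog, tp))
  side <- "left"
  for (b in seq_along(rev_blocks)) {
    side <- setdiff(c("left", "right"), side)
    parts[[b + 1L]] <- sr_frame(ifelse(rev_blocks[[b]], "open", "closed"),
                                "reversal", b, side, dog, tp)
  }
  out <- do.call(rbind, parts)
  out$index <- seq_len(nrow(out))
  out
}

ds_session <- function(first_search, dog = "d1", tp = "baseline",
                       location_order = c(1, 2, 3, 4, 2, 1, 4, 3, 1, 3, 2, 4)) {
  n <- length(first_search)
  types <- rep(DS_TRIAL_TYPES, times = DS_TYPE_COUNTS[DS_TRIAL_TYPES])[seq_len(n)]
  data.frame(dog_id = dog, timepoint = tp, index = seq_len(n),
             trial_type = types, baited_location = location_order[seq_len(n)],
             first_search = as.character(first_search),
             repeat_of = NA_integer_, stringsAsFactors = FALSE)
}

# first_search vector scoring `correct` per trial against the default order
ds_session_correct <- function(correct, ...) {
  order12 <- c(1, 2, 3, 4, 2, 1, 4, 3, 1, 3, 2, 4)
  fs <- ifelse(correct, order12[seq_along(correct)],
               ((order12[seq_along(correct)]) %% 4) + 1)
  ds_session(fs, ...)
}

cyl_session <- function(responded, touched, dog = "d1", tp = "baseline") {
  data.frame(dog_id = dog, timepoint = tp, index = seq_along(responded),
             responded = responded,
             touched_exterior = ifelse(responded, touched, NA),
             repeat_of = NA_integer_, stringsAsFactors = FALSE)
}

# a valid 3-row score table for round-trip tests
toy_score_table <- function() {
  data.frame(
    dog_id = c("a1", "a2", "a3"),
    timepoint = c("baseline", "baseline", "m6"),
    test_age_years = c(3.25, 11.5, NA),
    sex = c("female", "male", "female"),
    location = c("ACCC", "SSP", "CC"),
    sr_score = c(0.5, -1.25, 0.125),
    ds_score = c(1, NA, -0.5),
    cyl_score = c(-0.75, 0.25, NA),
    overall_score = c(0.25, -0.5, NA),
    sr_imputed = c(FALSE, FALSE, TRUE),
    ds_imputed = c(FALSE, TRUE, FALSE),
    cyl_imputed = c(FALSE, FALSE, NA),
    stringsAsFactors = FALSE)
}

# directly simulated long score table with known variance components
direct_scores <- function(n_dogs, icc, timepoints = c("baseline", "m6"),
                          mu_tp = rep(0, length(timepoints)), ages = NULL,
                          seed = 1) {
  set.seed(seed)
  tau2 <- icc
  sig2 <- 1 - icc
  u <- rnorm(n_dogs, 0, sqrt(tau2))
  if (is.null(ages)) ages <- runif(n_dogs, 1, 16)
  rows <- lapply(seq_along(timepoints), function(j) {
    data.frame(dog_id = sprintf("d%04d", seq_len(n_dogs)),
               timepoint = timepoints[j],
               test_age_years = ages + 0.5 * (j - 1),
               sex = NA_character_, location = NA_character_,
               overall_score = mu_tp[j] + u + rnorm(n_dogs, 0, sqrt(sig2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
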