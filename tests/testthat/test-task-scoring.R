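test_that("criterion_met matches its definition on hand cases", {
  expect_identical(criterion_met(c(TRUE, TRUE, TRUE, FALSE)), 4L)
  expect_identical(criterion_met(c(TRUE, TRUE, TRUE, TRUE)), 4L)
  expect_identical(criterion_met(rep(FALSE, 5)), NA_integer_)
  expect_identical(criterion_met(c(TRUE, TRUE, TRUE)), NA_integer_)  # t >= window
  expect_identical(criterion_met(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)), 5L)
})

test_that("criterion_met equals an exhaustive window scan on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    ok <- runif(sample(4:20, 1)) < runif(1)
    expect_identical(criterion_met(ok), oracle_first_window(ok))
  }
  # alternative window/required settings
  for (i in 1:100) {
    ok <- runif(12) < 0.5
    expect_identical(criterion_met(ok, window = 5L, required = 2L),
                     oracle_first_window(ok, window = 5L, required = 2L))
  }
})

test_that("a dog that never meets baseline criterion receives the worst score", {
  # strict alternation: no window of 4 holds 3 successes
  alt <- sr_session(rep(c(TRUE, FALSE), 10))
  m <- score_spatial_reversal(alt)
  expect_identical(m$blocks_completed, 0L)
  expect_identical(m$longest_block, 20L)
  expect_identical(m$trials_remaining, 0L)
  expect_true(m$baseline_failed)
  expect_false(m$aborted)

  # all-closed works too
  m2 <- score_spatial_reversal(sr_session(rep(FALSE, 20)))
  expect_identical(unlist(m2[1:3]), unlist(m[1:3]))
})

test_that("a perfect dog scores 4 blocks, longest 4, 8 trials remaining", {
  perfect <- sr_session(rep(TRUE, 4),
                        list(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4)))
  m <- score_spatial_reversal(perfect)
  expect_identical(m$blocks_completed, 4L)
  expect_identical(m$longest_block, 4L)
  expect_identical(m$trials_remaining, 8L)
})

test_that("no-choice administrations and their repeats do not affect scoring", {
  resolved <- sr_session(c(TRUE, TRUE, FALSE, TRUE),
                         list(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4)))
  with_nc <- resolved
  with_nc$index <- with_nc$index * 10L
  extra <- with_nc[6, ]
  extra$index <- 55L
  extra$response <- "no_choice"
  with_nc$repeat_of[6] <- 55L
  with_nc <- rbind(with_nc, extra)
  with_nc <- with_nc[order(with_nc$index), ]
  expect_identical(score_spatial_reversal(with_nc)[1:3],
                   score_spatial_reversal(resolved)[1:3])
})

test_that("sequences that stop mid-protocol are flagged aborted", {
  # baseline ends after 7 trials without criterion or cap
  m <- score_spatial_reversal(sr_session(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)))
  expect_true(m$aborted)
  expect_true(is.na(m$blocks_completed))
  # empty input likewise
  expect_true(score_spatial_reversal(NULL)$aborted)
})

test_that("Spatial Reversal scorer equals the replay oracle on simulated protocols", {
  cfg <- canid_sim_config(seed = 1)
  set.seed(77)
  abilities <- rnorm(250, 0, 1.4)
  for (i in seq_along(abilities)) {
    tr <- simulate_sr_trials(abilities[i], cfg, seed = 5000 + i)
    got <- score_spatial_reversal(tr)
    want <- oracle_score_sr(tr)
    expect_false(is.null(want))   # simulator always resolves the protocol
    expect_identical(got$blocks_completed, as.integer(want$blocks))
    expect_identical(got$longest_block, as.integer(want$longest))
    expect_identical(got$trials_remaining, as.integer(want$remaining))
  }
})

test_that("scored reversal trials plus trials remaining always equal 20", {
  cfg <- canid_sim_config(seed = 2)
  set.seed(88)
  for (i in 1:120) {
    tr <- simulate_sr_trials(rnorm(1, 0, 1.5), cfg, seed = 9000 + i)
    m <- score_spatial_reversal(tr)
    if (isTRUE(m$baseline_failed) || isTRUE(m$aborted)) next
    fin <- final_administrations(tr)
    used <- sum(fin$phase == "reversal" & fin$response != "no_choice")
    expect_identical(used + m$trials_remaining, 20L)
  }
})

test_that("faster criterion attainment weakly improves the scored measures", {
  # resolving every block at the 4-trial minimum dominates any slower run:
  # more blocks completed, shorter longest block, more trials remaining
  fast <- score_spatial_reversal(
    sr_session(rep(TRUE, 4), list(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4))))
  slow <- score_spatial_reversal(
    sr_session(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
               list(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                    rep(TRUE, 4), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))))
  expect_gte(fast$blocks_completed, slow$blocks_completed)
  expect_lte(fast$longest_block, slow$longest_block)
  expect_gte(fast$trials_remaining, slow$trials_remaining)
})

test_that("Delayed Search proportions follow the per-type counting rule", {
  all_ok <- score_delayed_search(ds_session_correct(rep(TRUE, 12)))
  expect_equal(unname(all_ok$prop_by_type), rep(1, 5))

  mixed <- score_delayed_search(
    ds_session_correct(c(TRUE, TRUE, FALSE, TRUE, rep(TRUE, 8))))
  expect_equal(unname(mixed$prop_by_type), c(0.75, 1, 1, 1, 1))
  expect_false(mixed$discontinued)
})

test_that("Delayed Search equals the counting oracle with randomly masked trials", {
  set.seed(55)
  for (i in 1:150) {
    correct <- runif(12) < 0.6
    tr <- ds_session_correct(correct)
    # mask a random subset as terminal no-choices
    mask <- runif(12) < 0.2
    tr$first_search[mask] <- "no_choice"
    got <- score_delayed_search(tr)
    expect_equal(unname(got$prop_by_type), unname(oracle_score_ds(tr)))
    expect_identical(got$n_no_choice, as.integer(sum(mask)))
    expect_identical(got$discontinued, sum(mask) >= 4L)
  }
})

test_that("Delayed Search rejects more trials of a type than the protocol allows", {
  tr <- ds_session_correct(rep(TRUE, 12))
  tr$trial_type[5] <- "no_delay"   # five no-delay trials
  expect_error(score_delayed_search(tr), class = "canid_validation_error")
})

test_that("Cylinder proportions and the exclusion rule are exact", {
  m <- score_cylinder(cyl_session(rep(TRUE, 4), c(FALSE, FALSE, FALSE, TRUE)))
  expect_equal(m$prop_success, 0.75)
  expect_false(m$excluded)

  m3 <- score_cylinder(cyl_session(c(TRUE, TRUE, TRUE, FALSE), rep(FALSE, 4)))
  expect_true(m3$excluded)
  expect_true(is.na(m3$prop_success))

  # all 16 response patterns with 4 responses match bit-count enumeration
  for (bits in 0:15) {
    touched <- as.logical(bitwAnd(bits, 2^(0:3)))
    m <- score_cylinder(cyl_session(rep(TRUE, 4), touched))
    expect_equal(m$prop_success, (4 - sum(touched)) / 4)
    expect_equal(m$prop_success, oracle_score_cyl(cyl_session(rep(TRUE, 4), touched)))
  }
})

test_that("scorers are pure: identical inputs give identical outputs", {
  tr <- simulate_sr_trials(0.3, canid_sim_config(seed = 1), seed = 123)
  expect_identical(score_spatial_reversal(tr), score_spatial_reversal(tr))
  ds <- ds_session_correct(c(rep(TRUE, 6), rep(FALSE, 6)))
  expect_identical(score_delayed_search(ds), score_delayed_search(ds))
})

test_that("score_sessions assembles one row per session with NA for absent tasks", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 25, seed = 9))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  expect_identical(nrow(m), nrow(study$sessions))
  # a session absent from sr_trials (fear abort) has NA SR measures
  key_m <- paste(m$dog_id, m$timepoint)
  key_sr <- unique(paste(study$sr_trials$dog_id, study$sr_trials$timepoint))
  absent <- !(key_m %in% key_sr)
  if (any(absent)) expect_true(all(is.na(m$sr_blocks[absent])))
  expect_true(all(m$cyl_prop %in% c(0, 0.25, 0.5, 0.75, 1, NA)))
})
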