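# Behavioral simulator: latent-ability cohort generation plus protocol-
# faithful trial generation for the three tasks, with ground truth recorded
# for parameter-recovery studies.  The latent model is
#   a_it = b0 + b1*age + b2*age^2 + u_i + delta_t + eps_it,
# u_i ~ N(0, tau^2), eps_it ~ N(0, sigma^2); trial outcomes follow logistic
# links from a_it.

#' Simulator configuration
#'
#' Builds a validated configuration for [simulate_canid_study()].  Defaults
#' emulate the study population the battery was developed on: 239 dogs
#' across three test locations, age mean 7 y and SD 4 y (truncated to 1--16
#' with pre-truncation moments adjusted so the realized moments match),
#' follow-up retention of 140/239 at six months and 118/239 at twelve, and
#' modest practice effects at the six-month retest.  Latent-model and
#' task-link parameters control the mapping from a dog's latent cognitive
#' ability to trial outcomes; see the package vignette for how the defaults
#' were chosen.
#'
#' @param n_dogs number of dogs at baseline.
#' @param age_mean,age_sd,age_range target age moments (years) and
#'   truncation bounds.
#' @param loc_probs location sampling probabilities (renormalized).
#' @param p_female probability a dog is female.
#' @param latent list: `b0`, `b1`, `b2` (intercept, linear, quadratic age
#'   coefficients on the raw-years scale), `tau` (between-dog SD), `sigma`
#'   (session residual SD), `delta_m6`, `delta_m12` (practice effects).
#' @param sr,ds,cyl task link parameter lists (see Details in the vignette):
#'   logistic intercepts/slopes, the Spatial Reversal perseveration penalty
#'   and its within-block decay, Delayed Search delay penalties (one per
#'   trial type, nondecreasing), no-choice / no-response rates, and
#'   fear-abort rates.
#' @param retention named probabilities of returning at `m6` and `m12`.
#' @param seed integer seed.
#' @return a validated list of class `canid_sim_config`.
#' @export
canid_sim_config <- function(n_dogs = 239L,
                             age_mean = 7, age_sd = 4, age_range = c(1, 16),
                             loc_probs = c(ACCC = 0.49, CC = 0.13, SSP = 0.33),
                             p_female = 0.5,
                             latent = list(b0 = 0.4, b1 = 0.06, b2 = -0.011,
                                           tau = 0.65, sigma = 0.45,
                                           delta_m6 = 0.23, delta_m12 = 0.04),
                             sr = list(intercept = 1.1, slope = 1.4,
                                       persev = 2.4, persev_decay = 0.55,
                                       no_choice_rate = 0.02, abort_rate = 0.02),
                             ds = list(intercept = 1.4, slope = 1.4,
                                       penalties = c(0, 0.5, 1.0, 1.4, 1.8),
                                       no_choice_rate = 0.015, abort_rate = 0.008,
                                       location_order = c(1, 2, 3, 4, 2, 1, 4, 3, 1, 3, 2, 4)),
                             cyl = list(intercept = 0.2, slope = 1.4,
                                        no_response_rate = 0.01),
                             retention = c(m6 = 140 / 239, m12 = 118 / 239),
                             seed = 1L) {
  ds$location_order <- as.integer(ds$location_order)
  cfg <- list(n_dogs = as.integer(n_dogs), age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, loc_probs = loc_probs / sum(loc_probs),
              p_female = p_female, latent = latent, sr = sr, ds = ds, cyl = cyl,
              retention = retention, seed = as.integer(seed))
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_dogs >= 1, "n_dogs must be >= 1")
  chk(age_sd > 0, "age_sd must be > 0")
  chk(age_range[1] > 0 && age_range[2] > age_range[1], "age_range must be positive and increasing")
  chk(all(cfg$loc_probs >= 0), "loc_probs must be non-negative")
  chk(p_female >= 0 && p_female <= 1, "p_female must be in [0,1]")
  chk(latent$tau > 0 && latent$sigma > 0, "latent tau and sigma must be > 0")
  rates <- c(sr$no_choice_rate, sr$abort_rate, ds$no_choice_rate, ds$abort_rate,
             cyl$no_response_rate, retention)
  chk(all(rates >= 0 & rates <= 1), "all rates/probabilities must be in [0,1]")
  chk(length(ds$penalties) == 5 && !is.unsorted(ds$penalties),
      "ds$penalties must be 5 nondecreasing values")
  chk(length(ds$location_order) == 12 &&
        all(table(factor(ds$location_order, levels = 1:4)) == 3) &&
        all(diff(ds$location_order) != 0),
      "ds$location_order must bait each location 3x with no consecutive repeats")
  if (length(problems)) {
    validation_error(paste("invalid simulator config:", paste(problems, collapse = "; ")))
  }
  class(cfg) <- "canid_sim_config"
  cfg
}

# closed-form moments of a normal truncated to [a, b]
truncnorm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig; be <- (b - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  phi_a <- stats::dnorm(al); phi_b <- stats::dnorm(be)
  m <- mu + sig * (phi_a - phi_b) / Z
  v <- sig^2 * (1 + (al * phi_a - be * phi_b) / Z - ((phi_a - phi_b) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# pre-truncation (mu, sigma) whose truncated moments match the targets
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mm["mean"] - target_mean)^2 + (mm["sd"] - target_sd)^2
  }
  opt <- stats::optim(c(target_mean, log(target_sd)), obj)
  c(mu = opt$par[1], sigma = exp(opt$par[2]))
}

rtruncnorm <- function(n, mu, sig, a, b) {
  u <- stats::runif(n, stats::pnorm(a, mu, sig), stats::pnorm(b, mu, sig))
  stats::qnorm(u, mu, sig)
}

latent_ability <- function(cfg, age, u, timepoint) {
  l <- cfg$latent
  delta <- c(baseline = 0, m6 = l$delta_m6, m12 = l$delta_m12)[timepoint]
  l$b0 + l$b1 * age + l$b2 * age^2 + u + unname(delta)
}

#' Simulate a study cohort
#'
#' Draws a seeded, reproducible population of dogs with demographic
#' covariates, session records at baseline and retained follow-ups, and the
#' latent cognitive ability of every session.  Follow-up dropout is
#' ability-independent (missing completely at random).
#'
#' @param config a [canid_sim_config()].
#' @return a list: `dogs`, `sessions` (both in the battery CSV layouts) and
#'   `truth` (per-session latent abilities, per-dog random intercepts, the
#'   true variance components and fixed effects, and the implied latent
#'   ICC `tau^2 / (tau^2 + sigma^2)`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "canid_sim_config"))
  with_seed(derive_seed(config$seed, "population"), {
    n <- config$n_dogs
    pre <- truncnorm_match(config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2])
    age0 <- rtruncnorm(n, pre["mu"], pre["sigma"],
                       config$age_range[1], config$age_range[2])
    dog_id <- sprintf("d%04d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
    dogs <- data.frame(
      dog_id = dog_id, sex = sex,
      neuter_status = ifelse(stats::runif(n) < 0.91, "altered", "intact"),
      weight_kg = round(exp(stats::rnorm(n, log(22) - 0.111, 0.47)), 1),
      breed_class = ifelse(stats::runif(n) < 0.51, "mixed", "purebred"),
      stringsAsFactors = FALSE)
    loc <- sample(names(config$loc_probs), n, TRUE, config$loc_probs)
    u <- stats::rnorm(n, 0, config$latent$tau)

    keep_m6 <- stats::runif(n) < config$retention["m6"]
    keep_m12 <- stats::runif(n) < config$retention["m12"]
    tp_list <- list(baseline = rep(TRUE, n), m6 = keep_m6, m12 = keep_m12)
    age_off <- c(baseline = 0, m6 = 0.5, m12 = 1)

    sess <- list(); tru <- list()
    for (tp in CANID_TIMEPOINTS) {
      idx <- which(tp_list[[tp]])
      if (!length(idx)) next
      age <- age0[idx] + age_off[[tp]]
      eps <- stats::rnorm(length(idx), 0, config$latent$sigma)
      ability <- latent_ability(config, age, u[idx], tp) + eps
      sess[[tp]] <- data.frame(
        dog_id = dog_id[idx], timepoint = tp, test_age_years = round(age, 2),
        location = loc[idx], vision_pass = TRUE,
        hearing_pass = stats::runif(length(idx)) > 0.05,
        stringsAsFactors = FALSE)
      tru[[tp]] <- data.frame(dog_id = dog_id[idx], timepoint = tp,
                              ability = ability, stringsAsFactors = FALSE)
    }
    sessions <- do.call(rbind, sess)
    rownames(sessions) <- NULL
    truth <- list(
      abilities = do.call(rbind, tru),
      u = stats::setNames(u, dog_id),
      true_icc = config$latent$tau^2 / (config$latent$tau^2 + config$latent$sigma^2),
      fixed = config$latent)
    rownames(truth$abilities) <- NULL
    list(dogs = dogs, sessions = sessions, truth = truth)
  })
}

# -- per-task trial generation --------------------------------------------

new_trial_rows <- function() {
  list(index = integer(), phase = character(), block_index = integer(),
       open_side = character(), response = character(), repeat_of = integer())
}

#' Simulate one Spatial Reversal session
#'
#' Replays the full task protocol for a dog of the given latent ability:
#' a side-choice trial fixes the baseline open side; baseline trials run to
#' the 3-of-4 criterion or the 20-trial cap (cap without criterion ends the
#' task with the worst score); up to three reversal blocks follow under a
#' 20-trial reversal cap.  Per-trial open-side probability is
#' `plogis(intercept + slope * ability - persev * persev_decay^(j-1))` with
#' `j` the scored trial position within a reversal block (no penalty in
#' baseline).  No-choice events occur at the configured rate and are
#' repeated after a motivator trial, the repeat carrying `repeat_of`;
#' no-choice administrations do not consume trials from the caps.
#'
#' @param ability latent ability of the session.
#' @param config a [canid_sim_config()].
#' @param seed integer seed.
#' @return a trial data frame in the `sr_trials.csv` layout (without the
#'   dog_id/timepoint keys).
#' @export
simulate_sr_trials <- function(ability, config, seed = 1L) {
  p <- config$sr
  with_seed(seed, {
    rows <- new_trial_rows()
    idx <- 0L
    emit <- function(phase, block, side, resp, rep_of = NA_integer_) {
      idx <<- idx + 1L
      rows$index <<- c(rows$index, idx)
      rows$phase <<- c(rows$phase, phase)
      rows$block_index <<- c(rows$block_index, block)
      rows$open_side <<- c(rows$open_side, side)
      rows$response <<- c(rows$response, resp)
      rows$repeat_of <<- c(rows$repeat_of, rep_of)
      idx
    }
    administer <- function(phase, block, side, p_open) {
      # repeat after each no-choice (motivator trials are not test trials)
      prev <- NA_integer_
      repeat {
        if (stats::runif(1) < p$no_choice_rate) {
          prev <- emit(phase, block, side, "no_choice", prev)
        } else {
          resp <- if (stats::runif(1) < p_open) "open" else "closed"
          emit(phase, block, side, resp, prev)
          return(resp == "open")
        }
      }
    }
    run_block <- function(phase, block, side, pen_fun, cap) {
      # returns list(met, len): criterion met?, scored trials used
      ok <- logical()
      while (length(ok) < cap) {
        p_open <- stats::plogis(p$intercept + p$slope * ability - pen_fun(length(ok) + 1L))
        ok <- c(ok, administer(phase, block, side, p_open))
        if (length(ok) >= 4L && sum(ok[(length(ok) - 3L):length(ok)]) >= 3L) {
          return(list(met = TRUE, len = length(ok)))
        }
      }
      list(met = FALSE, len = length(ok))
    }

    side0 <- sample(c("left", "right"), 1L)  # side-choice trial outcome
    base <- run_block("baseline", 0L, side0, function(j) 0, 20L)
    if (base$met) {
      rev_used <- 0L
      side <- side0
      for (b in 1:3) {
        side <- setdiff(c("left", "right"), side)
        res <- run_block("reversal", b, side,
                         function(j) p$persev * p$persev_decay^(j - 1L),
                         20L - rev_used)
        rev_used <- rev_used + res$len
        if (!res$met || rev_used >= 20L) break
      }
    }
    as.data.frame(rows, stringsAsFactors = FALSE)
  })
}

#' Simulate one Delayed Search session
#'
#' Twelve test trials in the protocol's fixed trial-type order (four
#' no-delay, two 10-s, then two each of 10-s, 20-s, 40-s with distraction)
#' with the configured fixed baited-location order.  Per-trial
#' `P(correct) = plogis(intercept + slope * ability - penalty[type])`;
#' errors are distributed uniformly over the three unbaited locations.
#' No-choice administrations are repeated after a motivator trial; once four
#' no-choices accumulate, the task is discontinued and remaining trials are
#' not administered.
#'
#' @inheritParams simulate_sr_trials
#' @return a trial data frame in the `ds_trials.csv` layout.
#' @export
simulate_ds_trials <- function(ability, config, seed = 1L) {
  p <- config$ds
  types <- rep(DS_TRIAL_TYPES, times = DS_TYPE_COUNTS[DS_TRIAL_TYPES])
  with_seed(seed, {
    rows <- list(index = integer(), trial_type = character(),
                 baited_location = integer(), first_search = character(),
                 repeat_of = integer())
    idx <- 0L
    n_nc <- 0L
    emit <- function(type, loc, fs, rep_of = NA_integer_) {
      idx <<- idx + 1L
      rows$index <<- c(rows$index, idx)
      rows$trial_type <<- c(rows$trial_type, type)
      rows$baited_location <<- c(rows$baited_location, loc)
      rows$first_search <<- c(rows$first_search, fs)
      rows$repeat_of <<- c(rows$repeat_of, rep_of)
      idx
    }
    for (t in seq_len(12L)) {
      type <- types[t]
      loc <- p$location_order[t]
      p_corr <- stats::plogis(p$intercept + p$slope * ability -
                                p$penalties[match(type, DS_TRIAL_TYPES)])
      prev <- NA_integer_
      repeat {
        if (stats::runif(1) < p$no_choice_rate) {
          n_nc <- n_nc + 1L
          prev <- emit(type, loc, "no_choice", prev)
          if (n_nc >= 4L) break  # discontinued
        } else {
          fs <- if (stats::runif(1) < p_corr) loc else sample(setdiff(1:4, loc), 1L)
          emit(type, loc, as.character(fs), prev)
          break
        }
      }
      if (n_nc >= 4L) break
    }
    as.data.frame(rows, stringsAsFactors = FALSE)
  })
}

#' Simulate one Cylinder session
#'
#' Four inhibitory-control trials with
#' `P(success) = plogis(intercept + slope * ability)`; failures touch the
#' exterior before retrieving the reward.  No-response administrations are
#' repeated after a motivator trial; four accumulated no-responses
#' discontinue the task (leaving fewer than four responded trials, hence
#' exclusion at scoring).
#'
#' @inheritParams simulate_sr_trials
#' @return a trial data frame in the `cyl_trials.csv` layout.
#' @export
simulate_cyl_trials <- function(ability, config, seed = 1L) {
  p <- config$cyl
  with_seed(seed, {
    rows <- list(index = integer(), responded = logical(),
                 touched_exterior = logical(), repeat_of = integer())
    idx <- 0L
    n_nr <- 0L
    emit <- function(resp, touch, rep_of = NA_integer_) {
      idx <<- idx + 1L
      rows$index <<- c(rows$index, idx)
      rows$responded <<- c(rows$responded, resp)
      rows$touched_exterior <<- c(rows$touched_exterior, touch)
      rows$repeat_of <<- c(rows$repeat_of, rep_of)
      idx
    }
    p_succ <- stats::plogis(p$intercept + p$slope * ability)
    for (t in 1:4) {
      prev <- NA_integer_
      repeat {
        if (stats::runif(1) < p$no_response_rate) {
          n_nr <- n_nr + 1L
          prev <- emit(FALSE, NA, prev)
          if (n_nr >= 4L) break
        } else {
          emit(TRUE, stats::runif(1) >= p_succ, prev)
          break
        }
      }
      if (n_nr >= 4L) break
    }
    as.data.frame(rows, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete study
#'
#' Generates the cohort ([simulate_population()]) and trial-level data for
#' every session and task, applying per-task fear-abort rates (an aborted
#' task contributes no trials, so its measures are missing and handled by
#' composite-level imputation).
#'
#' @param config a [canid_sim_config()].
#' @return a list: `dogs`, `sessions`, `sr_trials`, `ds_trials`,
#'   `cyl_trials` (battery CSV layouts) and `truth`.
#' @export
simulate_canid_study <- function(config = canid_sim_config()) {
  pop <- simulate_population(config)
  sess <- pop$sessions
  ab <- pop$truth$abilities
  key <- paste(sess$dog_id, sess$timepoint)
  ability <- ab$ability[match(key, paste(ab$dog_id, ab$timepoint))]

  sr_list <- list(); ds_list <- list(); cyl_list <- list()
  abort_draws <- with_seed(derive_seed(config$seed, "aborts"), {
    matrix(stats::runif(2 * nrow(sess)), ncol = 2)
  })
  for (i in seq_len(nrow(sess))) {
    base_seed <- derive_seed(config$seed, paste0("trials", i))
    if (abort_draws[i, 1] >= config$sr$abort_rate) {
      tr <- simulate_sr_trials(ability[i], config, seed = base_seed)
      if (nrow(tr)) {
        tr <- cbind(dog_id = sess$dog_id[i], timepoint = sess$timepoint[i], tr,
                    stringsAsFactors = FALSE)
        sr_list[[length(sr_list) + 1L]] <- tr
      }
    }
    if (abort_draws[i, 2] >= config$ds$abort_rate) {
      tr <- simulate_ds_trials(ability[i], config, seed = base_seed + 1L)
      if (nrow(tr)) {
        tr <- cbind(dog_id = sess$dog_id[i], timepoint = sess$timepoint[i], tr,
                    stringsAsFactors = FALSE)
        ds_list[[length(ds_list) + 1L]] <- tr
      }
    }
    tr <- simulate_cyl_trials(ability[i], config, seed = base_seed + 2L)
    if (nrow(tr)) {
      tr <- cbind(dog_id = sess$dog_id[i], timepoint = sess$timepoint[i], tr,
                  stringsAsFactors = FALSE)
      cyl_list[[length(cyl_list) + 1L]] <- tr
    }
  }
  bindr <- function(l) {
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  list(dogs = pop$dogs, sessions = sess,
       sr_trials = bindr(sr_list), ds_trials = bindr(ds_list),
       cyl_trials = bindr(cyl_list), truth = pop$truth)
}

#' Write a simulated study to a directory
#'
#' @param study output of [simulate_canid_study()].
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
write_canid_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dogs(study$dogs, file.path(dir, "dogs.csv"))
  write_sessions(study$sessions, file.path(dir, "sessions.csv"))
  write_trials(study$sr_trials, file.path(dir, "sr_trials.csv"), "sr")
  write_trials(study$ds_trials, file.path(dir, "ds_trials.csv"), "ds")
  write_trials(study$cyl_trials, file.path(dir, "cyl_trials.csv"), "cyl")
  jsonlite::write_json(list(true_icc = study$truth$true_icc,
                            fixed = study$truth$fixed,
                            abilities = study$truth$abilities),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
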