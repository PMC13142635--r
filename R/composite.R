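# Baseline-fitted composite scoring: task PCAs -> Yeo-Johnson -> z ->
# overall PCA -> z, all constants estimated on baseline data only and
# reused verbatim when projecting follow-up sessions.

SR_INPUTS <- c("sr_blocks", "sr_longest", "sr_remaining")
DS_INPUTS <- paste0("ds_p_", c("nodelay", "d10", "d10x", "d20x", "d40x"))

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a first-component summary model
#'
#' Principal components analysis on the correlation scale (inputs centered
#' and scaled before rotation), retaining the first component as the summary
#' score.  The component's sign is arbitrary in the eigendecomposition, so
#' the orientation is pinned by requiring a positive loading on
#' `orient_var`.
#'
#' @param x numeric matrix or data frame of complete cases (rows = sessions).
#' @param orient_var column whose loading is forced positive.
#' @return an object of class `canid_pca`: `center`, `scale`, `rotation`,
#'   `sdev`, `orientation_sign`, `var_share` (PC1 share of total variance).
#' @export
fit_pc1 <- function(x, orient_var = colnames(x)[1]) {
  x <- as.matrix(x)
  if (nrow(x) < 10L) fitting_error("need at least 10 complete cases to fit a PCA")
  if (anyNA(x)) fitting_error("PCA inputs must be complete cases")
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    fitting_error(sprintf("constant PCA input column: %s",
                          colnames(x)[scl == 0][1]))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  sgn <- if (p$rotation[orient_var, 1] >= 0) 1 else -1
  out <- list(center = p$center, scale = p$scale, rotation = p$rotation,
              sdev = p$sdev, orientation_sign = sgn,
              var_share = p$sdev[1]^2 / sum(p$sdev^2),
              inputs = colnames(x), orient_var = orient_var)
  class(out) <- "canid_pca"
  out
}

#' @rdname fit_pc1
#' @param object a `canid_pca` model.
#' @param newdata matrix or data frame with the model's input columns.
#' @param ... unused.
#' @return `predict()` returns the oriented first-component score.
#' @export
predict.canid_pca <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$inputs, drop = FALSE])
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(z %*% object$rotation[, 1]) * object$orientation_sign
}

# --- predictive mean matching for Delayed Search trial-type proportions ---

#' Impute Delayed Search trial-type proportions by predictive mean matching
#'
#' For each session with at least one observed and at least one missing
#' trial-type proportion, each missing entry is predicted by a linear
#' regression (fit on the donor pool) of that trial type on the session's
#' observed trial types; the imputed value is the *observed* value of one of
#' the `k` donors whose predictions are nearest the session's prediction,
#' drawn with the seeded generator.  Imputed values therefore always lie in
#' the donor pool's support.
#'
#' @param measures data frame containing the five `ds_p_*` columns.
#' @param pool donor pool: data frame of complete `ds_p_*` rows (baseline
#'   complete cases).
#' @param k number of nearest donors (default 5).
#' @param seed integer seed for the donor draw.
#' @return `measures` with missing `ds_p_*` entries filled and a logical
#'   `ds_imputed` column flagging rows that received any imputation.
#' @export
impute_ds_proportions <- function(measures, pool, k = 5L, seed = 1L) {
  pool <- as.data.frame(pool)[, DS_INPUTS, drop = FALSE]
  pool <- pool[stats::complete.cases(pool), , drop = FALSE]
  m <- as.data.frame(measures)
  obs <- !is.na(as.matrix(m[, DS_INPUTS, drop = FALSE]))
  needs <- rowSums(obs) >= 1L & rowSums(!obs) >= 1L
  m$ds_imputed <- needs
  if (!any(needs)) return(m)
  if (!nrow(pool)) fitting_error("empty donor pool for predictive mean matching")
  with_seed(seed, {
    for (i in which(needs)) {
      pred_cols <- DS_INPUTS[obs[i, ]]
      for (target in DS_INPUTS[!obs[i, ]]) {
        X <- cbind(1, as.matrix(pool[, pred_cols, drop = FALSE]))
        beta <- qr.coef(qr(X), pool[[target]])
        beta[is.na(beta)] <- 0
        yhat_pool <- drop(X %*% beta)
        x_row <- c(1, as.numeric(m[i, pred_cols]))
        yhat_row <- sum(x_row * beta)
        ord <- order(abs(yhat_pool - yhat_row), yhat_pool, seq_along(yhat_pool))
        donors <- ord[seq_len(min(k, length(ord)))]
        pick <- donors[sample.int(length(donors), 1L)]
        m[i, target] <- pool[[target]][pick]
      }
    }
  })
  m
}

# --- deterministic single-task-score imputation (regression prediction) ---

task_imp_design <- function(s1, s2, location) {
  loc <- factor(location, levels = CANID_LOCATIONS)
  cbind(1, s1, s2,
        CC = as.numeric(loc == "CC"),
        SSP = as.numeric(loc == "SSP"))
}

fit_task_imputation <- function(scores) {
  tasks <- c("sr_score", "ds_score", "cyl_score")
  cc <- scores[stats::complete.cases(scores[, tasks]) & !is.na(scores$location), ,
               drop = FALSE]
  models <- list()
  for (t in tasks) {
    others <- setdiff(tasks, t)
    X <- task_imp_design(cc[[others[1]]], cc[[others[2]]], cc$location)
    beta <- qr.coef(qr(X), cc[[t]])
    beta[is.na(beta)] <- 0
    models[[t]] <- list(predictors = others, coef = beta)
  }
  models
}

#' Impute a single missing task score
#'
#' Deterministic regression prediction (no noise term) of the one missing
#' task score from the two observed task scores and test location, using
#' coefficients estimated on baseline complete cases.  Rows with two or more
#' missing task scores are returned unchanged (no overall score is generated
#' for them downstream).
#'
#' @param scores data frame with `sr_score`, `ds_score`, `cyl_score`,
#'   `location`.
#' @param models imputation models from the fitted [canid_fit()] object.
#' @return `scores` with singly-missing task scores filled and
#'   `sr_imputed`/`ds_imputed_score`/`cyl_imputed` logical flags.
#' @keywords internal
impute_task_scores <- function(scores, models) {
  tasks <- c("sr_score", "ds_score", "cyl_score")
  flags <- matrix(FALSE, nrow(scores), 3, dimnames = list(NULL, tasks))
  n_missing <- rowSums(is.na(scores[, tasks, drop = FALSE]))
  for (i in which(n_missing == 1L)) {
    t <- tasks[is.na(as.numeric(scores[i, tasks]))]
    mod <- models[[t]]
    X <- task_imp_design(scores[[mod$predictors[1]]][i],
                         scores[[mod$predictors[2]]][i],
                         scores$location[i])
    scores[i, t] <- drop(X %*% mod$coef)
    flags[i, t] <- TRUE
  }
  attr(scores, "imputed_flags") <- flags
  scores
}

# --- the scoring model ----------------------------------------------------

#' Fit the baseline composite scoring model
#'
#' Using baseline sessions only, fits every component of the battery's
#' scoring system, in order:
#'
#' 1. predictive-mean-matching imputation of missing Delayed Search
#'    trial-type proportions (donor pool = baseline complete cases),
#' 2. task-level PCAs: Spatial Reversal on (blocks completed, longest block,
#'    trials remaining), Delayed Search on the five trial-type proportions;
#'    the first component is the task summary score (Cylinder's single
#'    proportion needs no PCA),
#' 3. Yeo-Johnson normalization of the Spatial Reversal and Delayed Search
#'    component scores (maximum-likelihood lambda) and z-standardization of
#'    all three task scores by their baseline mean/SD,
#' 4. deterministic regression imputation of a single missing task score
#'    from the two observed scores and test location,
#' 5. an overall PCA across the three standardized task scores, whose first
#'    component -- z-standardized on baseline -- is the overall battery
#'    score.  Sessions missing more than one task score get no overall
#'    score.
#'
#' All centers, scales, rotations, lambdas, and standardization constants
#' are frozen at fit time; [predict.canid_model()] projects any session
#' (baseline or follow-up) through them without refitting.
#'
#' @param measures baseline measures table from [score_sessions()].
#' @param sessions baseline session metadata (provides test location and age).
#' @param dogs optional dog metadata (provides sex for the score table).
#' @param pmm_k donors for predictive mean matching (default 5).
#' @param seed seed for the PMM donor draw.
#' @return an object of class `canid_model`; see [predict.canid_model()].
#' @export
canid_fit <- function(measures, sessions, dogs = NULL, pmm_k = 5L, seed = 1L) {
  base_sess <- sessions[sessions$timepoint == "baseline", , drop = FALSE]
  m <- merge(measures, base_sess[, c("dog_id", "timepoint", "test_age_years", "location")],
             by = c("dog_id", "timepoint"))
  if (nrow(m) < 10L) fitting_error("need at least 10 baseline sessions to fit the scoring model")

  ds_pool <- m[stats::complete.cases(m[, DS_INPUTS]), DS_INPUTS, drop = FALSE]
  m <- impute_ds_proportions(m, ds_pool, k = pmm_k, seed = seed)

  sr_cc <- m[stats::complete.cases(m[, SR_INPUTS]), SR_INPUTS, drop = FALSE]
  ds_cc <- m[stats::complete.cases(m[, DS_INPUTS]), DS_INPUTS, drop = FALSE]
  sr_pca <- fit_pc1(sr_cc, orient_var = "sr_blocks")
  ds_pca <- fit_pc1(ds_cc, orient_var = "ds_p_nodelay")

  sr_raw <- ifelse(stats::complete.cases(m[, SR_INPUTS]),
                   predict(sr_pca, m[, SR_INPUTS]), NA_real_)
  ds_raw <- ifelse(stats::complete.cases(m[, DS_INPUTS]),
                   predict(ds_pca, m[, DS_INPUTS]), NA_real_)
  cyl_raw <- m$cyl_prop

  yj_sr <- yj_fit_lambda(sr_raw[!is.na(sr_raw)])
  yj_ds <- yj_fit_lambda(ds_raw[!is.na(ds_raw)])
  sr_t <- yeo_johnson(sr_raw, yj_sr)
  ds_t <- yeo_johnson(ds_raw, yj_ds)

  std <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  sr_std <- std(sr_t); ds_std <- std(ds_t); cyl_std <- std(cyl_raw)

  scores <- data.frame(dog_id = m$dog_id, timepoint = m$timepoint,
                       test_age_years = m$test_age_years, location = m$location,
                       sr_score = (sr_t - sr_std["mean"]) / sr_std["sd"],
                       ds_score = (ds_t - ds_std["mean"]) / ds_std["sd"],
                       cyl_score = (cyl_raw - cyl_std["mean"]) / cyl_std["sd"],
                       stringsAsFactors = FALSE)

  imp_models <- fit_task_imputation(scores)
  scores <- impute_task_scores(scores, imp_models)

  triples <- scores[stats::complete.cases(scores[, c("sr_score", "ds_score", "cyl_score")]), ,
                    drop = FALSE]
  if (nrow(triples) < 3L) fitting_error("fewer than 3 complete task-score triples")
  overall_pca <- fit_pc1(triples[, c("sr_score", "ds_score", "cyl_score")],
                         orient_var = "sr_score")
  overall_raw <- ifelse(
    stats::complete.cases(scores[, c("sr_score", "ds_score", "cyl_score")]),
    predict(overall_pca, scores[, c("sr_score", "ds_score", "cyl_score")]),
    NA_real_)
  ov_std <- std(overall_raw)

  fingerprint <- dataset_fingerprint(measures[, c("dog_id", "timepoint", SR_INPUTS,
                                                  DS_INPUTS, "cyl_prop")])
  model <- structure(list(
    sr_pca = sr_pca, ds_pca = ds_pca, overall_pca = overall_pca,
    transforms = list(yj_lambda_sr = yj_sr, yj_lambda_ds = yj_ds,
                      sr = sr_std, ds = ds_std, cyl = cyl_std,
                      overall = ov_std),
    imputation = imp_models,
    ds_donor_pool = ds_pool,
    pmm_k = as.integer(pmm_k), seed = as.integer(seed),
    fitted_on = fingerprint,
    n_baseline = nrow(m)
  ), class = "canid_model")

  base_measures <- measures[measures$timepoint == "baseline", , drop = FALSE]
  model$baseline_scores <- predict(model, base_measures, base_sess, dogs = dogs,
                                   seed = seed)
  model
}

#' Project sessions into the baseline scoring space
#'
#' Applies the frozen baseline constants (PCA centers/scales/rotations,
#' Yeo-Johnson lambdas, standardization means/SDs, imputation coefficients)
#' to any set of scored sessions.  The model is never refit: projecting the
#' baseline fitting data returns the fitted scores.
#'
#' @param object a fitted `canid_model`.
#' @param measures measures table from [score_sessions()] for any timepoints.
#' @param sessions matching session metadata.
#' @param dogs optional dog metadata contributing the `sex` column.
#' @param seed seed for the PMM donor draw (defaults to the fit seed).
#' @param ... unused.
#' @return a long score table: one row per session with standardized
#'   `sr_score`, `ds_score`, `cyl_score`, `overall_score` and per-task
#'   imputation flags.  `overall_score` is `NA` when more than one task
#'   score is missing.
#' @export
predict.canid_model <- function(object, measures, sessions, dogs = NULL,
                                seed = object$seed, ...) {
  m <- merge(measures, sessions[, c("dog_id", "timepoint", "test_age_years", "location")],
             by = c("dog_id", "timepoint"))
  m <- impute_ds_proportions(m, object$ds_donor_pool, k = object$pmm_k, seed = seed)
  ds_imputed_trials <- m$ds_imputed

  sr_raw <- ifelse(stats::complete.cases(m[, SR_INPUTS]),
                   predict(object$sr_pca, m[, SR_INPUTS]), NA_real_)
  ds_raw <- ifelse(stats::complete.cases(m[, DS_INPUTS]),
                   predict(object$ds_pca, m[, DS_INPUTS]), NA_real_)
  tr <- object$transforms
  sr_s <- (yeo_johnson(sr_raw, tr$yj_lambda_sr) - tr$sr["mean"]) / tr$sr["sd"]
  ds_s <- (yeo_johnson(ds_raw, tr$yj_lambda_ds) - tr$ds["mean"]) / tr$ds["sd"]
  cyl_s <- (m$cyl_prop - tr$cyl["mean"]) / tr$cyl["sd"]

  scores <- data.frame(dog_id = m$dog_id, timepoint = m$timepoint,
                       test_age_years = m$test_age_years, location = m$location,
                       sr_score = unname(sr_s), ds_score = unname(ds_s),
                       cyl_score = unname(cyl_s), stringsAsFactors = FALSE)
  scores <- impute_task_scores(scores, object$imputation)
  flags <- attr(scores, "imputed_flags")

  complete3 <- stats::complete.cases(scores[, c("sr_score", "ds_score", "cyl_score")])
  overall_raw <- ifelse(complete3,
                        predict(object$overall_pca,
                                scores[, c("sr_score", "ds_score", "cyl_score")]),
                        NA_real_)
  scores$overall_score <- (overall_raw - tr$overall["mean"]) / tr$overall["sd"]

  sex <- rep(NA_character_, nrow(scores))
  if (!is.null(dogs)) sex <- dogs$sex[match(scores$dog_id, dogs$dog_id)]
  out <- data.frame(dog_id = scores$dog_id, timepoint = scores$timepoint,
                    test_age_years = scores$test_age_years, sex = sex,
                    location = scores$location,
                    sr_score = scores$sr_score, ds_score = scores$ds_score,
                    cyl_score = scores$cyl_score,
                    overall_score = scores$overall_score,
                    sr_imputed = flags[, "sr_score"],
                    ds_imputed = flags[, "ds_score"] | ds_imputed_trials,
                    cyl_imputed = flags[, "cyl_score"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.canid_model <- function(x, ...) {
  cat("CANID composite scoring model (baseline-fitted)\n")
  cat(sprintf("  baseline sessions: %d\n", x$n_baseline))
  cat(sprintf("  Yeo-Johnson lambdas: SR %.3f, DS %.3f\n",
              x$transforms$yj_lambda_sr, x$transforms$yj_lambda_ds))
  l <- x$overall_pca$rotation[, 1] * x$overall_pca$orientation_sign
  cat(sprintf("  overall PC1 loadings: SR %.2f, DS %.2f, Cyl %.2f (%.1f%% of variance)\n",
              l["sr_score"], l["ds_score"], l["cyl_score"],
              100 * x$overall_pca$var_share))
  invisible(x)
}

#' @export
summary.canid_model <- function(object, ...) {
  cat("CANID composite scoring model\n\n")
  cat("Spatial Reversal PC1 loadings (", sprintf("%.1f%%", 100 * object$sr_pca$var_share),
      " of input variance):\n", sep = "")
  print(round(object$sr_pca$rotation[, 1] * object$sr_pca$orientation_sign, 3))
  cat("\nDelayed Search PC1 loadings (", sprintf("%.1f%%", 100 * object$ds_pca$var_share),
      " of input variance):\n", sep = "")
  print(round(object$ds_pca$rotation[, 1] * object$ds_pca$orientation_sign, 3))
  cat("\nOverall PC1 loadings (", sprintf("%.1f%%", 100 * object$overall_pca$var_share),
      " of variance):\n", sep = "")
  print(round(object$overall_pca$rotation[, 1] * object$overall_pca$orientation_sign, 3))
  cat(sprintf("\nYeo-Johnson lambdas: SR %.4f, DS %.4f\n",
              object$transforms$yj_lambda_sr, object$transforms$yj_lambda_ds))
  invisible(object)
}

#' @export
coef.canid_model <- function(object, ...) {
  list(sr = object$sr_pca$rotation[, 1] * object$sr_pca$orientation_sign,
       ds = object$ds_pca$rotation[, 1] * object$ds_pca$orientation_sign,
       overall = object$overall_pca$rotation[, 1] * object$overall_pca$orientation_sign)
}

#' @export
plot.canid_model <- function(x, ...) {
  bs <- x$baseline_scores
  graphics::plot(bs$test_age_years, bs$overall_score,
                 xlab = "Age at test (years)", ylab = "Overall score (SD units)",
                 main = "Baseline overall scores by age", ...)
  ok <- stats::complete.cases(bs[, c("test_age_years", "overall_score")])
  lo <- stats::lowess(bs$test_age_years[ok], bs$overall_score[ok])
  graphics::lines(lo, lwd = 2)
  invisible(x)
}

# --- JSON (de)serialization ----------------------------------------------

#' Serialize a fitted scoring model to JSON
#'
#' Stores every frozen constant (centers, scales, rotations, lambdas,
#' standardization constants, imputation coefficients, PMM donor pool, and
#' the fingerprint of the fitting data) in a single JSON document so scores
#' can be reproduced elsewhere.
#'
#' @param model a fitted `canid_model`.
#' @param path output file.
#' @return `canid_model_from_json()` returns the restored `canid_model`
#'   (without the cached baseline score table).
#' @export
canid_model_to_json <- function(model, path) {
  pca_out <- function(p) list(center = as.list(p$center), scale = as.list(p$scale),
                              rotation = unclass(as.data.frame(p$rotation)),
                              rotation_rows = rownames(p$rotation),
                              sdev = p$sdev, orientation_sign = p$orientation_sign,
                              var_share = p$var_share, inputs = p$inputs,
                              orient_var = p$orient_var)
  doc <- list(
    package = "canid", object = "canid_model",
    sr_pca = pca_out(model$sr_pca), ds_pca = pca_out(model$ds_pca),
    overall_pca = pca_out(model$overall_pca),
    transforms = lapply(model$transforms, function(v) as.list(v)),
    imputation = lapply(model$imputation, function(m)
      list(predictors = m$predictors, coef = as.list(m$coef))),
    ds_donor_pool = unclass(model$ds_donor_pool),
    pmm_k = model$pmm_k, seed = model$seed,
    fitted_on = model$fitted_on, n_baseline = model$n_baseline)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname canid_model_to_json
#' @export
canid_model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca_in <- function(p) {
    rot <- as.matrix(as.data.frame(p$rotation))
    rownames(rot) <- p$rotation_rows
    structure(list(center = unlist(p$center), scale = unlist(p$scale),
                   rotation = rot, sdev = p$sdev,
                   orientation_sign = p$orientation_sign,
                   var_share = p$var_share, inputs = p$inputs,
                   orient_var = p$orient_var), class = "canid_pca")
  }
  structure(list(
    sr_pca = pca_in(doc$sr_pca), ds_pca = pca_in(doc$ds_pca),
    overall_pca = pca_in(doc$overall_pca),
    transforms = c(list(yj_lambda_sr = doc$transforms$yj_lambda_sr,
                        yj_lambda_ds = doc$transforms$yj_lambda_ds),
                   lapply(doc$transforms[c("sr", "ds", "cyl", "overall")], unlist)),
    imputation = lapply(doc$imputation, function(m)
      list(predictors = m$predictors, coef = unlist(m$coef))),
    ds_donor_pool = as.data.frame(doc$ds_donor_pool),
    pmm_k = doc$pmm_k, seed = doc$seed,
    fitted_on = doc$fitted_on, n_baseline = doc$n_baseline
  ), class = "canid_model")
}
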