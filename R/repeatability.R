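# Repeatability: intraclass correlations from variance components, with
# parametric bootstrap confidence intervals, and Cohen's kappa for
# inter-rater agreement.

icc_result <- function(estimate, ci, method, n, var_id = NA_real_, var_res = NA_real_) {
  est <- max(0, min(1, estimate))
  out <- list(estimate = est,
              ci_low = max(0, min(ci[1], est)),
              ci_high = min(1, max(ci[2], est)),
              method = method, n = n, var_id = var_id, var_res = var_res)
  class(out) <- "canid_icc"
  out
}

#' @export
print.canid_icc <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

# one-way ANOVA variance components for a balanced dog x 2-occasion layout;
# y is an n x 2 matrix
anova_components <- function(y) {
  n <- nrow(y)
  gm <- mean(y)
  row_means <- rowMeans(y)
  msb <- 2 * sum((row_means - gm)^2) / (n - 1)
  msw <- sum((y - row_means)^2) / n
  var_id <- max(0, (msb - msw) / 2)
  c(var_id = var_id, var_res = msw)
}

#' Pairwise (two-timepoint) intraclass correlation
#'
#' Estimates the ICC between two test occasions from the dogs measured at
#' both: variance components of a random-intercept (one-way) model on the
#' balanced complete-pairs subset, estimated by the ANOVA closed form (which
#' coincides with REML for balanced one-way data), with negative
#' between-dog components truncated at zero.  The 95% confidence interval
#' is a percentile parametric bootstrap: dogs are redrawn from the fitted
#' normal components and the ICC re-estimated with the same closed form.
#'
#' @param scores long score table (one row per dog x timepoint).
#' @param t1,t2 the two timepoints to compare (e.g. `"baseline"`, `"m6"`).
#' @param measure score column to analyse (default `"overall_score"`).
#' @param nboot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @return a `canid_icc` object: estimate, CI, variance components, n.
#' @export
pairwise_icc <- function(scores, t1, t2, measure = "overall_score",
                         nboot = 1000L, seed = 1L) {
  a <- scores[scores$timepoint == t1, c("dog_id", measure)]
  b <- scores[scores$timepoint == t2, c("dog_id", measure)]
  m <- merge(a, b, by = "dog_id")
  y <- as.matrix(m[, -1, drop = FALSE])
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y)
  if (n < 10L) {
    stop_canid("canid_insufficient_data",
               sprintf("only %d dogs have '%s' at both %s and %s (need >= 10)",
                       n, measure, t1, t2))
  }
  vc <- anova_components(y)
  est <- vc["var_id"] / (vc["var_id"] + vc["var_res"])
  boot <- with_seed(seed, {
    vapply(seq_len(nboot), function(i) {
      u <- stats::rnorm(n, 0, sqrt(vc["var_id"]))
      ysim <- u + matrix(stats::rnorm(2 * n, 0, sqrt(vc["var_res"])), n, 2)
      v <- anova_components(ysim)
      v["var_id"] / (v["var_id"] + v["var_res"])
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  icc_result(est, ci, "pairwise", n, vc["var_id"], vc["var_res"])
}

#' Model-based intraclass correlation (intercept-only or adjusted)
#'
#' Fits `measure ~ covariates + (1 | dog_id)` by REML and partitions the
#' residual variance: ICC = var(dog) / (var(dog) + var(residual)).  With no
#' covariates this is the unadjusted repeatability R; with age and other
#' covariates it is the adjusted ICC, in which systematic (e.g. age-driven)
#' variance is absorbed by the fixed effects before partitioning.  The 95%
#' CI is a percentile parametric bootstrap (simulate from the fitted model,
#' refit, re-estimate).
#'
#' @param scores long score table.
#' @param measure score column to analyse.
#' @param covariates `NULL` for the intercept-only model, or a one-sided
#'   formula of fixed effects, e.g.
#'   `~ orthogonal_poly(test_age_years, 2) + timepoint + sex + location`.
#' @param nboot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @return a `canid_icc` object.
#' @export
model_icc <- function(scores, measure = "overall_score", covariates = NULL,
                      nboot = 1000L, seed = 1L) {
  df <- prepare_model_frame(scores, measure)
  if (length(unique(df$timepoint)) < 2L) {
    stop_canid("canid_insufficient_data", "need at least 2 timepoints represented")
  }
  rhs <- if (is.null(covariates)) "1" else paste(deparse(covariates[[2]]), collapse = "")
  f <- stats::as.formula(paste(".y ~", rhs, "+ (1 | dog_id)"))
  fit <- lme4::lmer(f, data = df, REML = TRUE)
  vc <- lme4::VarCorr(fit)
  var_id <- as.numeric(vc$dog_id[1, 1])
  var_res <- attr(vc, "sc")^2
  if (var_id <= 1e-10) {
    warning("between-dog variance estimated at the zero boundary; ICC estimate is 0",
            call. = FALSE)
  }
  est <- var_id / (var_id + var_res)
  sims <- stats::simulate(fit, nsim = nboot, seed = derive_seed(seed, "model_icc"))
  boot <- vapply(seq_len(nboot), function(i) {
    refit_i <- suppressWarnings(suppressMessages(lme4::refit(fit, sims[[i]])))
    v <- lme4::VarCorr(refit_i)
    vi <- as.numeric(v$dog_id[1, 1]); vr <- attr(v, "sc")^2
    vi / (vi + vr)
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  icc_result(est, ci,
             if (is.null(covariates)) "intercept_only" else "adjusted",
             length(unique(df$dog_id)), var_id, var_res)
}

prepare_model_frame <- function(scores, measure) {
  df <- as.data.frame(scores)
  if (!measure %in% names(df)) {
    validation_error(sprintf("no column '%s' in the score table", measure))
  }
  df$.y <- df[[measure]]
  df$timepoint <- factor(df$timepoint, levels = CANID_TIMEPOINTS)
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("location" %in% names(df)) df$location <- factor(df$location, levels = CANID_LOCATIONS)
  keep <- !is.na(df$.y)
  df[keep, , drop = FALSE]
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' categorical rating vectors, with expected agreement `p_e` from the
#' product of the raters' marginal distributions.  When both raters are
#' constant and identical (`p_e = 1`), agreement is perfect and kappa is
#' defined as 1 by convention (a message notes this).
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return kappa, a number in `[-1, 1]`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2L) {
    validation_error("rating vectors must have equal length >= 2")
  }
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < 1e-12) {
    message("both raters constant and identical; kappa defined as 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Repeatability table across measures
#'
#' Convenience wrapper computing, for each score column, the adjusted ICC,
#' the intercept-only ICC, and the three pairwise ICCs (baseline/6-month,
#' baseline/12-month, 6-month/12-month) with 95% CIs.
#'
#' @param scores long score table.
#' @param measures score columns to summarize.
#' @param covariates fixed-effect formula for the adjusted ICC.
#' @param nboot,seed bootstrap settings passed through.
#' @return a data frame, one row per measure x ICC type.
#' @export
repeatability_table <- function(scores,
                                measures = c("overall_score", "sr_score",
                                             "ds_score", "cyl_score"),
                                covariates = ~ orthogonal_poly(test_age_years, 2) +
                                  timepoint + sex + location,
                                nboot = 1000L, seed = 1L) {
  rows <- list()
  for (msr in measures) {
    res <- list(
      adjusted       = tryCatch(model_icc(scores, msr, covariates, nboot, seed),
                                error = function(e) NULL),
      intercept_only = tryCatch(model_icc(scores, msr, NULL, nboot, seed),
                                error = function(e) NULL),
      baseline_m6    = tryCatch(pairwise_icc(scores, "baseline", "m6", msr, nboot, seed),
                                error = function(e) NULL),
      baseline_m12   = tryCatch(pairwise_icc(scores, "baseline", "m12", msr, nboot, seed),
                                error = function(e) NULL),
      m6_m12         = tryCatch(pairwise_icc(scores, "m6", "m12", msr, nboot, seed),
                                error = function(e) NULL))
    for (nm in names(res)) {
      r <- res[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = msr, icc = nm,
        estimate = if (is.null(r)) NA_real_ else r$estimate,
        ci_low   = if (is.null(r)) NA_real_ else r$ci_low,
        ci_high  = if (is.null(r)) NA_real_ else r$ci_high,
        n        = if (is.null(r)) NA_integer_ else r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
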