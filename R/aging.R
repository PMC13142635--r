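# Longitudinal aging models: quadratic (orthogonal-polynomial) age effects,
# practice-effect (timepoint) contrasts, sex and location covariates, a
# random intercept per dog, and likelihood-ratio age effect sizes.

#' Orthogonal polynomial design columns
#'
#' Centered, mutually orthogonal, unit-norm polynomial contrasts of `x`
#' (a thin wrapper over [stats::poly()]).  The basis constants are attached
#' so the same basis can be applied to new data via the `coefs` argument.
#'
#' @param x numeric vector with at least `degree + 1` distinct values.
#' @param degree polynomial degree (default 2).
#' @param coefs basis constants from a previous call, to re-apply a frozen
#'   basis to new data.
#' @return a numeric matrix with `degree` columns and a `"coefs"` attribute.
#' @export
orthogonal_poly <- function(x, degree = 2L, coefs = NULL) {
  if (is.null(coefs) && length(unique(x[!is.na(x)])) < degree + 1L) {
    validation_error(sprintf("need at least %d distinct values for degree %d",
                             degree + 1L, degree))
  }
  if (is.null(coefs)) {
    p <- stats::poly(x, degree = degree)
  } else {
    p <- stats::poly(x, degree = degree, coefs = coefs)
  }
  out <- unclass(p)[, , drop = FALSE]
  attr(out, "coefs") <- attr(p, "coefs")
  out
}

#' Fit the longitudinal aging model
#'
#' Linear mixed-effects model of a standardized battery score:
#' `score ~ orthogonal_poly(age, 2) + timepoint + sex + location + (1 | dog_id)`.
#' Timepoint contrasts (6- and 12-month retest vs baseline) estimate
#' practice effects; the second-degree orthogonal age polynomial
#' accommodates non-linear decline.  Reference levels are baseline, female,
#' and ACCC.  Reported coefficients come from the REML fit with Wald 95%
#' confidence intervals; maximum-likelihood refits of the full and
#' age-dropped models are stored for the likelihood-ratio age test
#' ([age_effect_size()]).  Covariates absent from the data (e.g. `sex`
#' entirely missing) are dropped from the fixed effects.
#'
#' @param scores long score table with columns `dog_id`, `timepoint`,
#'   `test_age_years` and the score column.
#' @param measure score column to model (default `"overall_score"`).
#' @return an object of class `canid_aging` with `coefficients` (estimate,
#'   SE, CI, p), variance components, the underlying `lmerMod` fits, and the
#'   frozen age-polynomial basis.
#' @export
fit_aging_model <- function(scores, measure = "overall_score") {
  df <- prepare_model_frame(scores, measure)
  df <- df[!is.na(df$test_age_years), , drop = FALSE]
  if (length(unique(df$timepoint)) < 2L) {
    stop_canid("canid_insufficient_data", "need at least 2 timepoints to fit the aging model")
  }
  ap <- orthogonal_poly(df$test_age_years, 2L)
  df$age1 <- ap[, 1]
  df$age2 <- ap[, 2]

  terms <- c("age1", "age2", "timepoint")
  for (cv in c("sex", "location")) {
    if (cv %in% names(df) && sum(!is.na(df[[cv]])) == nrow(df) &&
        length(unique(df[[cv]])) > 1L) {
      terms <- c(terms, cv)
    }
  }
  f_full <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + "), "+ (1 | dog_id)"))
  f_red  <- stats::as.formula(paste(".y ~", paste(setdiff(terms, c("age1", "age2")),
                                                  collapse = " + "), "+ (1 | dog_id)"))
  fit <- lme4::lmer(f_full, data = df, REML = TRUE)
  fit_ml  <- lme4::lmer(f_full, data = df, REML = FALSE)
  red_ml  <- lme4::lmer(f_red, data = df, REML = FALSE)

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  coefs <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                      ci_low = unname(b - stats::qnorm(0.975) * se),
                      ci_high = unname(b + stats::qnorm(0.975) * se),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  if (lme4::isSingular(fit)) {
    warning("random-intercept variance estimated at the boundary (singular fit)",
            call. = FALSE)
  }
  out <- list(coefficients = coefs,
              var_id = as.numeric(vc$dog_id[1, 1]),
              var_res = attr(vc, "sc")^2,
              fit = fit, fit_ml = fit_ml, reduced_ml = red_ml,
              poly_coefs = attr(ap, "coefs"),
              measure = measure,
              n_dogs = length(unique(df$dog_id)), n_obs = nrow(df))
  class(out) <- "canid_aging"
  out
}

# marginal (fixed-effects) R^2 of a fitted lmer model
marginal_r2 <- function(fit) {
  yhat <- drop(stats::model.matrix(fit) %*% lme4::fixef(fit))
  var_f <- stats::var(yhat)
  vc <- lme4::VarCorr(fit)
  var_f / (var_f + as.numeric(vc$dog_id[1, 1]) + attr(vc, "sc")^2)
}

#' Age effect size from the aging model
#'
#' Quantifies how much of the score variance age explains: a likelihood-
#' ratio test comparing maximum-likelihood fits with and without the two
#' age-polynomial terms (df = 2), plus partial R-squared
#' `(R2_full - R2_reduced) / (1 - R2_reduced)` and Cohen's f-squared
#' `(R2_full - R2_reduced) / (1 - R2_full)`, both computed on the marginal
#' (fixed-effects) R-squared of the mixed models.
#'
#' @param fit a `canid_aging` object from [fit_aging_model()].
#' @return a list of class `canid_age_effect`: `partial_r2`, `cohens_f2`,
#'   `lrt_chi2`, `lrt_df`, `lrt_p`, `r2_full`, `r2_reduced`.
#' @export
age_effect_size <- function(fit) {
  stopifnot(inherits(fit, "canid_aging"))
  ll_full <- as.numeric(stats::logLik(fit$fit_ml))
  ll_red  <- as.numeric(stats::logLik(fit$reduced_ml))
  lrt <- max(0, 2 * (ll_full - ll_red))
  r2f <- marginal_r2(fit$fit_ml)
  r2r <- marginal_r2(fit$reduced_ml)
  out <- list(partial_r2 = max(0, (r2f - r2r) / (1 - r2r)),
              cohens_f2 = max(0, (r2f - r2r) / (1 - r2f)),
              lrt_chi2 = lrt, lrt_df = 2L,
              lrt_p = stats::pchisq(lrt, df = 2L, lower.tail = FALSE),
              r2_full = r2f, r2_reduced = r2r)
  class(out) <- "canid_age_effect"
  out
}

#' @export
print.canid_age_effect <- function(x, ...) {
  cat(sprintf("Age effect: LRT chi^2(%d) = %.2f, p = %.3g\n", x$lrt_df, x$lrt_chi2, x$lrt_p))
  cat(sprintf("  partial R^2 = %.3f, Cohen's f^2 = %.3f (marginal R^2: full %.3f, reduced %.3f)\n",
              x$partial_r2, x$cohens_f2, x$r2_full, x$r2_reduced))
  invisible(x)
}

#' @export
print.canid_aging <- function(x, ...) {
  cat(sprintf("Aging model for '%s' (%d dogs, %d observations)\n",
              x$measure, x$n_dogs, x$n_obs))
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Variance components: dog %.3f, residual %.3f (ICC %.3f)\n",
              x$var_id, x$var_res, x$var_id / (x$var_id + x$var_res)))
  invisible(x)
}

#' @export
summary.canid_aging <- function(object, ...) {
  print(object)
  cat("\n")
  print(age_effect_size(object))
  invisible(object)
}

#' @export
coef.canid_aging <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
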