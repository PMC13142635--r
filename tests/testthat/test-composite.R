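test_that("first-component loadings match an eigendecomposition oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- 60
    p <- sample(3:5, 1)
    x <- matrix(rnorm(n * p), n, p) %*% matrix(runif(p * p, -1, 1), p)
    colnames(x) <- paste0("v", seq_len(p))
    mod <- fit_pc1(x, orient_var = "v1")
    ev <- eigen(cor(x))$vectors[, 1]
    if (ev[1] < 0) ev <- -ev
    got <- mod$rotation[, 1] * mod$orientation_sign
    expect_equal(unname(got), ev, tolerance = 1e-8)
    expect_equal(mod$var_share, eigen(cor(x))$values[1] / p, tolerance = 1e-8)
  }
})

test_that("PCA is on the correlation scale: loadings invariant to input scaling", {
  set.seed(12)
  x <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  x[, 2] <- x[, 1] * 0.7 + x[, 2]
  m1 <- fit_pc1(x, "a")
  x2 <- x
  x2[, 3] <- x2[, 3] * 1000   # inflate one variable's variance
  m2 <- fit_pc1(x2, "a")
  expect_equal(m1$rotation[, 1] * m1$orientation_sign,
               m2$rotation[, 1] * m2$orientation_sign, tolerance = 1e-10)
})

test_that("perfectly collinear inputs put all variance on the first component", {
  set.seed(13)
  blocks <- sample(0:4, 40, replace = TRUE)
  x <- cbind(sr_blocks = blocks, sr_longest = 24 - 4 * blocks)
  mod <- fit_pc1(x, "sr_blocks")
  expect_equal(mod$var_share, 1, tolerance = 1e-12)
  expect_true(mod$rotation["sr_blocks", 1] * mod$orientation_sign > 0)
  expect_true(mod$rotation["sr_longest", 1] * mod$orientation_sign < 0)
})

test_that("overall PCA behaves correctly in isotropic and rank-1 cases", {
  set.seed(14)
  # three mutually uncorrelated inputs: PC1 share near 1/3
  x <- matrix(rnorm(3 * 4000), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(fit_pc1(x, "a")$var_share, 1 / 3, tolerance = 0.05)
  # three perfectly correlated inputs: equal loadings, 100% share
  z <- rnorm(200)
  y <- cbind(a = z, b = 2 * z + 1, c = -0.5 * z)
  mod <- fit_pc1(y, "a")
  expect_equal(mod$var_share, 1, tolerance = 1e-12)
  expect_equal(abs(unname(mod$rotation[, 1])), rep(1 / sqrt(3), 3), tolerance = 1e-8)
})

test_that("projecting the center vector gives exactly zero", {
  set.seed(15)
  x <- cbind(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  mod <- fit_pc1(x, "a")
  expect_equal(unname(predict(mod, as.data.frame(t(mod$center)))), 0)
})

test_that("Yeo-Johnson transform has the documented special cases", {
  x <- c(-2.5, -1, 0, 0.5, 3)
  expect_equal(yeo_johnson(x, 1), x)                     # identity
  expect_equal(yeo_johnson(3, 0), log(4))                # log branch
  expect_equal(yeo_johnson(-3, 2), -log(4))              # negative log branch
  expect_equal(yeo_johnson(-1.5, 0.5),
               -((1 - (-1.5))^1.5 - 1) / 1.5)            # negative power branch
})

test_that("fitted lambda is near 1 for symmetric data and matches the grid oracle", {
  set.seed(16)
  x <- rnorm(10000)
  lam <- yj_fit_lambda(x)
  expect_lt(abs(lam - 1), 0.1)
  expect_equal(lam, oracle_yj_grid_lambda(x), tolerance = 2e-3)

  skewed <- rexp(5000) - 0.5
  lam_s <- yj_fit_lambda(skewed)
  expect_equal(lam_s, oracle_yj_grid_lambda(skewed), tolerance = 2e-3)
})

test_that("fitted lambda agrees with the standard power-transform estimator", {
  set.seed(17)
  x <- rexp(2000) - 0.3
  lam <- yj_fit_lambda(x)
  ref <- car::powerTransform(x ~ 1, family = "yjPower")$lambda
  expect_equal(unname(lam), unname(ref), tolerance = 1e-3)
})

test_that("the transform reduces skewness of the task score distribution", {
  skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
  set.seed(18)
  x <- -rexp(3000)   # left-skewed, like ceiling-limited task scores
  z <- yeo_johnson(x, yj_fit_lambda(x))
  expect_lt(abs(skewness(z)), abs(skewness(x)))
})

test_that("PMM imputation returns donor values and matches brute force at k = 1", {
  pool <- data.frame(ds_p_nodelay = c(1, 0.75, 0.5, 0.25),
                     ds_p_d10 = c(1, 1, 0.5, 0),
                     ds_p_d10x = c(1, 0.5, 0.5, 0),
                     ds_p_d20x = c(0.5, 1, 0, 0.5),
                     ds_p_d40x = c(1, 0.5, 0.5, 0))
  row <- pool[1, ]
  row$ds_p_d40x <- NA
  # no missing entries: unchanged
  out0 <- impute_ds_proportions(pool, pool, k = 3, seed = 1)
  expect_equal(out0[, names(pool)], pool)
  expect_false(any(out0$ds_imputed))
  # imputed value must be one of the donors' observed values
  for (s in 1:10) {
    out <- impute_ds_proportions(row, pool, k = 3, seed = s)
    expect_true(out$ds_p_d40x %in% pool$ds_p_d40x)
    expect_true(out$ds_imputed)
  }
  # k = 1 equals the nearest donor by lm prediction (exhaustive search)
  out1 <- impute_ds_proportions(row, pool, k = 1, seed = 7)
  obs_cols <- setdiff(names(pool), "ds_p_d40x")
  fml <- as.formula(paste("ds_p_d40x ~", paste(obs_cols, collapse = "+")))
  fit <- lm(fml, data = pool)
  pred_pool <- predict(fit)
  pred_row <- predict(fit, newdata = row)
  nearest <- which.min(abs(pred_pool - pred_row))
  expect_equal(out1$ds_p_d40x, pool$ds_p_d40x[nearest])
})

test_that("single-task-score imputation is deterministic and exact on linear data", {
  set.seed(19)
  n <- 40
  scores <- data.frame(
    sr_score = rnorm(n), ds_score = rnorm(n),
    location = sample(CANID_LOCATIONS, n, TRUE), stringsAsFactors = FALSE)
  scores$cyl_score <- 0.5 * (scores$sr_score + scores$ds_score)  # exact relation
  models <- canid:::fit_task_imputation(scores)

  # no missing values: returned unchanged
  out <- canid:::impute_task_scores(scores, models)
  expect_equal(out[, c("sr_score", "ds_score", "cyl_score")],
               scores[, c("sr_score", "ds_score", "cyl_score")])

  # exact linear recovery of a missing value
  row <- scores[1, ]
  row$cyl_score <- NA
  imp <- canid:::impute_task_scores(row, models)
  expect_equal(imp$cyl_score, 0.5 * (row$sr_score + row$ds_score), tolerance = 1e-10)
  expect_true(attr(imp, "imputed_flags")[1, "cyl_score"])

  # two missing scores: left alone
  row2 <- scores[2, ]
  row2$cyl_score <- NA; row2$ds_score <- NA
  imp2 <- canid:::impute_task_scores(row2, models)
  expect_true(is.na(imp2$cyl_score) && is.na(imp2$ds_score))
})

test_that("regression imputation beats mean imputation under correlated tasks", {
  set.seed(20)
  n <- 400
  z <- rnorm(n)
  scores <- data.frame(
    sr_score = sqrt(0.6) * z + sqrt(0.4) * rnorm(n),
    ds_score = sqrt(0.6) * z + sqrt(0.4) * rnorm(n),
    cyl_score = sqrt(0.6) * z + sqrt(0.4) * rnorm(n),
    location = sample(CANID_LOCATIONS, n, TRUE), stringsAsFactors = FALSE)
  models <- canid:::fit_task_imputation(scores)
  holdout <- scores
  truth <- holdout$cyl_score
  holdout$cyl_score <- NA
  imp <- canid:::impute_task_scores(holdout, models)
  rmse_reg <- sqrt(mean((imp$cyl_score - truth)^2))
  rmse_mean <- sqrt(mean((mean(scores$cyl_score) - truth)^2))
  expect_lt(rmse_reg, rmse_mean)
})

test_that("fitting is deterministic and projection reproduces the fitted scores", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 80, seed = 21))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod1 <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  mod2 <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  expect_identical(mod1$baseline_scores, mod2$baseline_scores)

  # projection identity on the fitting data
  base_m <- m[m$timepoint == "baseline", ]
  proj <- predict(mod1, base_m, study$sessions, dogs = study$dogs)
  expect_equal(proj, mod1$baseline_scores)

  # projection never alters stored parameters
  before <- mod1$overall_pca
  invisible(predict(mod1, m, study$sessions, dogs = study$dogs))
  expect_identical(mod1$overall_pca, before)
})

test_that("baseline fitted scores are standardized and overall missing iff >1 task absent", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 120, seed = 22))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  bs <- mod$baseline_scores
  expect_equal(mean(bs$overall_score, na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(sd(bs$overall_score, na.rm = TRUE), 1, tolerance = 1e-8)

  sc <- predict(mod, m, study$sessions, dogs = study$dogs)
  n_obs <- rowSums(!is.na(sc[, c("sr_score", "ds_score", "cyl_score")]))
  expect_identical(is.na(sc$overall_score), n_obs < 2L)
})

test_that("higher scores mean better performance: overall score declines with age", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 200, seed = 23))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  bs <- mod$baseline_scores
  ct <- cor.test(bs$test_age_years, bs$overall_score, method = "spearman",
                 exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # and all three tasks load positively on the overall component
  l <- coef(mod)$overall
  expect_true(all(l > 0))
})

test_that("projected follow-ups are unbiased when latent ability is unchanged", {
  lat <- list(b0 = 0.4, b1 = 0, b2 = 0, tau = 0.65, sigma = 0.45,
              delta_m6 = 0, delta_m12 = 0)
  cfg <- canid_sim_config(n_dogs = 500, latent = lat,
                          retention = c(m6 = 1, m12 = 0), seed = 24)
  study <- simulate_canid_study(cfg)
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  sc <- predict(mod, m, study$sessions, dogs = study$dogs)
  wide <- merge(sc[sc$timepoint == "baseline", c("dog_id", "overall_score")],
                sc[sc$timepoint == "m6", c("dog_id", "overall_score")],
                by = "dog_id")
  diffs <- wide$overall_score.y - wide$overall_score.x
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.05)
})

test_that("the scoring model survives a JSON round trip", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 60, seed = 25))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  canid_model_to_json(mod, path)
  back <- canid_model_from_json(path)
  sc1 <- predict(mod, m, study$sessions, dogs = study$dogs)
  sc2 <- predict(back, m, study$sessions, dogs = study$dogs)
  expect_equal(sc1, sc2, tolerance = 1e-12)
  expect_identical(back$fitted_on, mod$fitted_on)
})

test_that("orthogonality of retained rotations holds to tight tolerance", {
  study <- simulate_canid_study(canid_sim_config(n_dogs = 60, seed = 26))
  m <- score_sessions(study$sessions, study$sr_trials, study$ds_trials,
                      study$cyl_trials)
  mod <- canid_fit(m, study$sessions, dogs = study$dogs, seed = 5)
  for (p in list(mod$sr_pca, mod$ds_pca, mod$overall_pca)) {
    g <- crossprod(p$rotation)
    expect_equal(g, diag(ncol(g)), tolerance = 1e-8, ignore_attr = TRUE)
  }
})
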