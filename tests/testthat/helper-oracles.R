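# Independent oracles used to cross-check the package implementations.
# Written deliberately in a different style (exhaustive scans, brute force)
# from the production code paths they verify.

# first position t (t >= window) whose trailing window holds >= required
# successes, by scanning every window explicitly
oracle_first_window <- function(ok, window = 4L, required = 3L) {
  n <- length(ok)
  if (n < window) return(NA_integer_)
  for (t in window:n) {
    if (sum(ok[(t - window + 1L):t]) >= required) return(t)
  }
  NA_integer_
}

# step-by-step replay of the Spatial Reversal scoring rules on a trial frame
# (returns NULL for sequences that stop before the protocol resolves)
oracle_score_sr <- function(trials) {
  superseded <- trials$index %in% trials$repeat_of[!is.na(trials$repeat_of)]
  tr <- trials[!superseded & trials$response != "no_choice", , drop = FALSE]
  base_ok <- tr$response[tr$phase == "baseline"] == "open"
  crit <- if (length(base_ok)) oracle_first_window(base_ok) else NA_integer_
  rev <- tr[tr$phase == "reversal", , drop = FALSE]
  if (is.na(crit)) {
    if (length(base_ok) == 20L && nrow(rev) == 0L) {
      return(list(blocks = 0L, longest = 20L, remaining = 0L))
    }
    return(NULL)
  }
  lens <- crit
  blocks <- 1L
  used <- 0L
  for (b in sort(unique(rev$block_index))) {
    ok <- rev$response[rev$block_index == b] == "open"
    c2 <- oracle_first_window(ok)
    if (!is.na(c2)) {
      blocks <- blocks + 1L
      lens <- c(lens, c2)
      used <- used + c2
    } else {
      lens <- c(lens, length(ok))
      used <- used + length(ok)
      if (used < 20L) return(NULL)
    }
  }
  if ((blocks - 1L) < 3L && used < 20L) return(NULL)
  list(blocks = blocks, longest = max(lens), remaining = 20L - used)
}

# direct counting of Delayed Search proportions over final administrations
oracle_score_ds <- function(trials) {
  superseded <- trials$index %in% trials$repeat_of[!is.na(trials$repeat_of)]
  fin <- trials[!superseded & trials$first_search != "no_choice", , drop = FALSE]
  sapply(DS_TRIAL_TYPES, function(ty) {
    sub <- fin[fin$trial_type == ty, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    mean(as.integer(sub$first_search) == sub$baited_location)
  })
}

# Cylinder success count over final administrations
oracle_score_cyl <- function(trials) {
  superseded <- trials$index %in% trials$repeat_of[!is.na(trials$repeat_of)]
  fin <- trials[!superseded, , drop = FALSE]
  n_resp <- sum(fin$responded)
  if (n_resp <= 3L) return(NA_real_)
  sum(fin$responded & !fin$touched_exterior) / 4
}

# one-way ANOVA ICC closed form via R's aov mean squares
oracle_anova_icc <- function(y) {
  df <- data.frame(dog = factor(rep(seq_len(nrow(y)), 2)), y = c(y[, 1], y[, 2]))
  ms <- summary(aov(y ~ dog, data = df))[[1]][["Mean Sq"]]
  max(0, min(1, (ms[1] - ms[2]) / (ms[1] + ms[2])))
}

# Gram-Schmidt orthonormalization of (centered) age and age^2
oracle_gram_schmidt_poly <- function(x) {
  v1 <- x - mean(x)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- x^2 - mean(x^2)
  v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  cbind(v1, v2)
}

# Yeo-Johnson profile log-likelihood on a lambda grid (independent
# reimplementation of the transform)
oracle_yj_grid_lambda <- function(x, grid = seq(-3, 3, by = 0.001)) {
  tf <- function(x, l) {
    z <- numeric(length(x))
    pos <- x >= 0
    z[pos] <- if (abs(l) < 1e-10) log(x[pos] + 1) else ((x[pos] + 1)^l - 1) / l
    z[!pos] <- if (abs(2 - l) < 1e-10) -log(1 - x[!pos])
               else -((1 - x[!pos])^(2 - l) - 1) / (2 - l)
    z
  }
  ll <- vapply(grid, function(l) {
    z <- tf(x, l)
    n <- length(z)
    -n / 2 * log(sum((z - mean(z))^2) / n) + (l - 1) * sum(sign(x) * log(abs(x) + 1))
  }, numeric(1))
  grid[which.max(ll)]
}
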