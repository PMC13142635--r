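#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox power transform to the whole
#' real line and is used to normalize the skewed Spatial Reversal and
#' Delayed Search component scores before standardization.  For x >= 0 the
#' transform is ((x+1)^lambda - 1)/lambda (log(x+1) at lambda = 0); for
#' x < 0 it is -((1-x)^(2-lambda) - 1)/(2-lambda) (-log(1-x) at lambda = 2).
#' `lambda = 1` is the identity.
#'
#' @param x numeric vector.
#' @param lambda transformation parameter.
#' @return transformed vector of the same length.
#' @export
yeo_johnson <- function(x, lambda) {
  if (anyNA(lambda) || length(lambda) != 1L) stop("lambda must be a single number")
  out <- x
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  l2 <- 2 - lambda
  if (abs(l2) > 1e-10) {
    out[neg] <- -((1 - x[neg])^l2 - 1) / l2
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out
}

# profile log-likelihood of the normal model for YJ-transformed data
yj_loglik <- function(x, lambda) {
  z <- yeo_johnson(x, lambda)
  n <- length(z)
  s2 <- sum((z - mean(z))^2) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Maximum-likelihood Yeo-Johnson lambda
#'
#' Profiles the normal log-likelihood of the transformed data over a bounded
#' lambda interval and returns the maximizer, located by [stats::optimize()]
#' (golden-section search with parabolic refinement) to a tolerance of 1e-6.
#'
#' @param x numeric vector with at least 3 finite values.
#' @param interval search bounds for lambda.
#' @return the fitted lambda (scalar).
#' @export
yj_fit_lambda <- function(x, interval = c(-3, 3)) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) fitting_error("need at least 3 finite values to fit lambda")
  if (stats::sd(x) == 0) return(1)
  opt <- stats::optimize(function(l) yj_loglik(x, l), interval = interval,
                         maximum = TRUE, tol = 1e-6)
  opt$maximum
}
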