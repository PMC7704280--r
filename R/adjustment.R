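#' Point value of the match-attenuation factor lambda
#'
#' A suspected match only succeeds if none of the k quasi-identifier
#' values carries a data error (probability `(1 - e)^k` under
#' independent per-variable errors, with the adversary's own knowledge
#' assumed error-free) and if the match can then be verified
#' (probability v). With the default rates this is
#' `lambda = 0.23 * (1 - 0.0426)^k`.
#'
#' @param k number of active quasi-identifiers (>= 0).
#' @param params [risk_parameters()].
#' @return probability in (0, 1].
#' @examples
#' lambda_point(0)        # 0.23
#' lambda_point(9)        # ~0.155
#' @export
lambda_point <- function(k, params = risk_parameters()) {
  stopifnot(k >= 0)
  e <- unname(params$error_rate["mode"])
  v <- unname(params$verification_rate["mode"])
  v * (1 - e)^k
}

#' Conservative midpoint adjustment
#'
#' To avoid the error/verification adjustment over-attenuating the
#' risk, the model uses the midpoint between the sampled lambda and
#' its maximum value of 1: `lambda_c = (lambda_s + 1) / 2`.
#'
#' @param lambda_s probability in \[0, 1\] (vectorized).
#' @return probability in \[0.5, 1\].
#' @export
conservative_lambda <- function(lambda_s) {
  stopifnot(all(lambda_s >= 0 & lambda_s <= 1))
  (lambda_s + 1) / 2
}

# triangular(min, mode, max) quantile function, vectorized over u
qtriangular <- function(u, spec) {
  a <- spec[["min"]]; c_ <- spec[["mode"]]; b <- spec[["max"]]
  if (b == a) return(rep(a, length(u)))
  Fc <- (c_ - a) / (b - a)
  out <- numeric(length(u))
  lo <- u <= Fc
  out[lo] <- a + sqrt(u[lo] * (b - a) * (c_ - a))
  out[!lo] <- b - sqrt((1 - u[!lo]) * (b - a) * (b - c_))
  out
}

#' Sample correlated error and verification rates
#'
#' Draws one (error rate, verification rate) pair per real-sample
#' record from the two triangular distributions in `params`, with a
#' negative rank correlation between them induced through a Gaussian
#' copula: independent triangular marginals are coupled by feeding
#' correlated normal scores through their inverse CDFs, so the
#' marginals are exact and the Spearman correlation is (minus) the
#' configured magnitude. Data errors make verification less likely,
#' hence the negative sign.
#'
#' @param n_records number of draws (one per real-sample record).
#' @param params [risk_parameters()].
#' @param seed integer seed; defaults to `params$seed`. `NULL` uses
#'   the current RNG state.
#' @return data.frame with columns `e` and `v`.
#' @export
sample_error_verification <- function(n_records, params = risk_parameters(),
                                      seed = params$seed) {
  stopifnot(n_records >= 1)
  if (!is.null(seed)) set.seed(seed)
  rho_s <- -abs(params$correlation)
  # Pearson correlation of the normal scores giving the target Spearman
  rho_p <- 2 * sin(pi * rho_s / 6)
  z <- MASS::mvrnorm(n_records, mu = c(0, 0),
                     Sigma = matrix(c(1, rho_p, rho_p, 1), 2))
  z <- matrix(z, ncol = 2)
  u <- stats::pnorm(z)
  data.frame(e = qtriangular(u[, 1], params$error_rate),
             v = qtriangular(u[, 2], params$verification_rate))
}

#' Per-record adjustment draws
#'
#' Combines sampled (or supplied) error/verification rates with the
#' active quasi-identifier count k into the per-record attenuation
#' `lambda_s = v_s * (1 - e_s)^k` and its conservative version
#' `lambda_c = (lambda_s + 1) / 2`. The same (e, v) draws can be
#' re-scored at a different k — the attack search re-uses one set of
#' draws across configurations so the maximization is not inflated by
#' sampling noise.
#'
#' @param n_records number of real-sample records (ignored when `ev`
#'   is supplied).
#' @param k number of active quasi-identifiers.
#' @param params [risk_parameters()].
#' @param ev optional data.frame with columns `e`, `v` from
#'   [sample_error_verification()].
#' @param seed integer seed, defaults to `params$seed`.
#' @return data.frame of class `adjustment_draws` with columns `e`,
#'   `v`, `lambda_s`, `lambda_c` and attribute `k`.
#' @examples
#' draws <- sample_adjustments(5, k = 1, params = risk_parameters(seed = 1))
#' summary(draws$lambda_c)
#' @export
sample_adjustments <- function(n_records, k, params = risk_parameters(),
                               ev = NULL, seed = params$seed) {
  if (is.null(ev)) ev <- sample_error_verification(n_records, params, seed = seed)
  stopifnot(k >= 0, all(c("e", "v") %in% names(ev)))
  lambda_s <- ev$v * (1 - ev$e)^k
  out <- data.frame(e = ev$e, v = ev$v,
                    lambda_s = lambda_s,
                    lambda_c = conservative_lambda(lambda_s))
  attr(out, "k") <- as.integer(k)
  class(out) <- c("adjustment_draws", class(out))
  out
}
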