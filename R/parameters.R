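#' Risk assessment parameters
#'
#' Bundles the tunable parameters of the meaningful identity disclosure
#' risk model: the acceptability threshold, the minimum percentage `L` of
#' sensitive variables on which an adversary must learn something new,
#' the triangular distributions for the data-error and
#' match-verification rates, the rank correlation between the two, and
#' the MAD multiplier used by the continuous learn-something-new test.
#'
#' The default error rate (mean 4.26%) is the weighted mean error rate
#' reported for health databases, and the default verification rate
#' (mean 23%) is the rate at which suspected re-identification matches
#' could be verified in published attacks. Both are modelled as
#' triangular distributions `(min, mode, max)`; the shipped ranges are
#' symmetric about the cited value, so mode and mean coincide. The
#' correlation between the two rates is negative (data errors depress
#' verification) with magnitude 0.3, a medium effect size.
#'
#' @param threshold acceptable overall risk; a report at or below this
#'   value gets the verdict `"acceptable"`. Default 0.09, the threshold
#'   used by large health data custodians for public release.
#' @param L minimum percentage (0-100) of applicable sensitive variables
#'   that must meet the learn-something-new criterion for a match to
#'   count as meaningful. Default 5.
#' @param error_rate numeric `(min, mode, max)` triangular specification
#'   for the per-variable data error rate.
#' @param verification_rate numeric `(min, mode, max)` triangular
#'   specification for the probability that a suspected match can be
#'   verified.
#' @param correlation magnitude of the rank correlation between error
#'   and verification rates; applied with a negative sign.
#' @param mad_multiplier scale factor applied to the MAD in the
#'   continuous learn-something-new inequality. Default 1.48, which
#'   makes the MAD equivalent to one standard deviation under normality.
#' @param kmeans_max_k largest cluster count considered when
#'   discretizing continuous sensitive variables.
#' @param seed integer seed governing all stochastic stages of an
#'   assessment (the adjustment draws); `NULL` uses the current RNG
#'   state.
#' @return an object of class `risk_parameters`.
#' @examples
#' p <- risk_parameters()
#' lambda_point(9, p)
#' @export
risk_parameters <- function(threshold = 0.09,
                            L = 5,
                            error_rate = c(min = 0, mode = 0.0426, max = 0.0852),
                            verification_rate = c(min = 0, mode = 0.23, max = 0.46),
                            correlation = 0.3,
                            mad_multiplier = 1.48,
                            kmeans_max_k = 10,
                            seed = NULL) {
  error_rate <- check_triangular(error_rate, "error_rate")
  verification_rate <- check_triangular(verification_rate, "verification_rate")
  stopifnot(
    is.numeric(threshold), length(threshold) == 1, threshold >= 0, threshold <= 1,
    is.numeric(L), length(L) == 1, L >= 0, L <= 100,
    is.numeric(correlation), correlation >= 0, correlation <= 1,
    is.numeric(mad_multiplier), mad_multiplier > 0,
    kmeans_max_k >= 2
  )
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      threshold = threshold, L = L,
      error_rate = error_rate, verification_rate = verification_rate,
      correlation = correlation, mad_multiplier = mad_multiplier,
      kmeans_max_k = as.integer(kmeans_max_k), seed = seed
    ),
    class = "risk_parameters"
  )
}

# triangular specs are (min, mode, max) with min <= mode <= max, all in [0,1]
check_triangular <- function(x, what) {
  if (length(x) != 3 || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric (min, mode, max) triple", what), call. = FALSE)
  }
  names(x) <- c("min", "mode", "max")
  if (any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` values must lie in [0, 1]", what), call. = FALSE)
  }
  if (x["min"] > x["mode"] || x["mode"] > x["max"]) {
    stop(sprintf("`%s` must satisfy min <= mode <= max", what), call. = FALSE)
  }
  x
}

#' @export
print.risk_parameters <- function(x, ...) {
  cat("Risk assessment parameters\n")
  cat(sprintf("  threshold: %g   L: %g%%   MAD multiplier: %g\n",
              x$threshold, x$L, x$mad_multiplier))
  cat(sprintf("  error rate       (min, mode, max): %s\n",
              paste(signif(x$error_rate, 4), collapse = ", ")))
  cat(sprintf("  verification rate(min, mode, max): %s\n",
              paste(signif(x$verification_rate, 4), collapse = ", ")))
  cat(sprintf("  rank correlation: -%g   seed: %s\n",
              x$correlation, if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
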