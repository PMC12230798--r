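#' Inverse-logit (logistic) transform
#'
#' @param x numeric vector on the logit scale.
#' @return `1 / (1 + exp(-x))`, computed in a form stable for large `|x|`.
#' @keywords internal
#' @noRd
inv_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("parameter '%s' must be a single finite number (got %s)", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_prob <- function(x, name) {
  check_finite_scalar(x, name)
  if (x < 0 || x > 1) abort("parameter '%s' must lie in [0, 1] (got %g)", name, x)
  invisible(x)
}

# one draw per element from a Normal(mean, sd) left-truncated at `lower`,
# by inversion of the truncated CDF
rnorm_trunc_lower <- function(n, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean = mean, sd = sd)
  u <- stats::runif(n, min = plo, max = 1)
  # guard against u == 1 rounding to Inf
  u <- pmin(u, 1 - .Machine$double.eps)
  stats::qnorm(u, mean = mean, sd = sd)
}
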