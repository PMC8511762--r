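# Truncated-normal helpers used by the hierarchical priors and the
# synthetic-data generator. Infinite bounds reduce to the plain normal.

#' Truncated-normal density, log scale
#'
#' @param x quantiles.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds (may be infinite).
#' @return Log density; `-Inf` outside `[lower, upper]`.
#' @keywords internal
#' @noRd
dtnorm_log <- function(x, mean, sd, lower = -Inf, upper = Inf) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  out <- dnorm(x, mean, sd, log = TRUE) - log(z)
  out[x < lower | x > upper | !is.finite(x)] <- -Inf
  out
}

#' @noRd
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(lower >= upper)) {
    abort("truncated-normal bounds must satisfy lower < upper",
          class = "rrddm_config_error")
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# mean and sd of a truncated normal (moment oracle for generator tests)
#' @noRd
tnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  al <- (lower - mean) / sd
  be <- (upper - mean) / sd
  z <- pnorm(be) - pnorm(al)
  dl <- if (is.finite(al)) dnorm(al) else 0
  du <- if (is.finite(be)) dnorm(be) else 0
  m <- mean + sd * (dl - du) / z
  t1 <- if (is.finite(al)) al * dl else 0
  t2 <- if (is.finite(be)) be * du else 0
  v <- sd^2 * (1 + (t1 - t2) / z - ((dl - du) / z)^2)
  list(mean = m, sd = sqrt(v))
}
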