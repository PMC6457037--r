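# Study-design calculations for the IU test.
#
# Under a local alternative with pairwise-kernel mean mu1 != mu0 and
# first-projection conditional standard deviation tau1, the rejection
# probability of the two-sided level-alpha IU test is bounded below by
#   Phi( (sigma / (2 tau1)) * (sqrt(n) |mu1 - mu0| / sigma - z_{alpha/2}) ),
# and the bound inverts to a minimal sample size for target power beta.

#' Power specification for the IU test
#'
#' Bundle of the quantities entering the power bound: null and alternative
#' kernel means `mu0`, `mu1`; the conditional (first-projection) standard
#' deviation `tau1`; the null standard deviation `sigma` (the square root of
#' the Theorem-scale variance); the test level `alpha`; and either a sample
#' size `n` (power direction) or a target power `beta` (sample-size
#' direction).
#'
#' @param mu0,mu1 Null and alternative means of the pairwise kernel.
#' @param tau1,sigma Positive scale parameters.
#' @param alpha Test level in (0, 1).
#' @param n Sample size (power direction), positive integer.
#' @param beta Target power in (0, 1) (sample-size direction).
#' @return A `power_spec` list.
#' @export
power_spec <- function(mu0, mu1, tau1, sigma, alpha = 0.05,
                       n = NULL, beta = NULL) {
  if (tau1 <= 0 || sigma <= 0) stop("tau1 and sigma must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(beta) && (beta <= 0 || beta >= 1)) {
    stop("beta must be in (0, 1)")
  }
  structure(list(mu0 = mu0, mu1 = mu1, tau1 = tau1, sigma = sigma,
                 alpha = alpha, n = n, beta = beta),
            class = "power_spec")
}

#' Lower bound on the power of the IU test
#'
#' `Phi( (sigma / (2 tau1)) * (sqrt(n) |mu1 - mu0| / sigma - z_{alpha/2}) )`.
#' The bound keeps only the upper rejection tail, so it is conservative for
#' the two-sided test; the effect enters through `|mu1 - mu0|`.
#'
#' @param spec A [power_spec()] with `n` set (or pass `n`).
#' @param n Optional sample-size override.
#' @return A probability (lower bound on power); monotone increasing in `n`
#'   and in `|mu1 - mu0|`.
#' @export
power_lower_bound <- function(spec, n = spec$n) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(n) || n < 1) stop("a positive sample size n is required")
  z <- qnorm(1 - spec$alpha / 2)
  delta <- abs(spec$mu1 - spec$mu0)
  pnorm((spec$sigma / (2 * spec$tau1)) *
          (sqrt(n) * delta / spec$sigma - z))
}

#' Minimal sample size for target power
#'
#' Smallest integer `m >= (sigma^2 / (mu1 - mu0)^2) * (z_{alpha/2} +
#' 2 tau1 z_beta / sigma)^2`, with `z_beta = qnorm(beta)` so that
#' `power_lower_bound` at the returned `n` is at least `beta`.
#'
#' @param spec A [power_spec()] with `beta` set (or pass `beta`).
#' @param beta Optional target-power override.
#' @return Positive integer sample size.
#' @export
min_sample_size <- function(spec, beta = spec$beta) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(beta)) stop("a target power beta is required")
  delta <- abs(spec$mu1 - spec$mu0)
  if (delta == 0) {
    stop("mu1 = mu0: no alternative effect, required sample size is infinite")
  }
  z_a <- qnorm(1 - spec$alpha / 2)
  z_b <- qnorm(beta)
  bound <- (spec$sigma^2 / delta^2) * (z_a + 2 * spec$tau1 * z_b / spec$sigma)^2
  max(1L, as.integer(ceiling(bound)))
}

#' Pilot-data estimate of the projection scale tau1
#'
#' Convenience plug-in for [power_spec()]: estimates the first-projection
#' conditional standard deviation as the sample standard deviation over
#' subjects of `r_i_hat = Y_i S_i * (1/(n-1)) * sum_{j != i} Y_j S_j
#' <G_i, G_j>`, the leave-one-out estimate of `E(U_n | Z_i)`.
#'
#' @param y,s Pilot phenotype and expression vectors.
#' @param curves `genotype_curves` or a precomputed gram matrix.
#' @return Positive scalar estimate of `tau1` (0 with a warning when the
#'   pilot data are degenerate).
#' @export
estimate_tau1 <- function(y, s, curves) {
  gram <- as_gram(curves)
  n <- check_lengths(y, s, diag(gram))
  if (n < 3) stop("need at least 3 pilot subjects")
  w <- y * s
  r_hat <- w * (drop(gram %*% w) - diag(gram) * w) / (n - 1)
  tau1 <- sd(r_hat)
  if (tau1 == 0) {
    warning("degenerate pilot data: estimated tau1 is 0")
  }
  tau1
}
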