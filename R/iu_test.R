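# The integrative U statistic and its normal-reference inference.
#
# U_n = (1 / (n(n-1))) * sum_{i != j} Y_i Y_j S_i S_j <G_i, G_j>,
# where <G_i, G_j> is the L2 inner product of the smoothed genotype curves and
# phenotype/expression similarities are cross products. Under H0 (Y
# independent of (G, S), S independent of G, mu_Y * mu_S != 0) the
# standardized statistic T_n = sqrt(n) (U_n - mu0_hat) / sigma_hat is
# asymptotically standard normal.

check_lengths <- function(...) {
  ls <- vapply(list(...), length, integer(1))
  if (length(unique(ls)) != 1) stop("input lengths differ")
  ls[1]
}

as_gram <- function(x) {
  if (inherits(x, "genotype_curves")) curve_gram(x) else as.matrix(x)
}

#' Integrative U statistic
#'
#' Average over ordered subject pairs of the product of phenotype similarity
#' `Y_i Y_j`, expression similarity `S_i S_j`, and genotype-curve similarity
#' `gram[i, j]`. Computed as the quadratic form `Y' K_S Y / (n(n-1))` with
#' `K_S = (S S') * gram` and zero diagonal.
#'
#' @param y Phenotype vector.
#' @param s Expression vector.
#' @param gram n x n matrix of pairwise curve inner products, or a
#'   `genotype_curves` object.
#' @return The U statistic (scalar).
#' @export
compute_un <- function(y, s, gram) {
  gram <- as_gram(gram)
  n <- check_lengths(y, s, diag(gram))
  if (n < 2) stop("need at least 2 subjects (no pairs to average)")
  stopifnot_finite(y, "y"); stopifnot_finite(s, "s")
  Ks <- tcrossprod(s) * gram
  diag(Ks) <- 0
  drop(y %*% Ks %*% y) / (n * (n - 1))
}

#' Plug-in null mean of the IU statistic
#'
#' `mu0_hat = Ybar^2 * Sbar^2 * ||Gbar||^2`, substituting sample means for the
#' population means of phenotype, expression and the genotype process.
#'
#' @param y,s Phenotype and expression vectors.
#' @param moments A [functional_moments()] object.
#' @return Scalar estimate of the null mean.
#' @export
estimate_null_mean <- function(y, s, moments) {
  stopifnot(inherits(moments, "functional_moments"))
  yb <- mean(y); sb <- mean(s)
  if (yb == 0 || sb == 0) {
    warning("sample mean of phenotype or expression is exactly 0: ",
            "the non-degeneracy assumption mu_Y * mu_S != 0 is violated")
  }
  yb^2 * sb^2 * moments$mean_sq_norm
}

#' Plug-in null variance of the IU statistic
#'
#' Two printed forms are available. `"theorem"` (default) is the variance of
#' `sqrt(n) (U_n - mu0_hat)` accounting for the estimated null mean:
#' `4 * sum(lambda_k delta_k^2) * Ybar^2 Sbar^2 (Ybar^2 s_S^2 + Sbar^2 s_Y^2 +
#' s_Y^2 s_S^2) + 4 Ybar^2 Sbar^2 ||Gbar||^4 s_Y^2 s_S^2`. `"expansion"` is
#' the first-projection expansion appropriate when the null mean is treated as
#' known: `4 * (Ybar^2 Sbar^2 sum(lambda delta^2) (Ybar^2 + s_Y^2) (Sbar^2 +
#' s_S^2) + Ybar^2 Sbar^2 (Ybar^2 s_S^2 + Sbar^2 s_Y^2 + s_Y^2 s_S^2)
#' ||Gbar||^4)`. Sample variances use denominator n - 1. Null calibration
#' (see the methods vignette) selects `"theorem"` as the default.
#'
#' @param y,s Phenotype and expression vectors.
#' @param moments A [functional_moments()] object.
#' @param variant `"theorem"` or `"expansion"`.
#' @return Non-negative scalar variance estimate.
#' @export
estimate_null_variance <- function(y, s, moments,
                                   variant = c("theorem", "expansion")) {
  variant <- match.arg(variant)
  stopifnot(inherits(moments, "functional_moments"))
  yb <- mean(y); sb <- mean(s)
  sy2 <- var(y); ss2 <- var(s)
  ld <- moments$sum_lambda_delta2
  g2 <- moments$mean_sq_norm
  out <- if (variant == "theorem") {
    4 * ld * (yb^2 * sb^2 * (yb^2 * ss2 + sb^2 * sy2 + sy2 * ss2)) +
      4 * yb^2 * sb^2 * g2^2 * sy2 * ss2
  } else {
    4 * (yb^2 * sb^2 * ld * (yb^2 + sy2) * (sb^2 + ss2) +
           yb^2 * sb^2 * (yb^2 * ss2 + sb^2 * sy2 + sy2 * ss2) * g2^2)
  }
  stopifnot(out >= 0)
  out
}

warn_if_mean_degenerate <- function(x, label) {
  n <- length(x)
  se <- sd(x) / sqrt(n)
  if (se > 0 && abs(mean(x)) < 2 * se) {
    warning(sprintf(
      "sample mean of %s is within 2 standard errors of 0; the assumption mu_Y * mu_S != 0 underpinning the normal reference is at risk",
      label
    ), call. = FALSE)
  }
}

new_iu_result <- function(u_n, mu0_hat, sigma2_hat, n, alpha, variant,
                          diagnostics, statistic_name = "IU") {
  if (sigma2_hat <= 0) {
    stop("degenerate null variance (sigma_hat = 0): requires non-constant ",
         "phenotype/expression and non-identical genotype curves ",
         "(mu_Y * mu_S != 0, Var(r_1) > 0)", call. = FALSE)
  }
  t_n <- sqrt(n) * (u_n - mu0_hat) / sqrt(sigma2_hat)
  p <- 2 * pnorm(-abs(t_n))
  structure(
    list(
      statistic = statistic_name,
      u_n = u_n, mu0_hat = mu0_hat, sigma2_hat = sigma2_hat,
      t_n = t_n, p_value = p, n = n, alpha = alpha,
      reject = abs(t_n) > qnorm(1 - alpha / 2),
      variant = variant, diagnostics = diagnostics
    ),
    class = "iu_result"
  )
}

#' @export
print.iu_result <- function(x, ...) {
  cat(sprintf("%s test (n = %d, variant = %s)\n", x$statistic, x$n, x$variant))
  cat(sprintf("  U_n = %.6g, mu0_hat = %.6g, sigma2_hat = %.6g\n",
              x$u_n, x$mu0_hat, x$sigma2_hat))
  cat(sprintf("  T_n = %.4f, two-sided p = %.4g  [%s at alpha = %g]\n",
              x$t_n, x$p_value,
              if (x$reject) "reject H0" else "fail to reject H0", x$alpha))
  invisible(x)
}

#' Integrative U test for joint SNV-set and expression association
#'
#' Tests H0: the phenotype is independent of the genotype curves and the
#' expression value, against joint association, using the normal reference of
#' the standardized statistic `T_n`.
#'
#' @param y Phenotype vector (binary 0/1 or continuous). Must be pre-adjusted
#'   for covariates if needed.
#' @param s Per-subject expression values.
#' @param curves A `genotype_curves` object or a [genotype_matrix()] (smoothed
#'   internally via [fit_curves()]).
#' @param alpha Test level for the reject flag (default 0.05).
#' @param variant Null-variance form, see [estimate_null_variance()].
#' @param ... Passed to [fit_curves()] when `curves` is a genotype matrix.
#'
#' @return An `iu_result`: `u_n`, `mu0_hat`, `sigma2_hat`, `t_n`, two-sided
#'   `p_value`, `reject`, and diagnostics (sample means/variances, mean-curve
#'   norm, `sum lambda_k delta_k^2`).
#' @export
iu_test <- function(y, s, curves, alpha = 0.05,
                    variant = c("theorem", "expansion"), ...) {
  variant <- match.arg(variant)
  if (inherits(curves, "genotype_matrix")) curves <- fit_curves(curves, ...)
  stopifnot(inherits(curves, "genotype_curves"))
  n <- check_lengths(y, s, curves$coefficients[, 1])
  warn_if_mean_degenerate(y, "the phenotype")
  warn_if_mean_degenerate(s, "the expression")

  moments <- functional_moments(curves)
  u_n <- compute_un(y, s, curves)
  mu0 <- estimate_null_mean(y, s, moments)
  sig2 <- estimate_null_variance(y, s, moments, variant)
  diag_list <- list(
    y_bar = mean(y), s_bar = mean(s), s_y2 = var(y), s_s2 = var(s),
    mean_sq_norm = moments$mean_sq_norm,
    sum_lambda_delta2 = moments$sum_lambda_delta2
  )
  new_iu_result(u_n, mu0, sig2, n, alpha, variant, diag_list)
}

#' Genetics-only U test
#'
#' Drops the expression similarity: `U_G = (1/(n(n-1))) sum_{i != j} Y_i Y_j
#' <G_i, G_j>` with `mu_G_hat = Ybar^2 ||Gbar||^2` and (default) variance
#' `sigma_G^2 = 4 Ybar^2 s_Y^2 sum(lambda_k delta_k^2)`; the `"expansion"`
#' variant is `4 Ybar^2 ((Ybar^2 + s_Y^2) sum(lambda delta^2) + s_Y^2
#' ||Gbar||^4)`, appropriate for a known null mean.
#'
#' @inheritParams iu_test
#' @return An `iu_result` (statistic tag `"U_G"`).
#' @export
genetics_only_test <- function(y, curves, alpha = 0.05,
                               variant = c("theorem", "expansion"), ...) {
  variant <- match.arg(variant)
  if (inherits(curves, "genotype_matrix")) curves <- fit_curves(curves, ...)
  n <- check_lengths(y, curves$coefficients[, 1])
  warn_if_mean_degenerate(y, "the phenotype")
  moments <- functional_moments(curves)
  ones <- rep(1, n)
  u_g <- compute_un(y, ones, curves)
  yb <- mean(y); sy2 <- var(y)
  mu_g <- yb^2 * moments$mean_sq_norm
  ld <- moments$sum_lambda_delta2
  sig2 <- if (variant == "theorem") {
    4 * yb^2 * sy2 * ld
  } else {
    4 * yb^2 * ((yb^2 + sy2) * ld + sy2 * moments$mean_sq_norm^2)
  }
  diag_list <- list(
    y_bar = yb, s_y2 = sy2,
    mean_sq_norm = moments$mean_sq_norm, sum_lambda_delta2 = ld
  )
  new_iu_result(u_g, mu_g, sig2, n, alpha, variant, diag_list,
                statistic_name = "U_G")
}

#' Three-level integrative U statistic
#'
#' Adds a third omic layer `r` (e.g. methylation) with a cross-product
#' similarity: `U_n = (1/(n(n-1))) sum_{i != j} Y_i Y_j S_i S_j R_i R_j
#' <G_i, G_j>`.
#'
#' @param y,s Phenotype and expression vectors.
#' @param r Third-level omic vector.
#' @param gram Curve inner-product matrix or `genotype_curves`.
#' @return The three-level U statistic (scalar).
#' @export
multilevel_un <- function(y, s, r, gram) {
  stopifnot_finite(r, "r")
  check_lengths(y, s, r)
  compute_un(y, s * r, gram)
}

#' Three-level integrative U test
#'
#' Inference for [multilevel_un()] by the same standardization pattern as
#' [iu_test()], treating the product `S_i R_i` as a single composite
#' expression variable: `mu0_hat = Ybar^2 mean(SR)^2 ||Gbar||^2` and the
#' chosen variance form applied to `(Y, SR)`.
#'
#' @inheritParams iu_test
#' @param r Third-level omic vector.
#' @return An `iu_result` (statistic tag `"IU3"`).
#' @export
multilevel_test <- function(y, s, r, curves, alpha = 0.05,
                            variant = c("theorem", "expansion"), ...) {
  stopifnot_finite(r, "r")
  res <- iu_test(y, s * r, curves, alpha = alpha, variant = variant, ...)
  res$statistic <- "IU3"
  res
}
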