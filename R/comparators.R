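# Variance-component comparator tests.
#
# Two quadratic-form benchmarks on the raw (unsmoothed) genotype counts:
#  * Adj-SKAT: Q = (Y - mu_hat)' Ktilde_S (Y - mu_hat), with
#    Ktilde_S(i, j) = sum_k w_k S_i S_j G_ik G_jk;
#  * VCT: Qbar = (1/n) (Y - mu_hat)' {a1 GG' + a2 SS' + a3 CC'} (Y - mu_hat),
#    C = S * G columnwise.
# Both are referred to a weighted mixture of chi-squares whose weights are the
# eigenvalues of the residual-projected kernel scaled by the null-model
# dispersion (intercept-only mean; logistic for binary, identity for
# continuous phenotypes).

# Imhof's (1961) exact inversion integral for P(sum lambda_l chi2_1 > q).
imhof_tail <- function(q, lambda) {
  f <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(lu^2)))
    sin(theta) / (u * rho)
  }
  val <- integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                   subdivisions = 2000L, stop.on.error = TRUE)$value
  0.5 + val / pi
}

# Liu-Tang-Zhang moment-matching approximation (fallback path).
liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    ncp <- 0
    df <- 1 / s2
  }
  mu_x <- df + ncp
  sd_x <- sqrt(2) * sqrt(df + 2 * ncp)
  tstar <- (q - c1) / sqrt(2 * c2)
  pchisq(tstar * sd_x + mu_x, df = df, ncp = ncp, lower.tail = FALSE)
}

#' Tail probability of a weighted mixture of chi-squares
#'
#' Evaluates `P(sum_l lambda_l chi^2_1 > q)`, the reference distribution of
#' SKAT-family quadratic forms, by Imhof's exact inversion integral with a
#' moment-matching (Liu-Tang-Zhang) fallback when the integral fails
#' numerically. Weights can be given directly, or derived from a kernel
#' matrix and a residual projection (`lambda` = eigenvalues of `P K P` times
#' `scale`).
#'
#' @param q Observed statistic.
#' @param lambda Mixture weights (eigenvalues). Non-positive and negligible
#'   weights (below `1e-10 * max`) are dropped.
#' @param kernel,projection Alternative input: symmetric PSD kernel and
#'   projection matrix from which weights are computed.
#' @param scale Multiplier applied to kernel eigenvalues (null dispersion).
#' @return p-value in (0, 1]; returns 1 when all weights are ~0.
#' @export
quadform_pvalue <- function(q, lambda = NULL, kernel = NULL,
                            projection = NULL, scale = 1) {
  if (is.null(lambda)) {
    if (is.null(kernel)) stop("give either lambda or a kernel matrix")
    K <- as.matrix(kernel)
    if (!is.null(projection)) K <- projection %*% K %*% projection
    lambda <- eigen(sym_part(K), symmetric = TRUE, only.values = TRUE)$values
    lambda <- lambda * scale
  }
  lambda <- lambda[lambda > 0]
  if (!length(lambda) || max(lambda) <= 0 ||
      sum(lambda) < 1e-12 * max(1, abs(q))) {
    return(1)
  }
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  if (q <= 0) return(1)
  p <- tryCatch(imhof_tail(q, lambda), error = function(e) NA_real_)
  # the oscillatory integral can misbehave in deep tails; fall back to
  # moment matching there
  if (!is.finite(p) || p < 1e-10 || p > 1) p <- liu_tail(q, lambda)
  min(max(p, 1e-14), 1)
}

is_binary <- function(y) all(y %in% c(0, 1))

# Intercept-only null model: fitted mean, residuals and the dispersion that
# scales the kernel eigenvalues (mu(1-mu) for logistic, s^2 for identity).
null_model_fit <- function(y, phenotype_type = c("auto", "binary",
                                                 "continuous")) {
  phenotype_type <- match.arg(phenotype_type)
  if (phenotype_type == "auto") {
    phenotype_type <- if (is_binary(y)) "binary" else "continuous"
  }
  mu <- mean(y)
  if (phenotype_type == "binary") {
    if (mu <= 0 || mu >= 1) stop("singular null-model fit: phenotype constant")
    disp <- mu * (1 - mu)
  } else {
    disp <- var(y)
  }
  list(type = phenotype_type, mu = mu, residuals = y - mu, dispersion = disp)
}

quadform_result <- function(statistic, p_value, method, eigenweights) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         eigenweights = eigenweights),
    class = "quadform_result"
  )
}

#' @export
print.quadform_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%d eigenweights)\n",
              x$method, x$statistic, x$p_value, length(x$eigenweights)))
  invisible(x)
}

# Shared tail machinery: residual quadratic form in `K` with projected-kernel
# eigenweights scaled by the null dispersion.
quadform_test <- function(y, K, method, phenotype_type) {
  n <- length(y)
  nm <- null_model_fit(y, phenotype_type)
  e <- nm$residuals
  q <- drop(e %*% K %*% e)
  Kc <- K - matrix(colMeans(K), n, n, byrow = TRUE)
  PKP <- Kc - matrix(rowMeans(Kc), n, n)        # (I - 11'/n) K (I - 11'/n)
  lam <- eigen(sym_part(PKP), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)] * nm$dispersion
  if (max(abs(e)) == 0 || q <= 0) {
    return(quadform_result(max(q, 0), 1, method, lam))
  }
  quadform_result(q, quadform_pvalue(q, lam), method, lam)
}

genotype_counts <- function(G) {
  if (inherits(G, "genotype_matrix")) G$counts else as.matrix(G)
}

#' Expression-adjusted SKAT comparator
#'
#' SKAT quadratic form with the genotype kernel augmented by cross-product
#' expression similarity: `Ktilde_S(i, j) = sum_k w_k S_i S_j G_ik G_jk` on
#' the raw dosage counts (no smoothing), `Q = (Y - mu_hat)' Ktilde_S
#' (Y - mu_hat)` with an intercept-only null mean, and a mixture-chi-square
#' p-value.
#'
#' @param y Phenotype vector (binary 0/1 or continuous).
#' @param s Expression vector.
#' @param G A [genotype_matrix()] or plain n x p dosage matrix.
#' @param weights Per-SNV weights `w_k` (default all 1).
#' @param phenotype_type `"auto"` (default), `"binary"` or `"continuous"`.
#' @return A `quadform_result` (method `"adj_skat"`).
#' @export
adj_skat <- function(y, s, G, weights = NULL,
                     phenotype_type = c("auto", "binary", "continuous")) {
  Gm <- genotype_counts(G)
  n <- check_lengths(y, s, Gm[, 1])
  if (is.null(weights)) weights <- rep(1, ncol(Gm))
  if (length(weights) != ncol(Gm)) stop("one weight per SNV required")
  K <- tcrossprod(s) * (Gm %*% (weights * t(Gm)))
  quadform_test(y, K, "adj_skat", match.arg(phenotype_type))
}

#' Three-component variance component test (VCT) comparator
#'
#' `Qbar = (1/n) (Y - mu_hat)' { a1 GG' + a2 SS' + a3 CC' } (Y - mu_hat)`,
#' where `C` is the columnwise product of expression and genotypes (the
#' interaction design). By default each weight is the reciprocal square root
#' of the empirical variance of that component's kernel entries; a
#' zero-variance component has its variance floored (with a warning).
#'
#' @inheritParams adj_skat
#' @param weights Optional fixed `c(a1, a2, a3)`; `NULL` for the
#'   variance-scaled default.
#' @return A `quadform_result` (method `"vct"`).
#' @export
vct <- function(y, s, G, weights = NULL,
                phenotype_type = c("auto", "binary", "continuous")) {
  Gm <- genotype_counts(G)
  n <- check_lengths(y, s, Gm[, 1])
  K1 <- tcrossprod(Gm)
  K2 <- tcrossprod(s)
  K3 <- tcrossprod(Gm * s)
  if (is.null(weights)) {
    v <- c(var(as.vector(K1)), var(as.vector(K2)), var(as.vector(K3)))
    if (any(v < 1e-12)) {
      warning("zero-variance VCT component: weight capped")
      v <- pmax(v, 1e-12)
    }
    weights <- 1 / sqrt(v)
  }
  if (length(weights) != 3 || any(weights < 0)) {
    stop("weights must be 3 non-negative values (a1, a2, a3)")
  }
  K <- (weights[1] * K1 + weights[2] * K2 + weights[3] * K3) / n
  quadform_test(y, K, "vct", match.arg(phenotype_type))
}
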