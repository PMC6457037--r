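# Functional representation of genotype sequences.
#
# A region's minor-allele counts G_i(t_j) in {0,1,2} at physical positions t_j
# are treated as discrete observations of a smooth subject-level curve G_i(t)
# on [0,1]. Curves are fitted by penalized natural cubic splines with one
# shared basis and one shared roughness penalty, and everything downstream
# (inner products, mean curve, covariance eigen-structure) is computed in the
# shared coefficient space.

#' Construct a genotype matrix for one region
#'
#' @param counts Numeric matrix, subjects in rows and SNVs in columns; entries
#'   are minor-allele dosages 0/1/2, `NA` for missing.
#' @param positions Physical base-pair coordinates of the SNVs (length =
#'   `ncol(counts)`), non-decreasing after sorting.
#' @param sample_ids Optional subject labels.
#'
#' @details Columns are ordered by position. Duplicate positions are collapsed
#'   to a single column by averaging each subject's dosages (with a warning),
#'   since spline fitting needs distinct abscissae.
#'
#' @return An object of class `genotype_matrix` with elements `counts`,
#'   `positions`, `sample_ids`.
#' @export
genotype_matrix <- function(counts, positions, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  positions <- as.numeric(positions)
  if (length(positions) != ncol(counts)) {
    stop("length(positions) must equal ncol(counts)")
  }
  ok <- is.na(counts) | counts %in% c(0, 1, 2)
  if (!all(ok)) stop("non-missing genotype entries must be 0, 1 or 2")
  if (nrow(counts) < 2) stop("need at least 2 subjects")

  ord <- order(positions)
  positions <- positions[ord]
  counts <- counts[, ord, drop = FALSE]

  if (anyDuplicated(positions)) {
    warning("duplicate SNV positions collapsed by per-subject averaging")
    grp <- match(positions, unique(positions))
    counts <- t(apply(counts, 1, function(r) tapply(r, grp, mean)))
    positions <- unique(positions)
  }
  if (length(unique(positions)) < 2) {
    stop("need at least 2 distinct SNV positions")
  }
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(counts)))

  structure(
    list(counts = counts, positions = positions, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d subjects x %d SNVs, positions %s..%s, %d missing\n",
    nrow(x$counts), ncol(x$counts),
    format(min(x$positions)), format(max(x$positions)),
    sum(is.na(x$counts))
  ))
  invisible(x)
}

#' Rescale physical positions to the unit interval
#'
#' Affine map t -> (t - min) / (max - min); the first position maps to 0 and
#' the last to 1, preserving order.
#'
#' @param positions Numeric vector of at least 2 positions, not all equal.
#' @return Numeric vector in \[0, 1\].
#' @export
scale_positions <- function(positions) {
  stopifnot_finite(positions, "positions")
  if (length(positions) < 2) stop("need at least 2 positions")
  r <- range(positions)
  if (r[1] == r[2]) stop("all positions identical: degenerate domain")
  (positions - r[1]) / (r[2] - r[1])
}

# ---- natural cubic spline machinery (value representation) -----------------
#
# The basis is the cardinal natural-cubic-spline basis at K knots: B_k is the
# natural interpolant of the k-th unit vector, so a curve's coefficients are
# simply its values at the knots. The Green-Silverman band matrices give the
# roughness penalty Omega = Q R^-1 Q' with Omega[j,k] = integral B_j'' B_k''.

# 4-point Gauss-Legendre nodes/weights on [-1, 1]; exact through degree 7,
# enough for products of two cubics.
.gl4_x <- c(-0.8611363115940526, -0.3399810435848563,
            0.3399810435848563, 0.8611363115940526)
.gl4_w <- c(0.3478548451374538, 0.6521451548625461,
            0.6521451548625461, 0.3478548451374538)

gs_penalty <- function(knots) {
  K <- length(knots)
  if (K < 3) return(matrix(0, K, K))
  h <- diff(knots)
  Q <- matrix(0, K, K - 2)
  R <- matrix(0, K - 2, K - 2)
  for (j in 2:(K - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j, i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (i < K - 2) R[i, i + 1] <- R[i + 1, i] <- h[j] / 6
  }
  sym_part(Q %*% solve(R, t(Q)))
}

# Shared basis object: cardinal natural splines at `knots` (subset of the
# scaled positions, endpoints included).
ns_basis <- function(knots) {
  knots <- sort(unique(as.numeric(knots)))
  K <- length(knots)
  if (K < 2) stop("basis needs at least 2 knots")
  funs <- lapply(seq_len(K), function(k) {
    e <- numeric(K); e[k] <- 1
    splinefun(knots, e, method = "natural")
  })
  b <- structure(
    list(knots = knots, K = K, funs = funs),
    class = "ns_basis"
  )
  # exact Gram of the piecewise-cubic basis via per-interval Gauss-Legendre
  nodes <- unlist(lapply(seq_len(K - 1), function(i) {
    a <- knots[i]; bb <- knots[i + 1]
    (a + bb) / 2 + (bb - a) / 2 * .gl4_x
  }))
  wts <- unlist(lapply(seq_len(K - 1), function(i) {
    (knots[i + 1] - knots[i]) / 2 * .gl4_w
  }))
  B <- eval_basis(b, nodes)
  b$J <- sym_part(crossprod(B, wts * B))
  b$Omega <- gs_penalty(knots)
  b
}

# Evaluate all basis functions at points t: length(t) x K matrix.
eval_basis <- function(basis, t) {
  vapply(basis$funs, function(f) f(t), numeric(length(t)))
}

#' Fit penalized natural-cubic-spline curves to genotype sequences
#'
#' Each subject's dosage sequence is smoothed on the position-rescaled unit
#' interval with a shared natural-cubic-spline basis (cardinal basis at up to
#' `max_knots` knots placed at quantile-spaced SNV positions, endpoints
#' included) and a shared second-derivative roughness penalty. The penalty is
#' chosen once, by generalized cross-validation pooled over all subjects, so
#' subjects stay exchangeable.
#'
#' @param G A [genotype_matrix()] (no missing entries; see [impute_missing()]).
#' @param max_knots Cap on the number of knots/basis functions (default 35).
#' @param penalty `"gcv"` (default) or `"fixed"`.
#' @param penalty_value Roughness penalty when `penalty = "fixed"`.
#' @param lambda_grid Candidate penalties searched by GCV (log-spaced).
#'
#' @return An object of class `genotype_curves`: `basis` (knots, Gram matrix
#'   `J`, penalty matrix), `coefficients` (n x K; values of each fitted curve
#'   at the knots), `lambda` (penalty used), `positions01`.
#' @export
fit_curves <- function(G, max_knots = 35,
                       penalty = c("gcv", "fixed"), penalty_value = NULL,
                       lambda_grid = 10^seq(-8, 3, length.out = 16)) {
  penalty <- match.arg(penalty)
  if (!inherits(G, "genotype_matrix")) stop("G must be a genotype_matrix")
  Y <- G$counts
  if (anyNA(Y)) stop("missing genotypes present: run impute_missing() first")
  p <- ncol(Y)
  if (p < 4) stop("need at least 4 SNV positions for a cubic basis")

  t01 <- scale_positions(G$positions)
  K <- min(p, max_knots)
  knot_idx <- unique(round(seq(1, p, length.out = K)))
  basis <- ns_basis(t01[knot_idx])
  K <- basis$K

  N <- eval_basis(basis, t01)            # p x K design
  NtN <- crossprod(N)
  Rc <- tryCatch(chol(NtN), error = function(e) {
    chol(NtN + 1e-10 * mean(diag(NtN)) * diag(K))
  })
  # simultaneous diagonalization: (N'N + lambda*Omega)^-1 via eigen of
  # R^-T Omega R^-1
  RtO <- backsolve(Rc, basis$Omega, transpose = TRUE)       # R^-T Omega
  M <- sym_part(t(backsolve(Rc, t(RtO), transpose = TRUE))) # R^-T Omega R^-1
  eg <- eigen(M, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  RtNt <- backsolve(Rc, t(N), transpose = TRUE)             # R^-T N' (K x p)
  P1 <- crossprod(U, RtNt)                                  # U' R^-T N'
  E <- t(RtNt) %*% U                                        # N R^-1 U (p x K)
  Z <- P1 %*% t(Y)                                          # K x n

  if (penalty == "fixed") {
    if (is.null(penalty_value) || penalty_value < 0) {
      stop("penalty = \"fixed\" needs a non-negative penalty_value")
    }
    lambda <- penalty_value
  } else {
    gcv <- vapply(lambda_grid, function(l) {
      s <- 1 / (1 + l * d)
      fit <- E %*% (s * Z)                                  # p x n fitted
      rss <- sum((t(Y) - fit)^2)
      edf <- sum(s)
      (rss / (nrow(Y) * p)) / (1 - edf / p)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv)]
  }

  s <- 1 / (1 + lambda * d)
  beta <- t(backsolve(Rc, U %*% (s * Z)))                   # n x K
  dimnames(beta) <- list(G$sample_ids, NULL)

  structure(
    list(basis = basis, coefficients = beta, lambda = lambda,
         positions01 = t01),
    class = "genotype_curves"
  )
}

#' Evaluate fitted genotype curves
#'
#' @param object A `genotype_curves` object.
#' @param t Points in \[0, 1\] at which to evaluate.
#' @param ... Unused.
#' @return Matrix, subjects x `length(t)`.
#' @export
predict.genotype_curves <- function(object, t, ...) {
  object$coefficients %*% t(eval_basis(object$basis, t))
}

#' @export
print.genotype_curves <- function(x, ...) {
  cat(sprintf(
    "genotype_curves: %d subjects, %d basis functions, penalty %.3g\n",
    nrow(x$coefficients), x$basis$K, x$lambda
  ))
  invisible(x)
}

#' Pairwise inner products of fitted genotype curves
#'
#' Entry (i, j) is the L2 inner product of curves i and j on \[0, 1\],
#' computed exactly in coefficient space as `beta_i' J beta_j` with `J` the
#' basis Gram matrix.
#'
#' @param curves A `genotype_curves` object.
#' @return Symmetric positive semi-definite n x n matrix.
#' @export
curve_gram <- function(curves) {
  stopifnot(inherits(curves, "genotype_curves"))
  B <- curves$coefficients
  sym_part(B %*% curves$basis$J %*% t(B))
}

#' Functional moments of the fitted genotype curves
#'
#' Computes the sample mean curve, its squared L2 norm, and the eigenpairs of
#' the empirical covariance operator `Gamma_hat(s, t) = mean_i (G_i(t) -
#' Gbar(t))(G_i(s) - Gbar(s))` by solving the Gram-weighted eigenproblem in
#' coefficient space (so the eigenfunctions are orthonormal in L2), together
#' with the projections `delta_k` of the mean curve on each eigenfunction.
#' These are the ingredients of the plug-in null variance of the IU statistic.
#'
#' @param curves A `genotype_curves` object with n >= 2 subjects.
#' @param rel_tol Eigenvalues below `rel_tol * max(eigenvalue)` are dropped.
#' @return An object of class `functional_moments`: `mean_coeffs`,
#'   `mean_sq_norm`, `eigenvalues` (descending), `eigenfun_coeffs` (m x K),
#'   `deltas`, `sum_lambda_delta2`, `trace` (= integral of
#'   `Gamma_hat(t, t)`), plus the shared `basis`.
#' @export
functional_moments <- function(curves, rel_tol = 1e-10) {
  stopifnot(inherits(curves, "genotype_curves"))
  B <- curves$coefficients
  n <- nrow(B)
  if (n < 2) stop("need at least 2 subjects")
  J <- curves$basis$J
  mean_coeffs <- colMeans(B)
  mean_sq_norm <- drop(mean_coeffs %*% J %*% mean_coeffs)

  Cc <- sweep(B, 2, mean_coeffs)
  Scov <- crossprod(Cc) / n
  Rj <- chol(J)
  M <- sym_part(Rj %*% Scov %*% t(Rj))
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  total_trace <- sum(lam)

  keep <- if (total_trace > 0) which(lam > rel_tol * lam[1]) else integer(0)
  if (length(keep)) {
    V <- backsolve(Rj, eg$vectors[, keep, drop = FALSE])  # J-orthonormal
    deltas <- drop(crossprod(V, J %*% mean_coeffs))
    lam <- lam[keep]
  } else {
    V <- matrix(0, ncol(B), 0)
    deltas <- numeric(0)
    lam <- numeric(0)
  }

  structure(
    list(
      mean_coeffs = mean_coeffs,
      mean_sq_norm = mean_sq_norm,
      eigenvalues = lam,
      eigenfun_coeffs = t(V),
      deltas = deltas,
      sum_lambda_delta2 = sum(lam * deltas^2),
      trace = total_trace,
      basis = curves$basis,
      n = n
    ),
    class = "functional_moments"
  )
}

#' @export
print.functional_moments <- function(x, ...) {
  cat(sprintf(
    paste0("functional_moments: ||Gbar||^2 = %.4g, %d retained components,\n",
           "  sum lambda_k delta_k^2 = %.4g, trace(Gamma_hat) = %.4g\n"),
    x$mean_sq_norm, length(x$eigenvalues), x$sum_lambda_delta2, x$trace
  ))
  invisible(x)
}
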