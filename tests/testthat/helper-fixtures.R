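# Shared fixtures, built in code.

# Memoize expensive shared objects across test files.
.fixture_env <- new.env(parent = emptyenv())

# Default-spec haplotype panel used by the simulation-style tests.
shared_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- gen_genotype_panel(seed = 424242)
  }
  .fixture_env$panel
}

# Small deterministic genotype matrix (n subjects, p SNVs) with a smooth
# dosage signal plus subject-level variation.
tiny_genotypes <- function(n = 12, p = 20, seed = 99) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(5e4, p))
    t01 <- (pos - min(pos)) / (max(pos) - min(pos))
    counts <- t(vapply(seq_len(n), function(i) {
      prob <- pmin(pmax(0.15 + 0.1 * sin(2 * pi * t01 + i / 3), 0.02), 0.6)
      rbinom(p, 2, prob)
    }, numeric(p)))
    genotype_matrix(counts, pos)
  })
}

# Hand-built curves object on a given basis with arbitrary coefficients,
# bypassing the smoother (for oracle tests of gram/moments algebra).
manual_curves <- function(coefficients, knots) {
  basis <- iutest:::ns_basis(knots)
  structure(
    list(basis = basis, coefficients = as.matrix(coefficients),
         lambda = 0, positions01 = knots),
    class = "genotype_curves"
  )
}

# Unit-constant curves for n subjects: G_i(t) = 1 on [0, 1].
unit_curves <- function(n) {
  manual_curves(matrix(1, n, 2), c(0, 1))
}

# Seed-pinned normal draws (for null-reduction identities).
rnorm_with_seed <- function(n, mean, sd, seed) {
  withr::with_seed(seed, rnorm(n) + mean)
}

# Basis evaluation on a grid (internal helper surfaced for oracle tests).
eval_basis_for_test <- function(curves, t) {
  iutest:::eval_basis(curves$basis, t)
}

# Dense-grid trapezoid weights on [0, 1].
trapz_weights <- function(m) {
  h <- 1 / (m - 1)
  w <- rep(h, m)
  w[c(1, m)] <- h / 2
  w
}
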