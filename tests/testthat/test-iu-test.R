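test_that("the U statistic matches its defining double sum", {
  # single pair with unit similarities
  expect_equal(compute_un(c(1, 1), c(1, 1), unit_curves(2)), 1)
  # zero phenotype kills every summand
  expect_equal(compute_un(rep(0, 5), rnorm(5), unit_curves(5)), 0)

  # brute-force oracle over ordered pairs
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 8
      y <- rnorm(n); s <- rnorm(n)
      knots <- sort(c(0, runif(4), 1))
      cur <- manual_curves(matrix(rnorm(n * 6), n), knots)
    })
    gram <- curve_gram(cur)
    u_loop <- 0
    for (i in 1:8) for (j in 1:8) {
      if (i != j) u_loop <- u_loop + y[i] * y[j] * s[i] * s[j] * gram[i, j]
    }
    u_loop <- u_loop / (8 * 7)
    expect_equal(compute_un(y, s, gram), u_loop, tolerance = 1e-12)
  }
})

test_that("the plug-in null mean is Ybar^2 Sbar^2 ||Gbar||^2", {
  mom1 <- functional_moments(unit_curves(3))
  expect_equal(estimate_null_mean(c(1, 1, 1), c(1, 1, 1), mom1), 1)
  expect_warning(estimate_null_mean(c(-1, 0, 1), c(1, 1, 1), mom1),
                 "violated")

  withr::with_seed(7, {
    knots <- sort(c(0, runif(6), 1))
    cur <- manual_curves(matrix(rnorm(10 * 8), 10), knots)
    y <- rnorm(10, 2); s <- rnorm(10, 1)
  })
  mom <- functional_moments(cur)
  tt <- seq(0, 1, length.out = 2e4 + 1)
  gbar <- colMeans(predict(cur, tt))
  oracle <- mean(y)^2 * mean(s)^2 *
    sum(trapz_weights(length(tt)) * gbar^2)
  expect_equal(estimate_null_mean(y, s, mom), oracle, tolerance = 1e-6)
})

test_that("the null variance estimators follow their closed forms", {
  # constant phenotype and expression: theorem variance vanishes
  mom <- functional_moments(unit_curves(4))
  expect_equal(
    estimate_null_variance(rep(2, 4), rep(3, 4), mom, "theorem"), 0
  )
  # identical curves, unit means/variances: only the second term survives
  y <- c(0, 1, 2); s <- c(0, 1, 2)   # mean 1, sample variance 1
  mom3 <- functional_moments(unit_curves(3))
  expect_equal(estimate_null_variance(y, s, mom3, "theorem"), 4)
  # expansion variant at the same inputs: first term drops, second is
  # 4 * 1 * (1 + 1 + 1) * 1
  expect_equal(estimate_null_variance(y, s, mom3, "expansion"), 12)
})

test_that("the theorem variance tracks the Monte-Carlo variance of the statistic", {
  # n * Var_MC(U_n - mu0_hat) over fresh null replicates against the average
  # plug-in variance (the calibrated variant)
  panel <- shared_panel()
  n <- 500; reps <- 400
  stat <- sig <- sig_exp <- numeric(reps)
  for (r in seq_len(reps)) {
    seed <- iutest:::derive_seed(5151, r)
    G <- draw_genotypes(panel, n, 100, seed = iutest:::derive_seed(seed, 1))
    s <- gen_expression(n, seed = iutest:::derive_seed(seed, 2))
    y <- gen_null_phenotype("gaussian", n, seed = iutest:::derive_seed(seed, 3))
    cur <- fit_curves(G)
    mom <- functional_moments(cur)
    stat[r] <- compute_un(y, s, cur) - estimate_null_mean(y, s, mom)
    sig[r] <- estimate_null_variance(y, s, mom, "theorem")
    sig_exp[r] <- estimate_null_variance(y, s, mom, "expansion")
  }
  expect_lt(abs(n * var(stat) / mean(sig) - 1), 0.15)
  # the expansion variant targets the known-null-mean statistic and
  # over-estimates the variance of the estimated-mean statistic by a wide
  # margin — this is what pins "theorem" as the default
  expect_lt(n * var(stat) / mean(sig_exp), 0.6)
})

test_that("iu_test composes the estimator operations", {
  G <- tiny_genotypes(n = 30, p = 30, seed = 17)
  withr::with_seed(18, {
    y <- rnorm(30, 1)
    s <- rnorm(30, 1, 1.2)
  })
  cur <- fit_curves(G)
  res <- iu_test(y, s, cur)
  mom <- functional_moments(cur)
  un <- compute_un(y, s, cur)
  mu0 <- estimate_null_mean(y, s, mom)
  sig2 <- estimate_null_variance(y, s, mom, "theorem")
  tn <- sqrt(30) * (un - mu0) / sqrt(sig2)
  expect_equal(res$u_n, un, tolerance = 1e-12)
  expect_equal(res$t_n, tn, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(tn)), tolerance = 1e-12)
  expect_equal(res$p_value < 0.05, res$reject)
})

test_that("degenerate inputs are refused loudly", {
  G <- tiny_genotypes(n = 10, p = 20)
  cur <- fit_curves(G)
  # constant phenotype and expression: sigma_hat = 0
  expect_error(
    suppressWarnings(iu_test(rep(2, 10), rep(2, 10), cur)),
    "degenerate"
  )
  # near-zero sample mean triggers the assumption warning
  withr::with_seed(3, {
    y0 <- rnorm(10, 0, 1); y0 <- y0 - mean(y0) + 0.01
    s <- rnorm(10, 1, 0.1)
  })
  expect_warning(iu_test(y0, s, cur), "2 standard errors")
  # identical curves: genetics-only variance degenerates
  expect_error(
    suppressWarnings(genetics_only_test(c(0, 1, 2, 1), unit_curves(4))),
    "degenerate"
  )
  expect_error(compute_un(1, 1, matrix(1, 1, 1)), "at least 2")
})

test_that("unit expression collapses the IU statistic to the genetics-only test", {
  G <- tiny_genotypes(n = 16, p = 24, seed = 23)
  cur <- fit_curves(G)
  withr::with_seed(24, y <- rnorm(16, 1))
  ones <- rep(1, 16)
  full <- suppressWarnings(iu_test(y, ones, cur))
  gen <- genetics_only_test(y, cur)
  expect_equal(full$u_n, gen$u_n)
  expect_equal(full$mu0_hat, gen$mu0_hat)
  # with Sbar = 1 and s_S = 0 the two variance formulas coincide as well:
  # the S-variance terms drop and both reduce to 4 Ybar^2 s_Y^2 sum(lambda
  # delta^2)
  expect_gt(gen$sigma2_hat, 0)
  expect_equal(full$sigma2_hat, gen$sigma2_hat)
})

test_that("genetics-only test is calibrated under a Gaussian null", {
  panel <- shared_panel()
  reps <- 500
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    seed <- iutest:::derive_seed(8282, r)
    G <- draw_genotypes(panel, 200, 100, seed = iutest:::derive_seed(seed, 1))
    y <- gen_null_phenotype("gaussian", 200,
                            seed = iutest:::derive_seed(seed, 2))
    pv[r] <- genetics_only_test(y, fit_curves(G))$p_value
  }
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("the three-level statistic extends the two-level one", {
  G <- tiny_genotypes(n = 8, p = 20, seed = 29)
  cur <- fit_curves(G)
  gram <- curve_gram(cur)
  withr::with_seed(30, {
    y <- rnorm(8, 1); s <- rnorm(8, 1); rr <- rnorm(8, 1)
  })
  # unit third layer reduces exactly to the two-level statistic
  expect_identical(multilevel_un(y, s, rep(1, 8), gram),
                   compute_un(y, s, gram))
  expect_equal(multilevel_un(c(1, 1), c(1, 1), c(1, 1), unit_curves(2)), 1)

  # brute-force triple-weighted double sum
  u_loop <- 0
  for (i in 1:8) for (j in 1:8) {
    if (i != j) {
      u_loop <- u_loop +
        y[i] * y[j] * s[i] * s[j] * rr[i] * rr[j] * gram[i, j]
    }
  }
  expect_equal(multilevel_un(y, s, rr, gram), u_loop / 56,
               tolerance = 1e-12)

  res3 <- suppressWarnings(multilevel_test(y, s, rr, cur))
  res2 <- suppressWarnings(iu_test(y, s * rr, cur))
  expect_equal(res3$t_n, res2$t_n)
  expect_identical(res3$statistic, "IU3")
})

test_that("subject permutation leaves the test invariant", {
  G <- tiny_genotypes(n = 20, p = 25, seed = 37)
  cur <- fit_curves(G)
  withr::with_seed(38, {
    y <- rnorm(20, 1); s <- rnorm(20, 1, 1.2)
    perm <- sample(20)
  })
  base <- iu_test(y, s, cur)
  cur_p <- cur
  cur_p$coefficients <- cur$coefficients[perm, ]
  alt <- iu_test(y[perm], s[perm], cur_p)
  expect_equal(alt$u_n, base$u_n)
  expect_equal(alt$mu0_hat, base$mu0_hat)
  expect_equal(alt$sigma2_hat, base$sigma2_hat)
  expect_equal(alt$t_n, base$t_n)
})

test_that("rescaling phenotype or expression leaves T_n invariant", {
  G <- tiny_genotypes(n = 15, p = 22, seed = 41)
  cur <- fit_curves(G)
  withr::with_seed(42, {
    y <- rnorm(15, 2); s <- rnorm(15, 2, 1)
  })
  base <- iu_test(y, s, cur)
  for (cc in c(3, -0.5)) {
    alt <- iu_test(cc * y, s, cur)
    expect_equal(alt$u_n, cc^2 * base$u_n)
    expect_equal(alt$mu0_hat, cc^2 * base$mu0_hat)
    expect_equal(alt$sigma2_hat, cc^4 * base$sigma2_hat)
    expect_equal(abs(alt$t_n), abs(base$t_n))
    alt_s <- suppressWarnings(iu_test(y, cc * s, cur))
    expect_equal(abs(alt_s$t_n), abs(base$t_n))
  }
})
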