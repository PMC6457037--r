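test_that("generators are pure functions of parameters and seed", {
  p1 <- gen_genotype_panel(p = 60, n_hap = 200, seed = 5)
  p2 <- gen_genotype_panel(p = 60, n_hap = 200, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(
    p1$haplotypes, gen_genotype_panel(p = 60, n_hap = 200, seed = 6)$haplotypes
  ))

  G1 <- draw_genotypes(p1, 30, p = 20, seed = 9)
  expect_identical(G1, draw_genotypes(p1, 30, p = 20, seed = 9))
  expect_identical(gen_expression(50, seed = 3), gen_expression(50, seed = 3))
  expect_identical(gen_null_phenotype("t4", 50, seed = 3),
                   gen_null_phenotype("t4", 50, seed = 3))
})

test_that("the haplotype panel has the advertised LD and MAF structure", {
  # independence limit: block length 1
  p_ind <- gen_genotype_panel(p = 200, n_hap = 600, ld_block_len = 1,
                              seed = 11)
  G <- draw_genotypes(p_ind, 400, p = 200, seed = 12)
  adj_cor <- vapply(seq_len(199), function(j) {
    a <- G$counts[, j]; b <- G$counts[, j + 1]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  expect_lt(abs(mean(adj_cor, na.rm = TRUE)), 3 / sqrt(400))

  # default blocks: positive adjacent correlation on average
  pan <- shared_panel()
  Gd <- draw_genotypes(pan, 400, p = 200, seed = 13)
  adj_cor_d <- vapply(seq_len(199), function(j) {
    a <- Gd$counts[, j]; b <- Gd$counts[, j + 1]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  expect_gt(mean(adj_cor_d, na.rm = TRUE), 0.1)

  # every column polymorphic with MAF in (0, 0.5]
  expect_true(all(pan$maf > 0 & pan$maf <= 0.5))
  # realized median MAF inside the target spectrum's interquartile range
  big <- gen_genotype_panel(p = 2000, n_hap = 2000, seed = 14)
  iqr <- qbeta(c(0.25, 0.75), 0.3, 8)
  med <- stats::median(big$maf)
  expect_gt(med, pmax(iqr[1], 5e-4) * 0.5)
  expect_lt(med, iqr[2] * 2)
})

test_that("multinomial imputation respects the observed proportions", {
  pan <- gen_genotype_panel(p = 30, n_hap = 200, seed = 21)
  G <- draw_genotypes(pan, 25, p = 20, seed = 22)
  expect_identical(impute_missing(G, seed = 1), G)  # nothing to do

  # a column observed all zero imputes to zero
  counts <- G$counts
  counts[, 3] <- 0
  counts[1:5, 3] <- NA
  counts[2, 7] <- NA
  G_miss <- genotype_matrix(counts, G$positions)
  G_imp <- impute_missing(G_miss, seed = 2)
  expect_false(anyNA(G_imp$counts))
  expect_true(all(G_imp$counts[1:5, 3] == 0))
  # non-missing entries untouched
  keep <- !is.na(counts)
  expect_identical(G_imp$counts[keep], counts[keep])

  # frequency check against the observed proportions (0.25, 0.5, 0.25)
  obs_col <- c(rep(0, 5), rep(1, 10), rep(2, 5))
  draws <- vapply(1:2000, function(k) {
    cc <- cbind(c(obs_col, rep(NA, 5)), rep(1, 25))
    Gm <- genotype_matrix(cc, c(100, 200))
    sum(impute_missing(Gm, seed = 1000 + k)$counts[21:25, 1] == 1)
  }, numeric(1))
  frac1 <- sum(draws) / (2000 * 5)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.5 * 0.5 / 1e4))

  # fully missing column is an error
  cc <- cbind(rep(NA_real_, 6), rep(1, 6))
  expect_error(impute_missing(genotype_matrix(cc, c(1, 2)), seed = 1),
               "fully missing")
})

test_that("expression and null phenotype laws have the stated moments", {
  s <- gen_expression(1e5, seed = 31)
  expect_lt(abs(mean(s) - 1), 3 * 1.2 / sqrt(1e5))
  expect_lt(abs(sd(s) / 1.2 - 1), 0.02)

  yb <- gen_null_phenotype("bernoulli", 1e5, seed = 32)
  p0 <- 1 / (1 + exp(0.2))
  expect_lt(abs(mean(yb) - p0), 3 * sqrt(p0 * (1 - p0) / 1e5))

  yg <- gen_null_phenotype("gaussian", 1e5, seed = 33)
  expect_lt(abs(mean(yg) - 1), 3 / sqrt(1e5))

  # symmetry of the unshifted heavy-tail nulls
  yt <- gen_null_phenotype("t2", 1e5, shift = 0, seed = 34)
  expect_lt(abs(stats::median(yt)), 3 * 1.57 / sqrt(1e5))
  # default shift recenters at 1
  yt1 <- gen_null_phenotype("t2", 1e5, seed = 34)
  expect_equal(yt1, yt + 1)
  yd <- gen_null_phenotype("de", 1e5, seed = 35)
  expect_lt(abs(mean(yd) - 1), 3 * sqrt(2) / sqrt(1e5))
})

test_that("alternative models reduce exactly to their nulls", {
  pan <- gen_genotype_panel(p = 60, n_hap = 400, seed = 41)
  G <- draw_genotypes(pan, 500, p = 50, seed = 42)
  s <- gen_expression(500, seed = 43)

  # Model 1 with all effects zero is the Bernoulli / Gaussian null stream
  y_m1 <- gen_model1(G, s, sigma_G = 0, beta_S = 0, gamma_bound = 0,
                     noise = "logit", seed = 44)
  expect_identical(y_m1, gen_null_phenotype("bernoulli", 500, seed = 44))
  y_m1g <- gen_model1(G, s, 0, 0, 0, noise = "gauss", seed = 44)
  expect_equal(y_m1g, rnorm_with_seed(500, 2, 1, seed = 44))

  # Model 2 with no causal SNVs is the same null stream
  y_m2 <- gen_model2(G, s, c_scale = 1, m = 0, noise = "logit", seed = 45)
  expect_identical(y_m2, gen_null_phenotype("bernoulli", 500, seed = 45))

  # Model 3 with an unreachable threshold is the baseline model
  v_max <- max(abs(s) * rowSums(G$counts))
  y_m3 <- gen_model3(G, s, d = v_max + 1, m = 4, noise = "gauss", seed = 46)
  y_null <- gen_model2(G, s, c_scale = 0, m = 4, noise = "gauss", seed = 46)
  expect_identical(y_m3, y_null)
})

test_that("model effects scale and threshold as designed", {
  pan <- gen_genotype_panel(p = 60, n_hap = 400, seed = 51)
  G <- draw_genotypes(pan, 2000, p = 50, seed = 52)
  s_pos <- abs(gen_expression(2000, seed = 53)) + 0.1

  # linearity in c on the same seed: equal increments
  y0 <- gen_model2(G, s_pos, c_scale = 0, m = 4, noise = "gauss", seed = 54)
  y1 <- gen_model2(G, s_pos, c_scale = 1, m = 4, noise = "gauss", seed = 54)
  y2 <- gen_model2(G, s_pos, c_scale = 2, m = 4, noise = "gauss", seed = 54)
  expect_equal(y2 - y1, y1 - y0, tolerance = 1e-12)

  # added interaction variance exceeds the noise variance
  expect_gt(var(y1), 1)

  # with everything positive, threshold zero coincides with Model 2 at c = 1
  y_m3_0 <- gen_model3(G, s_pos, d = 0, m = 4, noise = "gauss", seed = 54)
  expect_equal(y_m3_0, y1, tolerance = 1e-12)

  # crossing fraction non-increasing in the threshold
  fracs <- vapply(c(0, 1, 2, 4, 8), function(d) {
    ym <- gen_model3(G, s_pos, d = d, m = 4, noise = "gauss", seed = 54)
    mean(ym != y0)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))

  # logit link monotone in expression under beta_S = 2
  G2 <- draw_genotypes(pan, 2e4, p = 50, seed = 55)
  s2 <- gen_expression(2e4, seed = 56)
  yl <- gen_model1(G2, s2, sigma_G = 0, beta_S = 2, gamma_bound = 0,
                   noise = "logit", seed = 57)
  dec <- cut(s2, quantile(s2, 0:10 / 10), include.lowest = TRUE)
  rate_by_decile <- tapply(yl, dec, mean)
  expect_gt(cor(seq_len(10), rate_by_decile, method = "spearman"), 0.9)
})

test_that("case-control subsampling is balanced, unique and uniform", {
  withr::with_seed(61, y <- rbinom(300, 1, 0.45))
  idx <- sample_case_control(y, 50, 50, seed = 62)
  expect_length(idx, 100)
  expect_false(anyDuplicated(idx) > 0)
  expect_equal(sum(y[idx] == 1), 50)
  expect_equal(sum(y[idx] == 0), 50)

  expect_error(sample_case_control(c(0, 1, 1), 2, 2, seed = 1), "exhausted")

  # uniformity over cases: chi-square goodness of fit on a small pool
  y_small <- c(rep(1, 10), rep(0, 10))
  counts <- numeric(10)
  for (k in 1:4000) {
    id <- sample_case_control(y_small, 3, 3, seed = 70000 + k)
    counts[id[id <= 10]] <- counts[id[id <= 10]] + 1
  }
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})
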