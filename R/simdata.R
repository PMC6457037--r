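# Seeded generators for the simulation study.
#
# Genotypes come from a synthetic block-LD haplotype pool: a latent Gaussian
# with autoregressive correlation inside blocks is thresholded column-wise to
# hit a Beta-distributed minor-allele-frequency spectrum skewed toward rare
# variants; subjects are formed by pairing haplotypes. Expression is
# N(1, 1.2^2). Null phenotypes come in five flavours (Bernoulli(1/(1+e^0.2)),
# N(1,1), shifted T2 / T4 / double-exponential), and three alternative model
# families add marginal, multiplicative-interaction and threshold-interaction
# effects. Every generator is a pure function of (parameters, seed).

#' Generate a synthetic block-LD haplotype panel
#'
#' Emulates a resequenced 1 Mb region: `n_hap` haplotypes over `p` SNVs with
#' positive adjacent-SNV correlation inside blocks of `ld_block_len` SNVs and
#' a Beta minor-allele-frequency spectrum. Columns that come out monomorphic
#' or with frequency above 0.5 are resampled/flipped so every panel column is
#' a polymorphic minor-allele count.
#'
#' @param p Number of SNVs in the panel (default 3000, the density of a
#'   resequenced 1 Mb region).
#' @param n_hap Number of haplotypes (default 2184, i.e. 1092 diploids).
#' @param maf_spectrum `c(shape1, shape2)` of the Beta target MAF law
#'   (default `c(0.3, 8)`: rare-skewed, median MAF about 1% and roughly 78%
#'   of SNVs below 5%, as in resequencing data); draws are clipped to
#'   `[maf_min, 0.5]`.
#' @param maf_min Lower clip for target MAFs.
#' @param ld_block_len Block length; 1 gives independent SNVs.
#' @param rho Within-block latent autocorrelation.
#' @param window Physical span (bp) over which positions are drawn uniformly.
#' @param seed RNG seed (same seed, same panel, bit for bit).
#' @return A `genotype_panel`: `haplotypes` (n_hap x p 0/1), `positions`
#'   (sorted bp), `maf` (realized haplotype frequencies), `resampled`
#'   (count of columns that had to be redrawn).
#' @export
gen_genotype_panel <- function(p = 3000, n_hap = 2184,
                               maf_spectrum = c(0.3, 8), maf_min = 5e-4,
                               ld_block_len = 50, rho = 0.95,
                               window = 1e6, seed = NULL) {
  stopifnot(p >= 1, n_hap >= 4, ld_block_len >= 1)
  with_seed_opt(seed, {
    maf <- pmin(pmax(rbeta(p, maf_spectrum[1], maf_spectrum[2]), maf_min), 0.5)
    block <- ceiling(seq_len(p) / ld_block_len)
    z <- matrix(rnorm(n_hap * p), n_hap, p)
    if (ld_block_len > 1) {
      for (j in 2:p) {
        if (block[j] == block[j - 1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
    }
    H <- (z <= matrix(qnorm(maf), n_hap, p, byrow = TRUE)) + 0L

    # enforce polymorphic minor-allele columns
    resampled <- 0L
    for (j in seq_len(p)) {
      tries <- 0L
      while (length(unique(H[, j])) == 1L && tries < 50L) {
        H[, j] <- (rnorm(n_hap) <= qnorm(max(maf[j], 2 / n_hap))) + 0L
        tries <- tries + 1L
        resampled <- resampled + (tries == 1L)
      }
      if (length(unique(H[, j])) == 1L) {
        # last resort: plant one carrier so the column is polymorphic
        H[sample.int(n_hap, 1L), j] <- 1L - H[1L, j]
        resampled <- resampled + 1L
      }
      f <- mean(H[, j])
      if (f > 0.5) H[, j] <- 1L - H[, j]
    }

    positions <- sort(sample.int(window, p))
    structure(
      list(haplotypes = H, positions = positions, maf = colMeans(H),
           target_maf = maf, resampled = resampled,
           provenance = "synthetic block-LD panel"),
      class = "genotype_panel"
    )
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel (%s): %d haplotypes x %d SNVs, median MAF %.3f\n",
    x$provenance, nrow(x$haplotypes), ncol(x$haplotypes), stats::median(x$maf)
  ))
  invisible(x)
}

#' Draw a genotype matrix from a haplotype panel
#'
#' Picks a segment of `p` consecutive SNVs uniformly from the panel and forms
#' `n` diploid subjects by pairing two haplotypes drawn with replacement.
#'
#' @param panel A [gen_genotype_panel()] object.
#' @param n Number of subjects.
#' @param p Segment length (consecutive SNVs; default 100).
#' @param seed RNG seed.
#' @param start Optional fixed window start (1-based SNV index); by default
#'   the window is drawn uniformly. Fixing it pins the genetic architecture
#'   across replicates (e.g. for power experiments at one locus).
#' @return A [genotype_matrix()].
#' @export
draw_genotypes <- function(panel, n, p = 100, seed = NULL, start = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  P <- ncol(panel$haplotypes)
  if (p > P) stop("segment longer than panel")
  if (!is.null(start) && (start < 1 || start > P - p + 1)) {
    stop("window start out of range")
  }
  with_seed_opt(seed, {
    if (is.null(start)) start <- sample.int(P - p + 1L, 1L)
    cols <- start:(start + p - 1L)
    i1 <- sample.int(nrow(panel$haplotypes), n, replace = TRUE)
    i2 <- sample.int(nrow(panel$haplotypes), n, replace = TRUE)
    counts <- panel$haplotypes[i1, cols, drop = FALSE] +
      panel$haplotypes[i2, cols, drop = FALSE]
    genotype_matrix(counts, panel$positions[cols])
  })
}

#' Impute missing genotypes from the per-SNV sample proportions
#'
#' Each missing entry is drawn from {0, 1, 2} with probabilities equal to the
#' observed genotype proportions at that SNV (a multinomial plug-in).
#'
#' @param G A [genotype_matrix()], possibly with `NA` entries.
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(G, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  counts <- G$counts
  if (!anyNA(counts)) return(G)
  with_seed_opt(seed, {
    for (j in seq_len(ncol(counts))) {
      miss <- is.na(counts[, j])
      if (!any(miss)) next
      obs <- counts[!miss, j]
      if (!length(obs)) stop(sprintf("SNV column %d is fully missing", j))
      prob <- tabulate(obs + 1L, nbins = 3L) / length(obs)
      counts[miss, j] <- sample(0:2, sum(miss), replace = TRUE, prob = prob)
    }
    genotype_matrix(counts, G$positions, G$sample_ids)
  })
}

#' Generate gene expression values
#'
#' i.i.d. normal with mean 1 and standard deviation 1.2, the expression law
#' used throughout the simulation study.
#'
#' @param n Number of subjects.
#' @param mean,sd Distribution parameters.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
gen_expression <- function(n, mean = 1, sd = 1.2, seed = NULL) {
  with_seed_opt(seed, rnorm(n, mean, sd))
}

#' Generate a null phenotype
#'
#' The five null laws of the type-I-error study: `"bernoulli"` with success
#' probability `1/(1 + e^0.2)`, `"gaussian"` N(1, 1), Student `"t2"` / `"t4"`,
#' and `"de"` (double-exponential/Laplace, scale 1). The heavy-tailed laws are
#' conventionally centered at 0, but the test's normal reference needs a
#' nonzero phenotype mean, so they get a location `shift` (default +1,
#' mirroring the Gaussian null); set `shift = 0` to stress-test the
#' degenerate regime.
#'
#' @param dist One of `"bernoulli"`, `"gaussian"`, `"t2"`, `"t4"`, `"de"`.
#' @param n Number of subjects.
#' @param shift Location shift added to the t and double-exponential draws.
#' @param seed RNG seed.
#' @return Numeric phenotype vector.
#' @export
gen_null_phenotype <- function(dist = c("bernoulli", "gaussian", "t2", "t4",
                                        "de"),
                               n, shift = 1, seed = NULL) {
  dist <- match.arg(dist)
  with_seed_opt(seed, {
    switch(dist,
      bernoulli = rbinom(n, 1, 1 / (1 + exp(0.2))),
      gaussian = rnorm(n, 1, 1),
      t2 = rt(n, df = 2) + shift,
      t4 = rt(n, df = 4) + shift,
      de = {
        # Laplace(0, 1) as difference representation
        e <- rexp(n) - rexp(n)
        e / 1 + shift
      }
    )
  })
}

noise_draw <- function(noise, n) {
  switch(noise,
    gauss = rnorm(n),
    t2 = rt(n, df = 2),
    stop("unknown noise type: ", noise)
  )
}

link_response <- function(lp, noise, n) {
  if (noise == "logit") {
    rbinom(n, 1, 1 / (1 + exp(-lp)))
  } else {
    lp + noise_draw(noise, n)
  }
}

#' Phenotypes under the marginal-effect model (Model 1)
#'
#' Linear predictor `intercept + G' beta_G + S beta_S + S G' gamma` with
#' `beta_G ~ N(0, sigma_G^2)` i.i.d. per SNV and `gamma` either all zero or
#' i.i.d. uniform on `(-a, a)` (the random-effect interaction). The binary
#' model uses a logit link with intercept -0.2; the continuous models use
#' intercept 2 plus Gaussian or T2 noise.
#'
#' @param G A [genotype_matrix()] or dosage matrix.
#' @param s Expression vector.
#' @param sigma_G SD of the per-SNV marginal effects.
#' @param beta_S Expression effect.
#' @param gamma_bound Half-width `a` of the uniform interaction-effect law;
#'   0 for no interaction.
#' @param noise `"logit"` (binary), `"gauss"` or `"t2"`.
#' @param seed RNG seed (effects are redrawn per call).
#' @return Numeric phenotype vector.
#' @export
gen_model1 <- function(G, s, sigma_G = 0.1, beta_S = 0, gamma_bound = 0,
                       noise = c("logit", "gauss", "t2"), seed = NULL) {
  noise <- match.arg(noise)
  Gm <- genotype_counts(G)
  n <- check_lengths(s, Gm[, 1])
  p <- ncol(Gm)
  with_seed_opt(seed, {
    beta_G <- if (sigma_G > 0) rnorm(p, 0, sigma_G) else numeric(p)
    gam <- if (gamma_bound > 0) runif(p, -gamma_bound, gamma_bound)
           else numeric(p)
    intercept <- if (noise == "logit") -0.2 else 2
    lp <- intercept + drop(Gm %*% beta_G) + s * beta_S +
      s * drop(Gm %*% gam)
    link_response(lp, noise, n)
  })
}

#' Phenotypes under the multiplicative-interaction model (Model 2)
#'
#' Predictor `intercept + c * S * G' W` with `W` the indicator of `m`
#' causal SNVs chosen uniformly without replacement; `m = 0` or `c = 0`
#' reduces exactly to the null.
#'
#' @inheritParams gen_model1
#' @param c_scale Interaction scale `c`.
#' @param m Number of causal SNVs.
#' @param causal_idx Optional fixed causal-SNV indices (overrides the random
#'   choice of `m` SNVs; useful to hold the architecture fixed across
#'   replicates).
#' @return Numeric phenotype vector.
#' @export
gen_model2 <- function(G, s, c_scale = 1, m = 4,
                       noise = c("logit", "gauss", "t2"), seed = NULL,
                       causal_idx = NULL) {
  noise <- match.arg(noise)
  Gm <- genotype_counts(G)
  n <- check_lengths(s, Gm[, 1])
  if (m > ncol(Gm)) stop("m exceeds the number of SNVs")
  with_seed_opt(seed, {
    w <- numeric(ncol(Gm))
    if (!is.null(causal_idx)) w[causal_idx] <- 1
    else if (m > 0) w[sample.int(ncol(Gm), m)] <- 1
    intercept <- if (noise == "logit") -0.2 else 2
    lp <- intercept + c_scale * s * drop(Gm %*% w)
    link_response(lp, noise, n)
  })
}

#' Phenotypes under the threshold-interaction model (Model 3)
#'
#' The interaction `S * G' W` (with `W` as in [gen_model2()]) contributes only
#' for subjects whose value exceeds the threshold `d`; a large `d` means a
#' weak effect and `d` above the maximum reduces exactly to the null.
#'
#' @inheritParams gen_model2
#' @param d Threshold (non-negative).
#' @return Numeric phenotype vector.
#' @export
gen_model3 <- function(G, s, d = 0, m = 4,
                       noise = c("logit", "gauss", "t2"), seed = NULL,
                       causal_idx = NULL) {
  noise <- match.arg(noise)
  if (d < 0) stop("threshold d must be non-negative")
  Gm <- genotype_counts(G)
  n <- check_lengths(s, Gm[, 1])
  if (m > ncol(Gm)) stop("m exceeds the number of SNVs")
  with_seed_opt(seed, {
    w <- numeric(ncol(Gm))
    if (!is.null(causal_idx)) w[causal_idx] <- 1
    else if (m > 0) w[sample.int(ncol(Gm), m)] <- 1
    v <- s * drop(Gm %*% w)
    eff <- ifelse(v > d, v, 0)
    intercept <- if (noise == "logit") -0.2 else 2
    link_response(intercept + eff, noise, n)
  })
}

#' Balanced case-control subsampling
#'
#' Uniformly samples `n_case` cases (Y = 1) and `n_ctrl` controls (Y = 0)
#' without replacement from a binary phenotype pool.
#'
#' @param y Binary pool phenotype vector.
#' @param n_case,n_ctrl Required class counts.
#' @param seed RNG seed.
#' @return Integer vector of selected indices (cases first).
#' @export
sample_case_control <- function(y, n_case, n_ctrl, seed = NULL) {
  if (!is_binary(y)) stop("pool phenotype must be 0/1")
  cases <- which(y == 1)
  ctrls <- which(y == 0)
  if (length(cases) < n_case || length(ctrls) < n_ctrl) {
    stop(sprintf("pool exhausted: %d cases / %d controls available, %d / %d needed",
                 length(cases), length(ctrls), n_case, n_ctrl))
  }
  with_seed_opt(seed, {
    c(sample(cases, n_case), sample(ctrls, n_ctrl))
  })
}
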