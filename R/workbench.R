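# Experiment workbench: type-I-error tables, power curves, and the per-gene
# scan. Replicate seeds are chained from one master seed in counter mode, so
# conditions are reproducible independently of execution order.

method_pvalue <- function(method, y, s, G, curves_cache, max_knots) {
  switch(method,
    iu = {
      if (is.null(curves_cache$curves)) {
        curves_cache$curves <- fit_curves(G, max_knots = max_knots)
      }
      suppressWarnings(iu_test(y, s, curves_cache$curves))$p_value
    },
    vct = vct(y, s, G)$p_value,
    adjskat = adj_skat(y, s, G)$p_value,
    stop("unknown method: ", method)
  )
}

# One simulation replicate: draw a fresh genotype segment, expression, and a
# phenotype from `gen_y(G, s, seed)`; optionally subsample a balanced
# case-control set from a larger pool (binary phenotypes). Returns the
# p-value of every requested method.
run_replicate <- function(panel, n, seed, gen_y, methods,
                          balanced = FALSE, p_seg = 100, max_knots = 35,
                          pool_factor = 3, max_attempts = 20) {
  if (!balanced) {
    G <- draw_genotypes(panel, n, p_seg, seed = derive_seed(seed, 1))
    s <- gen_expression(n, seed = derive_seed(seed, 2))
    y <- gen_y(G, s, derive_seed(seed, 3))
  } else {
    n_case <- n %/% 2
    n_ctrl <- n - n_case
    found <- FALSE
    for (att in seq_len(max_attempts)) {
      pool_n <- pool_factor * n
      Gp <- draw_genotypes(panel, pool_n, p_seg,
                           seed = derive_seed(seed, 1, att))
      sp <- gen_expression(pool_n, seed = derive_seed(seed, 2, att))
      yp <- gen_y(Gp, sp, derive_seed(seed, 3, att))
      idx <- tryCatch(
        sample_case_control(yp, n_case, n_ctrl,
                            seed = derive_seed(seed, 4, att)),
        error = function(e) NULL
      )
      if (!is.null(idx)) { found <- TRUE; break }
    }
    if (!found) stop("case-control pool exhausted after ", max_attempts,
                     " regeneration attempts")
    G <- genotype_matrix(Gp$counts[idx, , drop = FALSE], Gp$positions)
    s <- sp[idx]
    y <- yp[idx]
  }
  cache <- new.env(parent = emptyenv())
  cache$curves <- NULL
  vapply(methods, method_pvalue, numeric(1),
         y = y, s = s, G = G, curves_cache = cache, max_knots = max_knots)
}

# Replicate loop for one condition; returns reps x methods p-value matrix.
condition_pvalues <- function(panel, n, reps, cond_seed, gen_y, methods, ...) {
  P <- matrix(NA_real_, reps, length(methods),
              dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    P[r, ] <- run_replicate(panel, n, derive_seed(cond_seed, r), gen_y,
                            methods, ...)
  }
  P
}

null_gen_y <- function(dist, shift = 1) {
  force(dist); force(shift)
  function(G, s, seed) gen_null_phenotype(dist, length(s), shift, seed)
}

experiment_result <- function(df) {
  class(df) <- c("experiment_result", "data.frame")
  df
}

#' Empirical type-I-error table
#'
#' For each phenotype distribution, sample size and method: simulate null
#' replicates (fresh genotype segment, fresh expression, fresh phenotype per
#' replicate), run the test, and report the rejection fraction at each
#' nominal level with its Monte-Carlo standard error.
#'
#' @param dists Null phenotype distributions (see [gen_null_phenotype()]).
#' @param n Sample size(s).
#' @param alphas Nominal levels.
#' @param reps Replicates per condition.
#' @param methods Any of `"iu"`, `"vct"`, `"adjskat"`.
#' @param seed Master seed; every condition and replicate seed is derived
#'   from it deterministically.
#' @param balanced_binary If `TRUE`, Bernoulli conditions use balanced
#'   case-control subsampling from a 3x pool (the sample-size sweep design).
#' @param panel Optional pre-built [gen_genotype_panel()]; built from the
#'   master seed otherwise.
#' @param p_seg,max_knots Segment length and basis size for the smoother.
#' @return An `experiment_result` data frame: method, dist, n, alpha, reps,
#'   rate, mc_se, seed.
#' @export
run_type1_table <- function(dists = c("bernoulli", "gaussian", "t2", "t4",
                                      "de"),
                            n = 200, alphas = 0.05, reps = 1000,
                            methods = c("iu", "vct", "adjskat"),
                            seed = 1, balanced_binary = FALSE,
                            panel = NULL, p_seg = 100, max_knots = 35) {
  if (is.null(panel)) {
    panel <- gen_genotype_panel(seed = derive_seed(seed, 999))
  }
  out <- list()
  for (dist in dists) {
    for (nn in n) {
      cond_seed <- derive_seed(seed, match(dist, dists), nn)
      bal <- balanced_binary && dist == "bernoulli"
      P <- condition_pvalues(panel, nn, reps, cond_seed,
                             null_gen_y(dist), methods,
                             balanced = bal, p_seg = p_seg,
                             max_knots = max_knots)
      for (m in methods) {
        for (a in alphas) {
          rate <- mean(P[, m] < a)
          out[[length(out) + 1L]] <- data.frame(
            method = m, dist = dist, n = nn, alpha = a, reps = reps,
            rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
            seed = cond_seed
          )
        }
      }
    }
  }
  experiment_result(do.call(rbind, out))
}

alt_gen_y <- function(model, noise, value, sweep_param, params) {
  force(model); force(noise); force(value); force(params)
  function(G, s, seed) {
    switch(model,
      m1 = gen_model1(G, s,
        sigma_G = params$sigma_G,
        beta_S = if (sweep_param == "beta_S") value else params$beta_S,
        gamma_bound = params$gamma_bound, noise = noise, seed = seed),
      m1_random = gen_model1(G, s,
        sigma_G = params$sigma_G, beta_S = params$beta_S,
        gamma_bound = if (sweep_param == "gamma_bound") value
                      else params$gamma_bound,
        noise = noise, seed = seed),
      m2 = gen_model2(G, s,
        c_scale = if (sweep_param == "c_scale") value else params$c_scale,
        m = if (sweep_param == "m") value else params$m,
        noise = noise, seed = seed),
      m3 = gen_model3(G, s,
        d = if (sweep_param == "d") value else params$d,
        m = params$m, noise = noise, seed = seed),
      stop("unknown model: ", model)
    )
  }
}

default_alt_params <- function(model) {
  switch(model,
    m1 = list(sigma_G = 0.1, beta_S = 0, gamma_bound = 0),
    m1_random = list(sigma_G = 0, beta_S = 0, gamma_bound = 0),
    m2 = list(c_scale = 1, m = 4),
    m3 = list(m = 4, d = 0),
    stop("unknown model: ", model)
  )
}

#' Empirical power curve along one swept parameter
#'
#' Simulates the chosen alternative model at each value of the swept
#' parameter and reports the rejection fraction of each method at level
#' `alpha`. Binary phenotypes (`noise = "logit"`) use the balanced
#' case-control design (n/2 cases, n/2 controls subsampled from a pool);
#' continuous phenotypes use all `n` simulated subjects.
#'
#' @param model `"m1"` (marginal effects, sweep `beta_S`), `"m1_random"`
#'   (uniform random interaction, sweep `gamma_bound`), `"m2"`
#'   (multiplicative interaction, sweep `"m"` or `"c_scale"`), `"m3"`
#'   (threshold interaction, sweep `d`).
#' @param sweep_param Name of the swept parameter.
#' @param sweep_values Numeric grid (a zero-effect point reproduces the size).
#' @param noise `"logit"`, `"gauss"` or `"t2"`.
#' @param n Analysis sample size.
#' @param alpha Test level.
#' @param reps Replicates per grid point.
#' @param methods Any of `"iu"`, `"vct"`, `"adjskat"`.
#' @param seed Master seed.
#' @param params Overrides for the non-swept model parameters.
#' @param panel Optional pre-built genotype panel.
#' @param p_seg,max_knots Segment length and basis size.
#' @return An `experiment_result` data frame: method, model, noise,
#'   sweep_param, value, n, alpha, reps, rate, mc_se, seed.
#' @export
run_power_curve <- function(model = c("m1", "m1_random", "m2", "m3"),
                            sweep_param, sweep_values,
                            noise = c("logit", "gauss", "t2"),
                            n = 200, alpha = 0.05, reps = 500,
                            methods = c("iu", "vct", "adjskat"),
                            seed = 1, params = list(), panel = NULL,
                            p_seg = 100, max_knots = 35) {
  model <- match.arg(model)
  noise <- match.arg(noise)
  prm <- utils::modifyList(default_alt_params(model), params)
  if (is.null(panel)) {
    panel <- gen_genotype_panel(seed = derive_seed(seed, 999))
  }
  balanced <- noise == "logit"
  out <- list()
  for (k in seq_along(sweep_values)) {
    v <- sweep_values[k]
    cond_seed <- derive_seed(seed, 7000, k)
    P <- condition_pvalues(panel, n, reps, cond_seed,
                           alt_gen_y(model, noise, v, sweep_param, prm),
                           methods, balanced = balanced, p_seg = p_seg,
                           max_knots = max_knots)
    for (m in methods) {
      rate <- mean(P[, m] < alpha)
      out[[length(out) + 1L]] <- data.frame(
        method = m, model = model, noise = noise,
        sweep_param = sweep_param, value = v, n = n, alpha = alpha,
        reps = reps, rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
        seed = cond_seed
      )
    }
  }
  experiment_result(do.call(rbind, out))
}

#' Per-gene integrative scan
#'
#' Runs the requested tests on every region of a gene list: extract the
#' region's SNVs, impute missing genotypes from sample proportions, smooth,
#' and test the joint association with expression and phenotype. Regions with
#' fewer than `min_snvs` polymorphic SNVs are skipped (with a log entry).
#'
#' @param genotypes A [genotype_matrix()] (e.g. from [read_genotype_vcf()] or
#'   [read_genotype_tsv()]); subject order must match `expression` and
#'   `phenotype` after ID intersection.
#' @param expression,phenotype Named vectors (names = sample IDs) or plain
#'   vectors aligned with `genotypes`.
#' @param regions Data frame with columns `name`, `start`, `end` (1-based
#'   inclusive; use [read_bed_regions()] for BED input) and optionally
#'   `chrom`.
#' @param methods Any of `"iu"`, `"vct"`, `"adjskat"`.
#' @param alpha Level used for the Bonferroni-adjusted significance column.
#' @param min_snvs Minimum SNVs per region (default 4, the cubic-basis floor).
#' @param seed Seed for the imputation draws.
#' @return A `scan_result` data frame (one row per scanned region, sorted by
#'   the first method's p-value) with raw and Bonferroni-adjusted p-value
#'   columns; skipped regions are recorded in `attr(, "skipped")` and
#'   QQ-plot coordinates for the first method in `attr(, "qq")`.
#' @export
gene_scan <- function(genotypes, expression, phenotype, regions,
                      methods = "iu", alpha = 0.05, min_snvs = 4,
                      seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- genotypes$sample_ids
  expression <- align_samples(expression, ids, "expression")
  phenotype <- align_samples(phenotype, ids, "phenotype")
  if (!all(c("name", "start", "end") %in% names(regions))) {
    stop("regions needs columns name, start, end")
  }
  if (!nrow(regions)) stop("empty region list")
  chrom_attr <- attr(genotypes, "chrom")

  rows <- list()
  skipped <- list()
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    inside <- genotypes$positions >= rg$start & genotypes$positions <= rg$end
    if (!is.null(chrom_attr) && !is.null(rg$chrom) && !is.na(rg$chrom)) {
      inside <- inside & chrom_attr == as.character(rg$chrom)
    }
    sub <- genotypes$counts[, inside, drop = FALSE]
    poly <- apply(sub, 2, function(x) {
      xx <- x[!is.na(x)]
      length(xx) > 0 && var(xx) > 0
    })
    sub <- sub[, poly, drop = FALSE]
    if (ncol(sub) < min_snvs) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        name = rg$name,
        reason = sprintf("%d polymorphic SNVs (< %d)", ncol(sub), min_snvs)
      )
      next
    }
    Gk <- impute_missing(
      genotype_matrix(sub, genotypes$positions[inside][poly], ids),
      seed = if (is.null(seed)) NULL else derive_seed(seed, k)
    )
    curves <- NULL
    pv <- vapply(methods, function(m) {
      switch(m,
        iu = {
          if (is.null(curves)) curves <<- fit_curves(Gk)
          suppressWarnings(iu_test(phenotype, expression, curves))$p_value
        },
        vct = vct(phenotype, expression, Gk)$p_value,
        adjskat = adj_skat(phenotype, expression, Gk)$p_value,
        stop("unknown method: ", m)
      )
    }, numeric(1))
    row <- data.frame(name = rg$name,
                      chrom = if (is.null(rg$chrom)) NA else rg$chrom,
                      start = rg$start, end = rg$end, n_snvs = ncol(sub))
    for (m in methods) row[[paste0("p_", m)]] <- pv[[m]]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no region passed the SNV-count filter")
  res <- do.call(rbind, rows)
  key <- paste0("p_", methods[1])
  res <- res[order(res[[key]]), , drop = FALSE]
  rownames(res) <- NULL
  for (m in methods) {
    res[[paste0("p_", m, "_bonf")]] <-
      pmin(1, res[[paste0("p_", m)]] * nrow(res))
  }
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(name = character(),
                                          reason = character())
  obs <- sort(res[[key]])
  attr(res, "qq") <- data.frame(
    expected = -log10((seq_along(obs) - 0.5) / length(obs)),
    observed = -log10(obs)
  )
  attr(res, "alpha") <- alpha
  class(res) <- c("scan_result", "data.frame")
  res
}

align_samples <- function(x, ids, what) {
  if (!is.null(names(x))) {
    if (!all(ids %in% names(x))) {
      stop(sprintf("%s is missing values for some genotyped samples", what))
    }
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(sprintf("%s length does not match the genotype matrix", what))
  }
  stopifnot_finite(unname(x), what)
  unname(x)
}
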