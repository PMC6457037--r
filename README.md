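# iutest

Nonparametric **integrative U (IU) tests** for the joint association of a
set of single-nucleotide variants (SNVs) and a gene expression measurement
with a binary or continuous phenotype — for statistical geneticists running
gene-based integrative scans, and for methodologists benchmarking
variance-component tests under non-Gaussian phenotypes.

## The method in one paragraph

The dosage sequence of a gene region, `G_i(t_j) ∈ {0,1,2}` at positions
`t_j`, is smoothed into a functional curve `G_i(t)` on [0, 1] with penalized
natural cubic splines (shared basis, one pooled GCV-selected penalty). With
cross-product similarities for phenotype and expression, the statistic is
the pairwise-similarity average

```
U_n = 1/(n(n-1)) * Σ_{i≠j}  Y_i Y_j · S_i S_j · ∫ G_i(t) G_j(t) dt,
```

standardized as `T_n = √n (U_n − μ̂₀)/σ̂ → N(0,1)` under the null, where
`μ̂₀ = Ȳ² S̄² ‖Ḡ‖²` and `σ̂²` is a plug-in built from the functional
principal components of the genotype process (eigenvalues `λ̂_k` and
mean-curve projections `δ̂_k` of the empirical covariance operator). Because
no regression model links phenotype to genotype or expression, the test
holds its size under heavy-tailed phenotypes and detects interactions of
unspecified form. The package also provides a genetics-only variant, a
three-level extension (e.g. + methylation), a power lower bound with its
minimal-sample-size inverse, the two benchmark quadratic-form tests
(expression-adjusted SKAT and a three-component variance component test)
with Imhof mixture-of-chi-squares references, seeded simulation generators,
and a type-I-error/power workbench plus per-gene scan pipeline.

## Worked example

Simulate a 100-SNV region for 300 subjects from the synthetic haplotype
panel, add an expression effect plus weak marginal SNV effects to a Gaussian
phenotype, and test:

```r
library(iutest)

panel <- gen_genotype_panel(seed = 1)            # synthetic 1 Mb block-LD panel
G <- draw_genotypes(panel, n = 300, p = 100, seed = 2)
s <- gen_expression(300, seed = 3)               # N(1, 1.2^2)
y <- gen_model1(G, s, sigma_G = 0.1, beta_S = 0.5, noise = "gauss", seed = 4)

iu_test(y, s, G)
#> IU test (n = 300, variant = theorem)
#>   U_n = 0.0243627, mu0_hat = 0.0153509, sigma2_hat = 0.00190182
#>   T_n = 3.5792, two-sided p = 0.0003446  [reject H0 at alpha = 0.05]
```

`U_n` exceeds its null mean `μ̂₀` by 3.6 null standard errors: the joint
SNV-set + expression association is detected (two-sided p ≈ 3×10⁻⁴). The
comparators agree on these data (`adj_skat(y, s, G)` and `vct(y, s, G)`
both reject). Study design from the same pilot quantities:

```r
cur <- fit_curves(G)
res <- iu_test(y, s, cur)
sp <- power_spec(mu0 = res$mu0_hat, mu1 = res$u_n,
                 tau1 = estimate_tau1(y, s, cur),
                 sigma = sqrt(res$sigma2_hat), alpha = 0.05, beta = 0.8)
power_lower_bound(sp, n = 100)   #> 0.5206
min_sample_size(sp)              #> 321
```

At this effect size, 100 subjects give at least ~52% power and 321 subjects
suffice for 80%.

For file-based scans there is a thin CLI (`inst/cli/iu.R`) with subcommands
`test`, `power`, `scan` and `type1`, reading genotype TSV/VCF, per-sample
value TSVs and BED region lists; `gene_scan()` is the in-R equivalent.

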