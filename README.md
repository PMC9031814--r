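# divrate

Predicting intraspecific genetic diversity from long-term molecular
evolutionary rates, and detecting species-specific selection as deviations
from that prediction.

## The scientific problem

Within a species, the amount of standing genetic variation differs widely
among genes. Under near-neutral theory both a gene's long-term substitution
rate (r = νp, mutation rate times the neutral fraction) and its
intraspecific diversity (the proportion of segregating sites q = νpF, with
F a genome-wide genealogical factor) scale with the same neutral fraction
p. Among-gene variation in q should therefore be predictable from gene-tree
branch lengths accumulated over tens of millions of years — and genes whose
diversity falls short of (or exceeds) that prediction in one species are
candidates for lineage-specific enhanced (or relaxed) functional
constraint.

`divrate` implements this framework end to end for users working with
phylogenomic gene trees plus population variant data (or wanting to study
the method's behavior on simulated data):

- **Rate summaries** (`summarize_branch_lengths`): mean, median, and
  truncated mean branch length per gene tree, with the Poisson sampling
  variance `V[b̄] = b̄ / (M·l)` and a seeded Poisson branch resampler.
- **Gene and branch effects** (`estimate_gene_branch_effects`): closed-form
  maximum-likelihood decomposition of scaled branch lengths
  `E[b_ik·L_i] = c·L_i·α_i·β_k` under `Σ L_i α_i = Σ β_k = 1`, with
  per-cell interaction ratios.
- **Diversity statistics** (`tabulate_gene_variation`, `window_pi`):
  segregating sites, singletons and q per gene; nucleotide diversity π in
  1000-bp windows; feature assignment with a 100-kb intergenic rule;
  genetic-map interpolation with Haldane recombination fractions.
- **Background selection** (`fit_bgs`): window diversity modeled as
  `π = π₀ · exp Σᵢ [−U·Δx·shᵢ / (2(shᵢ + Rᵢ)²)]` with rate-dependent
  selective effects `shᵢ = exp(α + β rᵢ)` on exon windows; least-squares
  fitting per chromosome × feature and a two-way ANOVA decomposition of the
  fitted parameters.
- **Bias-corrected correlation** (`corrected_correlation`): disattenuation
  of the observed rate–diversity correlation using per-gene sampling
  variances, plus the coalescent variance formulas
  `V(K) = E(K) + E(K)²·b_n/a_n²` and the non-equilibrium
  negative-binomial form.
- **Diversity baseline** (`fit_nb_loglink`, `fit_linear_rate_model`):
  negative-binomial regression `log E[K] = log L + α + β log r + γ·DX`
  and the linear-rate alternative `E[K] = L(α + β r)·e^{γ·DX}`.
- **Species-specific selection** (`gene_deviation_pvalue`,
  `gene_set_t_test`, `bh_select`): lower-tailed mid-p per gene against the
  NB baseline, normal-quantile transform, per-set t test (negative t =
  enhanced constraint, positive t = relaxed constraint), BH selection,
  and PCA / correspondence-analysis ordination across species.
- **Synthetic data** (`generator_config`, `gen_*`): seeded generators that
  emulate each model layer, so every stage ships with a recovery oracle and
  the whole pipeline runs without external downloads (`run_pipeline`).

## Worked example

Simulate 2,000 gene trees, regress simulated segregating-site counts on
the median branch length, disattenuate the rate–diversity correlation, and
scan 40 gene sets (10 of which were generated with an enhanced-constraint
shift of δ = −0.4):

```r
library(divrate)

cfg <- generator_config(seed = 42, n_genes = 2000,
                        set_sizes = rep(15L, 40L),
                        set_deltas = c(rep(0, 30L), rep(-0.4, 10L)))
gen   <- gen_gene_trees(cfg)
rates <- summarize_gene_trees(gen$trees)
rt    <- subset(data.frame(gene_id = rates$gene_id, rate = rates$median_bl,
                           L = as.integer(gen$lengths[rates$gene_id])), rate > 0)
poly  <- gen_gene_polymorphism(cfg, rt)
poly$median_bl <- rt$rate

(fit <- fit_nb_loglink(poly))
#> <nb_fit loglink> K ~ median_bl: intercept -2.239, slope 0.3996, gamma -0.2859, theta 10.1669, n 2000

pred <- nb_predict(fit, poly$L, poly$median_bl, poly$is_X)
vs_b <- rates$sampling_var_mean[match(poly$gene_id, rates$gene_id)]
corrected_correlation(poly$median_bl, poly$q, vs_b, pred$variance / poly$L^2)
#> <corrected_cor> raw r = 0.5383, corrected r = 0.6968 (n = 2000, plugin)
```

The fitted slope (0.40) and dispersion (θ ≈ 10.2) recover the generating
values (0.413 and 10); the raw correlation 0.538 is attenuated by the
counting noise in q, and the correction lifts it toward the latent value.
The gene-set scan then ranks sets by t; the most negative t-values are the
sets simulated with a diversity deficit:

```r
sets  <- gen_gene_sets(cfg, poly)
dev   <- gene_deviation_pvalue(sets$members$K, sets$members$mu, fit$theta)
dev$set_id <- sets$members$set_id
res <- do.call(rbind, lapply(split(dev$z, dev$set_id), gene_set_t_test))
res$significant <- bh_select(res$p_value, 0.01)
#>  set_id  m   t_value      p_value significant
#>   S0035 15 -6.231067 2.195805e-05        TRUE
#>   S0036 15 -6.189688 2.354869e-05        TRUE
#>   S0038 15 -5.299532 1.122648e-04        TRUE
#>   S0040 15 -5.189361 1.372304e-04        TRUE
# 10 of 40 sets significant at FDR 0.01 — exactly the ten shifted ones
```

`run_pipeline(out_dir, config)` chains all stages (simulation → rate
summaries → effects → correlations → NB baselines → background-selection
fits → gene-set tests → PCA/CA ordination) and writes TSV artifacts plus a
`manifest.json`; reruns with the same seed are byte-identical.

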