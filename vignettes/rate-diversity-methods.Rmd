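---
title: "Models and methods: predicting diversity from long-term rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: predicting diversity from long-term rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divrate)
```

# Overview

`divrate` connects two time scales of molecular evolution. Over tens of
millions of years, a gene's substitution rate is `r = ν p`: the mutation
rate times the fraction of mutations that are selectively neutral. Within a
present-day species, the probability that a site is segregating is
`q = ν p F`, where `F` collects the genealogical history that all genes of
a genome share. Both quantities scale with the gene-specific neutral
fraction `p`, so among-gene variation in diversity should be predictable
from gene-tree branch lengths — and per-species departures from that
prediction are signals of lineage-specific selection. The integral defining
`F` over selection intensities and demography is background theory; it is
not computed anywhere in the package. What the package computes is the
chain of estimators built on this idea, each described below.

# Rate summaries from gene trees

A gene tree contributes its branch-length multiset `b_(i)k` (substitutions
per site) and alignment length `l_(i)`. Three rate proxies are exposed:

* **mean** `b̄ = Σ b_k / M` — efficient but sensitive to the occasional
  extremely long branch left by alignment error or lineage-specific
  selection;
* **median** — robust to single outliers; for even `M` the average of the
  two central order statistics;
* **truncated mean** — the mean after removing the five longest branches
  (configurable). This exists because highly conserved genes can have more
  than half their branches at zero length, which forces the median to 0 and
  breaks any log-scale regression. When `M ≤ 5` the truncated mean is
  reported as missing, never as 0.

Zero-length branches are retained throughout: pruning them would bias the
summaries of conserved genes, and the tree-reading layer deliberately keeps
every branch of the newick input (no root edge is synthesized; maximum
likelihood gene trees are effectively unrooted).

Treating the substitution count on a branch as Poisson with mean
`b_k · l` gives the sampling variance of the mean branch length,
`V[b̄] = b̄ / (M l)`, and a simple resampling scheme
(`poisson_branch_resample`): redraw counts, divide by `l`, summarize. Both
are used by the correlation correction below; the resampler also covers the
median, for which no closed form is available.

# Gene and branch effects

Scaled branch lengths follow the multiplicative model
`E[b_(i)k · L_i] = c · L_i · α_i · β_k` with the identifiability
constraints `Σ_i L_i α_i = Σ_k β_k = 1`. `α_i` is the gene effect (relative
variability, proportional to the gene's neutral fraction), `β_k` the
branch effect (time × mutation rate up to the scale `c`). For a complete
gene × branch matrix the constrained Poisson maximum-likelihood estimators
have closed forms,

```
α̂_i = Σ_k b_(i)k / Σ_j Σ_k b_(j)k L_j ,
β̂_k = Σ_i b_(i)k L_i / Σ_j Σ_k b_(j)k L_j ,
ĉ   = Σ_i Σ_k b_(i)k L_i ,
```

which the test suite verifies against direct numerical maximization of the
constrained likelihood on random matrices. The printed form of these
denominators in the literature is typographically ambiguous; the reading
implemented here is the one forced by the stated constraints, which the
estimators satisfy to 1e-10 after every fit. With missing taxa the sums
run over observed cells only — the same robustness argument that motivates
using mean branch lengths — and a strict mode can require completeness.
The interaction ratio `p̂_ik = b_(i)k L_i / (ĉ L_i α̂_i β̂_k)` captures
branch-specific shifts of a gene's constraint. `β̂_k` and `ĉ` are reported
separately rather than pre-multiplied, so users can choose either scaling
of the branch-level time × rate product.

# Diversity statistics

`q` is segregating sites over gene length, with the gene footprint defined
as the union of its annotated coding intervals — diversity of
protein-coding sequence is the target quantity. A site counts toward `K`
once per gene even when records are split across alternate alleles
(segregation is a per-site property); each alternate allele still
contributes to singleton classification, where a singleton is any allele —
alternate or reference — carried by exactly one chromosome. Overlapping
genes each count a shared site (configurable upstream by editing the
feature track).

Window diversity π sums the unbiased per-site heterozygosity
`2p̂(1−p̂)·n/(n−1)` over the variants of a 1000-bp window and divides by
the nominal window width, so that `Σ_windows π · 1000` exactly conserves
the per-site total (the chromosome-end window may be short; it is still
divided by 1000 to preserve this conservation property). Windows farther
than 100,000 bp from every gene boundary are `intergenic`; otherwise the
label is the majority feature class over the window with precedence
exon > 5′-UTR > 3′-UTR > intron on exact ties. A window near a gene but
overlapping no annotated feature has no honest label in that closed set
and is reported as missing and excluded from model fitting.

Genetic-map lookups interpolate cumulative cM linearly (linear
extrapolation beyond the map ends) and convert distance to a recombination
fraction with the Haldane map function `R = ½(1 − e^(−2d/100))`. The
literature this model comes from does not state the cM-to-fraction
conversion; Haldane is the field's default and has the required saturation
at 0.5.

# Background selection in windows

The diversity of a target window is its intrinsic level π₀ reduced by
selection on the exon windows of the chromosome:

```
π = π₀ · Π_i [ 1 − U·Δx·sh_i / (2 (sh_i + R_i)²) ]
  ≈ π₀ · exp Σ_i [ −U·Δx·sh_i / (2 (sh_i + R_i)²) ]
```

with `sh_i = exp(α + β r_i)` tying the selective effect of exon window `i`
to the long-term rate `r_i` of its gene, `R_i` the recombination fraction
to the target, and constants `U = 1e-8` per position per haploid genome and
`Δx = 1000` bp. Both the exact product and the exponential approximation
are implemented; they agree to first order whenever per-window terms are
small (verified to relative 1e-3 on generated data), and fitting uses the
exponential form, which is the form the approximation is derived for.

Fitting is nonlinear least squares per chromosome × feature stratum.
Because π₀ enters linearly, it is profiled out exactly
(`π̂₀ = Σ y g / Σ g²` for reduction profile `g(α, β)`), and the remaining
two-parameter surface is searched by Nelder–Mead from a fixed multi-start
grid (`α = log 0.01`, `β ∈ {0, ±10, ±100}`), keeping the best residual sum
of squares. This profiled search replaces a three-parameter
Levenberg–Marquardt iteration: the profiling is exact, removes the
worst-conditioned direction, and behaves well in the flat limit `U → 0`,
which the fitter detects and flags explicitly (all reduction factors within
1e-8 of 1) rather than reporting arbitrary `(α, β)`. A window spanned by
two genes takes the larger of the two rates (the conservative choice for a
selection model).

The fitted `(π₀, α, β)` grid over chromosomes × features is decomposed by
two-way ANOVA without replication (residual = interaction), giving variance
shares and the two main-effect F tests. Intergenic windows are deliberately
out of scope: this model family is known not to explain their diversity.

# Correcting the rate–diversity correlation

Observed rates and observed counts both carry sampling noise, which
attenuates their Pearson correlation across genes. The implemented
correction multiplies the raw correlation by
`sqrt[(1 + E V_S(B̂)/V_G(B̂)) (1 + E V_S(K̂)/V_G(K̂))]`, with among-gene
variances of the *observed* vectors in the denominators and sample means
of the supplied per-gene sampling variances as plug-ins. This is a mild
approximation (the latent-variance denominators `V_G(obs) − E V_S` give
classical disattenuation and are available as `mode = "exact"`), but the
plug-in form is the package default for continuity with how such
corrections are reported in this literature. The corrected value can
exceed 1 at small n; it is clamped with a warning. Sampling variances for
counts come from the coalescent formulas: at equilibrium
`V(K) = E(K) + E(K)² b_n/a_n²` (harmonic sums over the sample size), and
for an arbitrary history `V(K) = E(K) + E(K)² V(T_c)/E(T_c)²` — which is
exactly a negative-binomial variance with shape `θ = E(T_c)²/V(T_c)`, the
observation that motivates the regression family used next.

# The negative-binomial baseline

The default baseline is `log E[K] = log L + α + β log r + γ·D_X`, fitted
by `MASS::glm.nb` (jointly estimated shape, offset `log L`, X-linkage
dummy absorbing the smaller effective population size of the X). Genes
with zero rate under the chosen proxy are dropped for the log link, with a
count reported. Near-Poisson data push `θ̂` to very large values; this is
expected, harmless, and verified to reproduce a pure Poisson fit's
predictions. Both the median and truncated-mean proxies are supported;
the median is the default regression covariate, with the truncated mean
the fallback when medians degenerate to zero.

The alternative linear-rate mean `E[K] = L(α + β r) e^{γ D_X}` is fitted
by direct likelihood maximization (Nelder–Mead then BFGS, five perturbed
method-of-moments starts under a fixed seed; any parameter vector
producing a non-positive mean is rejected by barrier). Its intercept has a
specific interpretation — `α > 0` means mutations destined for loss on the
macroevolutionary scale still survive within species — so the fit reports
a 95% profile-likelihood interval for `α` alongside the estimate.

# Per-gene deviations and gene-set tests

Given a gene's predicted mean `μ` and shape `θ̂`, the deviation statistic
is the lower-tailed **mid-p** value `P(X ≤ K−1) + ½P(X = K)` mapped
through the standard-normal quantile. The mid-p convention is a deliberate
choice the package makes on its own: a plain `P(X ≤ K)` tail is
stochastically larger than uniform for discrete counts and would bias
every z upward, while mid-p restores `E[p] = 0.5` exactly (the test suite
verifies both the exact identity and near-uniformity, KS < 0.02 at 50,000
genes). p-values are clamped to `[1e-300, 1 − 1e-16]` before the quantile
transform.

A gene set's statistic is the one-sample t of its members' z values
(`m ≥ 2`), with a two-sided p from the t distribution on `m − 1` degrees
of freedom. Two-sided is again a package decision: signed t-values are the
reported effect direction (negative = enhanced constraint, positive =
relaxed), and findings in both directions are of interest, so a one-sided
test would have to be run twice anyway. Degenerate sets (zero spread) are
reported as `t = 0, p = 1` when all z are 0, or against an sd floor of
1e-12 with a warning otherwise. Significance is flagged by
Benjamini–Hochberg at FDR 0.01 by default.

Cross-species synthesis uses column-standardized PCA of the per-species
`q` matrix plus the long-term rate (standardization is the default because
`q` and rates live on different scales; component signs are fixed so each
component's dominant loading is positive), and correspondence analysis of
`−log10 p` profiles (SVD of the mass-standardized residuals; axis signs
fixed so each axis's dominant species coordinate is positive, which makes
row permutations exactly equivariant; zero p-values are floored at
1e-300).

# What the generators emulate — and what they do not

Every model layer has a seeded generator so each estimator can be tested
against known truth without any download:

* `gen_gene_trees` draws lognormal gene and branch effects, normalizes
  them to the model constraints, and draws Poisson substitution counts;
  the scale constant is set so the average branch length matches a target
  (default 0.03 substitutions/site, a typical mammalian gene-tree scale).
* `gen_gene_polymorphism` draws `K` from the negative-binomial regression
  model (defaults: intercept `log 0.113`, slope 0.413 — the fitted form of
  a singleton regression at study scale — and `θ = 10`, moderate
  overdispersion chosen so the deviation machinery has realistic noise to
  work against), singletons by binomial thinning, and de-novo counts as
  rate-independent Poisson, so the de-novo null is true by construction.
* `gen_bgs_windows` builds a 5-Mb chromosome (5,000 windows, 150 genes of
  4 consecutive exon windows, a linear 1.2 cM/Mb map — a human-typical
  recombination scale) and generates window diversity from the
  background-selection model with truth `π₀ = 1e-3, α = −3, β = 50` plus
  Gaussian noise of sd 1e-4, truncated at zero.
* `gen_gene_sets` resamples member counts with the mean multiplied by
  `e^δ` for constraint shifts `δ`.

Defaults mirror the study scale (14,671 genes, 50 branches); the test
suite runs most properties at 1/10 of that scale, and the full-scale
recovery checks (14,000-gene regression grids, 50,000-gene calibration)
are concentrated in the acceptance tests. The generators deliberately do
**not** simulate coalescent genealogies, linkage between neighboring
genes' counts, sequence evolution, or demographic history: passing tests
demonstrate that the estimators recover the models they assume, not that
those models describe any particular genome. Real-data headline numbers
(correlations around 0.6 for human data, 88-row parameter tables, specific
significant-set counts) depend on dozens of downloaded genomes and
five population variant datasets and are not reproduced here.

# Numerical choices and limitations

* Effects estimation: zero gene rows / branch columns yield zero effects
  with a warning; an all-zero matrix errors.
* `glm.nb` iteration-limit chatter on near-Poisson data is muffled; true
  non-convergence still errors with the iteration count.
* The linear-rate model's profile CI uses `uniroot` on the profiled
  likelihood-ratio statistic; an unbounded side is reported as `NA`.
* BGS fitting is deterministic given the data (fixed multi-start grid, no
  randomness); the accepted optimum never exceeds the RSS of any start.
* Ties in the "five longest branches" are broken by stable input order —
  only the count removed affects the mean.
* VCF ingestion takes AC/AN from INFO when present, otherwise derives
  counts from genotypes; indels, spanning deletions and malformed records
  are skipped with a counter. Multi-allelic records are split per
  alternate allele.
* Coordinates: VCF positions are 1-based; intervals, windows and all
  internal arithmetic are 0-based half-open.
* The pipeline (`run_pipeline`) writes a manifest without timestamps so
  that reruns under the same seed are byte-identical.

Known limitations: no phasing, imputation, ancestral-allele polarization
or per-population stratification; no confidence intervals for the
corrected correlation; the BGS model is not applied to intergenic windows;
branch identity across genes assumes a shared reference topology.
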