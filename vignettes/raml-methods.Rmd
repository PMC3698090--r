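---
title: "The rare admixture maximum likelihood test: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rare admixture maximum likelihood test: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramltest)
```

## The testing problem

Single rare variants are essentially untestable one at a time: with minor
allele frequencies (MAF) of a fraction of a percent, even large
case-control studies observe a handful of carriers per variant. Burden
tests therefore combine evidence across all rare variants in a gene or
region. The difficulty is that a realistic gene mixes deleterious,
protective and (mostly) neutral variants, so naive collapsing — counting
rare alleles per subject — loses power whenever effects are sparse or go in
both directions.

The rare admixture maximum likelihood (RAML) test treats this mixture
structure as the model. Each proxy variant $i$ contributes a signed score
statistic $z_i$; under no association $z_i \sim N(0,1)$. With probability
$\alpha$ the variant is associated, in which case its latent mean effect is
$\mu \sim N(\eta, \sigma^2)$ and marginally $z_i \sim N(\eta, 1+\sigma^2)$.
Relative to the all-null model, the log-likelihood is

$$
l(\alpha, \eta, \sigma) \;=\; \sum_i \log\!\left[(1-\alpha) +
\frac{\alpha}{\sqrt{1+\sigma^2}}
\exp\!\left(-\tfrac12\Big(\frac{(z_i-\eta)^2}{1+\sigma^2} - z_i^2\Big)\right)
\right],
$$

and the test statistic is $\Lambda = \max l$ over a bounded box. As
$\alpha \to 0$ the likelihood tends to the null value $0$, so
$\Lambda \ge 0$ always; we clamp at zero. Because no closed-form null
distribution is available for a maximum over a constrained mixture,
significance comes from phenotype permutation.

## Pipeline stages and their parameters

1. **Rare filter.** A variant is rare when $0 < \mathrm{MAF} \le 0.04$
   (boundary inclusive). MAF is computed on the combined case-control
   sample; computing it in controls only is possible upstream but
   case-enrichment of risk alleles then distorts the filter.
2. **LD proxies.** Correlated variants distort the statistic because they
   contribute nearly identical $z$ repeatedly. Variants are grouped by
   single-link clustering: edges where the squared dose correlation
   exceeds $r^2 = 0.9$ (strictly; the boundary does not link), groups are
   the connected components. Each group is replaced by one proxy whose
   dose is the subject's maximum rare-allele count over members (0, 1
   or 2). Proxies are deliberately not re-filtered on MAF: filtering
   applies to variants, clustering only de-duplicates them.
3. **Score statistics.** The per-proxy evidence is
   $z = U/\sqrt{V}$, $U = \sum_i g_i (y_i - \hat y_i)$ from the
   covariate-only null model (logistic for case-control, least squares
   for quantitative traits), with $V$ the efficient score variance
   $g'Wg - g'WX(X'WX)^{-1}X'Wg$. Projecting out the covariates keeps
   $z \sim N(0,1)$ under the null, which the mixture's null component
   assumes; the naive variance $g'Wg$ would be anti-conservative with
   informative covariates. Missing doses are mean-imputed so that $n$ is
   constant across variants; MAF is computed on observed doses only.
4. **Bounded maximisation.** The box is
   $\alpha \in (0, 0.2]$, $\eta \in [-5, 5]$, $\sigma^2 \in [0.25, 25]$.
   The first three bounds express prior plausibility: most variants are
   null, effects larger than $|z| = 5$ per variant are already detectable
   singly, and associated effects should vary by at least
   $\sigma^2 = 0.25$. The $\sigma^2$ ceiling is ours: some compact upper
   bound is needed for a box-constrained optimiser, and with
   $|\eta| \le 5$ a spread beyond $\sigma^2 = 25$ changes the likelihood
   negligibly. $\alpha$ has a numerical floor of $10^{-6}$; the null is
   the boundary limit.
5. **Permutation.** The p-value is $(1+b)/(1+B)$ with $b$ the number of
   permuted statistics $\ge \Lambda_{obs}$ — a conservative estimator that
   can never be zero. Phenotype labels are shuffled; with covariates the
   null model is refit in every permutation. Clustering and proxies depend
   only on genotypes, so they are computed once and reused; permutations
   never touch genotypes, which is what makes the precomputation unbiased.

## Optimisation

The log-likelihood is concave in $\alpha$ for fixed $(\eta, \sigma^2)$
(each term is the log of a function linear in $\alpha$), so $\alpha$ is
profiled out exactly by a safeguarded Newton search on the derivative.
The remaining two-dimensional profile surface can be multimodal in $\eta$
— a handful of large positive and negative $z$ values create separate
basins — so the bounded BOBYQA optimiser is started from a fixed
$3 \times 3$ lattice of $(\eta, \sigma)$ values
($\eta \in \{-2, 0, 2\}$, $\sigma \in \{0.5, 1, 2\}$) plus the best points
of a coarse profile-likelihood scan. Profiling dominates a start lattice
in $\alpha$: every start is searched at the exact inner optimum rather
than at three guesses of $\alpha$. All starts are deterministic, so fits
are exactly reproducible.

Permutation testing repeats this maximisation thousands of times per
region, so the permutation path runs entirely in compiled code: the same
profile objective with a coarse $(\eta, \sigma^2)$ scan and a bounded
Nelder-Mead refinement from the three best, eta-separated scan points.
The observed statistic is pushed through this same code path, so observed
and permuted $\Lambda$ are always compared like for like; the two
optimisers agree to about $10^{-8}$ on test fixtures, far below
permutation resolution. Numerical safeguards: the likelihood is evaluated
in log space (`log1p`/`expm1`) so large $|z|$ cannot overflow, and the
log-ratio is capped at 350 in the compiled fast path, far beyond any
score statistic a real data set produces.

Adaptive permutation stops early once the 99% normal-approximation
confidence interval of the running p-value lies entirely above the largest
significance level of interest (default 0.05), never before 100
permutations. The estimator is unchanged, so early stopping only truncates
clearly null runs; we verified on null simulations that adaptive and
exhaustive p-values agree in distribution.

## The disease simulator

Power evaluation needs cohorts with a known genetic architecture. The
simulator draws two haplotypes per individual (with replacement — the
population is treated as an infinite mixture of the pool's haplotypes),
computes the log-additive risk score $s = \sum_v \beta_v \, g_v$, assigns
disease with probability $\mathrm{expit}(\mu_0 + s)$, and accrues exactly
the target numbers of cases and controls. The intercept $\mu_0$ is
calibrated by root-finding so that the Monte-Carlo population prevalence
equals 0.10.

Effects follow seven scenario distributions indexed by how concentrated
and how directional they are: with per-site scale $\sigma_v$, scenarios
1-2 draw $\beta \sim N(2\sigma_v, \sigma_v^2)$, 3-4
$N(\sigma_v, \sigma_v^2)$, 5-6 $N(\sigma_v/2, \sigma_v^2)$ and 7
$N(0, \sigma_v^2)$; even-numbered scenarios flip 20% of causal variants
to the mirror-image negative-mean distribution. The scale ties effect to
frequency, $\sigma_v = -0.04 \log(p_v) / k$ with $k$ = 1, 1, 1.5, 1.5, 2,
2, 2.5 across scenarios 1-7, so rarer variants carry larger effects.
Causal variants are drawn among rare sites only — the design question the
test addresses — and are re-drawn in every power replicate, so power
averages over the scenario's effect distribution rather than conditioning
on one realisation.

Two deliberately documented ambiguities: the log in $\sigma_v$ is taken as
natural (the conventional reading in likelihood work; `log_base = "log10"`
is available), and the 0.7/0.5 down-weighting used when 10% or 20% of
variants are causal scales the whole distribution (both mean and spread),
which keeps each scenario's mean:sd ratio intact; scaling the mean alone
is available behind `scale_mean_only`.

### The synthetic haplotype pool

`gen_pool()` provides study material without any external download. Its
defaults emulate the rare-variant profile of a resequenced cancer-gene
region: 2000 haplotypes over 320 sites, site frequencies from a
$1/x$-shaped spectrum truncated to $[5 \times 10^{-4}, 0.5]$ — which puts
roughly 70% of rare sites below MAF 0.01, matching what large reference
panels show for genes such as BRCA2 — and block-wise LD from an
8-founder mosaic structure with 20-site blocks, plus occasional exact
carrier-set duplications within a block. The duplications matter: they
create the perfectly correlated variant pairs that the proxy-clustering
stage exists to absorb.

What the generator does **not** emulate: recombination gradients within
blocks, population structure and relatedness, genotyping error, and the
long-range haplotype sharing of real panels. Tests passing on synthetic
pools therefore validate the statistical machinery — calibration of type-I
error, monotonicity of power, parameter recovery — not robustness to
cohort artefacts like stratification, which callers must handle upstream
(e.g. by covariate adjustment with principal components).

## Problem sizes used in the automated checks

The checked claims run at desk scale, chosen to finish in minutes while
leaving the Monte-Carlo error small relative to each tolerance:
likelihood identities on $10^4$ random parameter tuples; optimizer
agreement with a dense grid on 50 vectors of up to 30 statistics;
parameter recovery with 100 replicates of $m = 2000$ statistics at
$(\alpha, \eta, \sigma) = (0.15, 3, 1)$; type-I error on 500 all-null
cohorts of 500 cases + 500 controls with $B = 999$ adaptive permutations;
and a 50-replicate power cell for the 2000+2000 design. The full
21-scenario, three-region, two-design sweep at 200 replicates is a
long-running recipe exposed through `run_power()` and the command-line
front end, not part of the default checks.

## Known limitations

* The test reports no analytic p-value; permutation cost is the price of
  exactness, mitigated by adaptive stopping and the compiled fast path.
* Permutation assumes exchangeability of phenotype labels given
  covariates. Strong genotype-covariate dependence (e.g. ancestry) can
  make label permutation only approximately valid; a residual-permutation
  scheme is a possible extension and is not currently implemented.
* The score test is asymptotic; with very few carriers per proxy the null
  $N(0,1)$ approximation for individual $z_i$ is rough. The permutation
  layer absorbs this for the test decision (type-I error stays nominal),
  but fitted $(\hat\alpha, \hat\eta, \hat\sigma)$ should be read as
  descriptive, not as calibrated estimates, in sparse data.
* Sex chromosomes, dosage data and survival phenotypes are out of scope.

## A worked example

```{r example, eval = FALSE}
pool <- gen_pool(seed = 42)                       # synthetic region panel
spec <- scenario_spec(1, prop_causal = 0.05,
                      n_cases = 1000, n_controls = 1000)
eff <- draw_effects(pool, spec, seed = 1)
mu0 <- calibrate_intercept(pool, eff)             # prevalence 0.10
coh <- simulate_cohort(pool, eff, mu0, spec, seed = 2)
res <- raml_test(coh$gm, coh$pc, B = 999, seed = 3)
summary(res)
```
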