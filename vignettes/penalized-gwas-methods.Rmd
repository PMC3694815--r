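---
title: "Penalized multiple regression for GWAS: models, tuning and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized multiple regression for GWAS: models, tuning and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrgwas)
```

# The model

Single-marker association tests regress the phenotype on one marker at a
time and therefore ignore the polygenic architecture of complex traits.
Penalized multiple regression (PMR) instead fits all markers jointly,

$$\hat\beta = \arg\max_\beta \; \ell(\beta) - \sum_j P(|\beta_j|;\lambda),$$

where $\ell$ is the log-likelihood of a linear (identity link, normal
error) or logistic regression over the $n \times p$ dosage matrix plus
unpenalized covariates, and $P$ is a sparsity penalty that forces most
marker coefficients to exactly zero. Joint fitting shrinks the residual
variance and exploits the fact that a marker's *conditional* association
given other trait loci is often stronger than its marginal one, which is
how weak associations invisible to single-marker scans become
detectable.

## Penalty families

All five implemented penalties share a rate parameter $\lambda$, the
slope of the penalty at the origin (per-unit-coefficient cost in
log-likelihood units); the non-convex families carry one extra shape
parameter controlling how fast the derivative tails off:

| family | $P(b)$, $b \ge 0$ | shape | behavior |
|---|---|---|---|
| lasso | $\lambda b$ | — | convex, unique optimum, over-selects |
| adaptive lasso | $\lambda w_j b$, $w_j = 1/\sqrt{|\hat\beta_j^{init}|}$ | — | convex given weights; oracle property |
| MCP | $\lambda b - b^2/2\gamma$ for $b \le \gamma\lambda$, then constant | $\gamma > 1$ | derivative reaches exactly 0 at $\gamma\lambda$ |
| LOG | $\lambda\,\log(1 + b/\eta)/\log(1 + 1/\eta)$ | $\eta > 0$ | concave, lasso as $\eta \to \infty$ |
| NEG | $-\log$ NEG marginal density, function of $b/\gamma$ | shape $a > 0$ | heavy polynomial tails, derivative $\to (2a+1)/b$ |

The LOG penalty uses the normalized parameterization (value $\lambda$ at
$b = \eta$, lasso limit for large $\eta$); the unnormalized
$\lambda\log(b + \eta)$ variant differs only by rescaling of $\lambda$
and is not separately exposed. Adaptive-lasso weights follow the
inverse-root rule; markers with a zero initial estimate stay penalizable
at the largest assigned weight rather than being excluded, so a
first-stage miss is recoverable.

The NEG penalty's derivative is $(2a+1)/\gamma$ times a ratio of
parabolic cylinder functions of $b/\gamma$. We evaluate that ratio
through the Tricomi confluent hypergeometric function
$U(q, \tfrac12, x)$: adaptive quadrature of a bounded transformed
integrand for $x \le 1$, a generalized Gauss–Laguerre rule for
$1 < x \le 10^4$, and the large-argument asymptotic beyond. Values are
tabulated on a 400-point grid per $(\lambda, a)$ pair and interpolated
inside the solver; beyond the table the derivative follows its exact
$(2a+1)/b$ asymptote, so large coefficients saturate instead of
overflowing.

# The MM coordinate-ascent solver

Coordinate $j$ is updated by maximizing the quadratic minorant

$$-\tfrac{d_j}{2}(\beta_j - z_j)^2 - P(|\beta_j|), \qquad
  z_j = \beta_j + g_j / d_j,$$

where $g_j$ is the coordinate gradient of $\ell$ and $d_j$ an upper
bound on its negative curvature: $d_j = \sum_i x_{ij}^2$ for linear
models and $\sum_i x_{ij}^2/4$ for logistic models (the Bernoulli
variance never exceeds 1/4). Because the surrogate minorizes the
objective, every accepted update is guaranteed not to decrease the
penalized objective — no step-size search or likelihood evaluation per
step is needed. The univariate maximizer is closed-form for lasso (soft
threshold), MCP (firm threshold, with candidate comparison when the
surrogate itself is non-convex, $\gamma d_j \le 1$) and LOG (roots of a
quadratic stationarity condition); NEG uses a safeguarded grid +
golden-section search over $(0, |z|]$ compared against exactly zero,
with an explicit surrogate-non-decrease guard so the MM property holds
despite the approximate inner search.

Covariates (intercept included) are updated unpenalized each sweep.
Convergence is declared when the largest coefficient change in a sweep
falls below `tol` (default $10^{-5}$), with a 500-sweep budget;
non-converged fits are flagged but returned. For speed the production
path cycles the active (nonzero) set to convergence and then screens
all coordinates with one BLAS matrix–vector gradient evaluation,
re-entering only coordinates whose thresholding update would actually
move; `debug = TRUE` instead runs plain cyclic sweeps and records the
objective after every update, which the monotonicity tests assert on.
Both paths converge to the same fixed point (tested).

Marker columns are mean-centered internally, so $\lambda$ has a
per-allele meaning and reported coefficients stay on the dosage scale.
For linear models the solver maximizes the least-squares working
objective $-\mathrm{RSS}/2$ (consistent with $d_j = \sum x_{ij}^2$);
model selection converts to the profile Gaussian log-likelihood.

# Tuning and model selection

The number of coefficients detectable at sample size $n$ scales like
$\sqrt{n/\log n}$; `model_size_bound(n)` caps every search
(13 at $n = 1000$, 25 at $n = 5000$).

*Convex path.* $\lambda_{\max}$ is the entry threshold
$\max_j |g_j|$ at the covariate-only fit (the null model is exactly
optimal there). Twenty log-spaced rates run from $\lambda_{\max}$ down
to $0.01\lambda_{\max}$, each fit warm-started from the previous, and
the path stops once the bound is reached. The adaptive lasso runs the
lasso path, converts the AIC-selected fit into weights, and traces the
weighted path.

*Non-convex grid.* All three non-convex families contain the lasso as
their convexity limit, so the 2D search starts from lasso solutions at
(up to) five equally spaced model sizes and, per starting size, chains
fits along a five-point shape schedule of increasing non-convexity
(MCP $\gamma$: 100, 30, 10, 3, 1.5; LOG $\eta$: 100 … 0.01; NEG shape:
10 … 0.1), which avoids many sub-optimal modes. The 1D variant fixes
the shape at its conventional value ($\gamma = 30$ for MCP) and
searches the rate only. Because the penalized surface is multimodal,
every grid cell is refit under 100 random coordinate-update orders
(seeded; the same order set is reused across cells, and warm starts
chain per order), and all fits are retained in a `model_path` with
models-examined / unique-model bookkeeping. The grid densities
(20 rates, 5 shapes, 5 sizes) are this package's choices; all are
arguments.

Selection minimizes AIC, $-2\ell + 2(k + \#\text{covariates})$, over
fits respecting the size bound, with ties going to the smaller model
and then to the earlier fit; AIC alone selects implausibly many markers
at finite $n$, which is what the bound prevents. BIC and
cross-validation are deliberately not the default. As an alternative
rate-tuning baseline, `perm_mcp_rate()` implements permutation tuning:
the MCP ($\gamma = 30$) entry path is traced on permuted phenotypes and
the rate interpolated so the mean selected count equals
$\mathrm{eFPR} \times p_{\mathrm{screened}}$ (defaults
$\mathrm{eFPR} = 10^{-3}$ with a 0.001 pre-screen, the combination that
performs best for this approach).

## Pre-screening

Markers with single-marker p-values above 0.01 (default) are dropped
before joint fitting. Marginal screening retains relevant variables
with probability tending to one, approximates the exact screening rules
available for the lasso, and cuts memory and time by roughly two orders
of magnitude; empirically it has almost no effect on the selected
models.

# Post-hoc scoring and diagnostics

The selected model is refit unpenalized, and each selected marker is
tested by a drop-one likelihood-ratio test ($\chi^2_1$). Markers in the
same LD block inflate each other's coefficient variance, so the report
loop repeatedly finds the pair with the largest absolute dosage
correlation (Pearson, on imputed dosages), drops the member with the
smaller absolute refit coefficient (ties drop the higher marker index),
and re-tests, until all pairwise correlations are at or below 0.1.
Every marker — dropped ones included — keeps the *smallest* p-value it
received in any iteration. These scores rank markers by confidence but
are not strict asymptotic p-values. Pairs that are numerically
collinear in-sample (correlation above 0.9999) cannot be refit jointly
at all; they are resolved before the first refit by the same tie rule,
and the dropped twin inherits its surviving duplicate's score.
Reporting thresholds default to $10^{-7}$ for 2D-MCP reports and
$10^{-5}$ otherwise; the full ranked list is always emitted.

Overfitting is assessed by the residual-QQ diagnostic: refit the
selected markers unpenalized, take residuals (response scale for
linear, deviance residuals for logistic), regress every non-selected
marker on them, and compute the genomic inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_1)/0.4549$ of the resulting
p-values. Values near 1 with only slight tail inflation indicate an
honest fit; marked deflation is the signature of a model that has
absorbed noise. The same $\lambda_{GC}$ on the initial single-marker
scan should be checked (with covariates and principal components, which
this package accepts but does not compute) before any PMR analysis.

The two-stage conditional scan is also provided: stage-1 hits at
p $\le 10^{-5}$ (the cutoff is configurable; the conventional
suggestive-association level is the default) are pruned to the
strongest marker per 100 kb, added as covariates, and all other markers
re-tested, reporting each marker's better of the two p-values.

# The simulator

Genotypes come from a pool of 200 haplotypes laid out in LD blocks of
5–50 markers (5 kb spacing, 1 cM/Mb). Within a block, allele $j{+}1$ on
a haplotype copies allele $j$ with a per-pair probability and is
otherwise drawn fresh at its marker frequency (frequencies 0.05–0.5);
individuals are formed by drawing two haplotypes per block
independently across blocks, so LD decays within blocks and vanishes
between them. Half of the adjacent pairs (configurable) are
near-duplicates (copying probability 0.95–0.999) and the rest decay at
0.65–0.95, mixing tight LD clumps with ordinary block-level decay the
way recombination hotspots partition real haplotypes. This mixture was
chosen so that a causal variant has an $r^2 \ge 0.8$ proxy for roughly
80–90% of loci, matching the coverage for which common genotyping
arrays were designed: with a uniformly decaying chain most causal loci
have no adequate proxy, and every downstream figure of merit measures
panel coverage instead of method performance. Block-independent
haplotype draws matter for the same reason: drawing whole-genome
haplotypes from a small pool induces genome-wide case–control structure
and $\lambda_{GC} \approx 4$.

Phenotypes follow the additive liability-threshold model: $m$ causal
markers are drawn uniformly among markers with MAF $\ge 0.05$, effects
$\beta_c \sim N(0,1)$ independent of frequency (so most *marginal*
heritabilities, $2f_c(1-f_c)\beta_c^2/\mathrm{Var}(L)$, are very
small), environmental noise has variance
$\mathrm{Var}(g)(1-h^2)/h^2$, and the case threshold is the $(1-K)$
liability quantile estimated from an independent 20,000-draw
calibration sample, so the realized population prevalence matches $K$
out of sample (the default $K = 0.5$). Individuals are drawn until the
case and control quotas are met, and the causal columns are removed
from the emitted dataset, so methods must find loci through LD proxies.
Full determinism under `seed` covers the pool, effects and
ascertainment.

What the simulator does **not** emulate: population structure and
relatedness, ascertainment toward special sampling designs, rare
variants, genotyping error, and interaction effects. Passing tests on
these data show the machinery is correct and that the power ordering
holds under clean polygenic architecture; they do not certify behavior
under confounding.

# Evaluation

A reported marker is a true positive if its squared correlation with
any hidden causal dosage reaches 0.8 (configurable; 0.5 is the usual
sensitivity setting). The TP count is the number of *distinct* causal
loci tagged. False positives are greedily clustered — most significant
first, absorbing false positives within ±50 kb — and counted as
clusters. Power at FDR $q$ walks the ranked list and takes the largest
recall among prefixes with
$\mathrm{FP}_{\mathrm{clusters}}/(\mathrm{FP}_{\mathrm{clusters}} +
\mathrm{TP}) \le q$; the incremental clustering reproduces the greedy
definition exactly. Note the criterion's hard edge: with $m = 10$ loci
a single false cluster already forces FDR $\ge 1/11$, so power at 5%
FDR counts only loci ranked ahead of every false cluster — and a causal
locus whose best existing proxy falls below the $r^2$ threshold is
scored against the method even though the method reported the best
marker available.

# Problem sizes used by the test suite

Unit tests run on small synthetic instances (hundreds of individuals,
up to a few thousand markers). The headline property is checked at 20
replicates of the reference condition — 1000 cases/1000 controls,
20,000 markers, 10 causal loci, $h^2 = 0.5$, prevalence 50%,
pre-screen 0.01, 100 reorderings — comparing mean power at 5% FDR of
the 2D-MCP pipeline against the single-marker scan, with the report
FDR at the default threshold tracked alongside. Oracle-equivalence
checks compare the solver against a derivative-free optimizer at
$n = 200$, $p \le 10$, where such an optimizer is reliable.

# Known limitations

* Scores from the pruning loop are heuristic ranks, not calibrated
  p-values; downstream FDR procedures should not be applied to them
  blindly.
* The NEG update relies on tabulated derivatives; rates far outside the
  tabulated coefficient range (|b| > 150) use the asymptotic tail.
* Linear-model fitting uses the unit-variance working likelihood
  internally; rates are therefore not comparable across phenotype
  scalings (standardize the phenotype if comparability matters).
* The simulator's haplotype pool is small (200) by design for speed;
  allele-frequency granularity is 1/400.
* Only additive coding is implemented; dominance and interactions are
  out of scope.
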