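# pmrgwas

Penalized multiple regression (PMR) for genome-wide association
studies. Instead of testing markers one at a time, `pmrgwas` fits all
markers jointly in a sparse penalized generalized linear model

```
max over beta:  l(beta) - sum_j P(|beta_j|; lambda)
```

where `l` is the linear or logistic log-likelihood (with unpenalized
covariates) and `P` is one of five sparsity penalties — Lasso, Adaptive
Lasso, LOG, NEG, MCP — whose rate parameter `lambda` sets the slope at
the origin and, for the non-convex families, a shape parameter controls
how fast the derivative tails off. Joint modeling of the polygenic
signal shrinks the residual variance and exploits conditional
associations, which is how tag markers too weak for a single-marker
scan become detectable at a controlled false discovery rate.

The package provides:

* a minorize-maximization (MM) coordinate-ascent solver with
  closed-form or safeguarded univariate updates and a monotone-ascent
  guarantee (curvature bounds `sum x^2` / `sum x^2 / 4`);
* data-adaptive tuning: regularization paths for the convex penalties,
  a rate-by-shape grid for the non-convex ones started from lasso
  solutions, 100 random coordinate-update reorderings per grid cell to
  explore multiple modes, and AIC model selection capped at the
  `sqrt(n / log n)` model-size bound;
* post-hoc scoring: unpenalized refit, drop-one likelihood-ratio
  tests, iterative correlation pruning to a 0.1 bound with minimum-p
  score accumulation, and a residual-QQ overfitting diagnostic;
* single-marker and two-stage conditional scans, pre-screening,
  genomic-control diagnostics, permutation-based MCP tuning
  (`perm_mcp_rate`);
* PLINK transposed-text (TPED/TFAM) input/output with mean imputation
  of sporadic missing calls;
* a case/control simulator (LD-blocked haplotype pool, additive
  liability-threshold phenotypes, hidden causal variants) and
  LD-tagging evaluation (power at fixed FDR, precision–recall).

## Worked example

Simulate a 1,000-individual case/control study with 6 hidden causal
loci, run the recommended 2D-MCP pipeline, and evaluate against truth:

```r
library(pmrgwas)

cfg <- sim_config(n_cases = 500, n_controls = 500, p = 5000, m = 6,
                  h2 = 0.5, seed = 42)
sim <- simulate_gwas(cfg)

scan <- single_marker_scan(sim$genotypes, sim$phenotype)
genomic_inflation(scan)
#> 1.085

run <- run_pipeline(sim$genotypes, sim$phenotype, penalty = "mcp",
                    mode = "2D", seed = 1)
#> pre-screen: retained 101 / 4994 markers (2.02%)
run
#> pmr_run (mcp 2D): lambda_gc 1.085, 101 screened, 11 selected,
#>   3 significant at 1.0e-07
#> 2507 models examined (14 unique); diagnostic lambda 1.070

head(run$report, 3)
#>         id chrom       bp coefficient        score iteration retained
#> 1 snp03399     1 16995000    1.641001 8.998243e-40         3     TRUE
#> 2 snp00056     1   280000    1.718144 9.595037e-31         0     TRUE
#> 3 snp00378     1  1890000   -1.099796 1.914065e-20         2     TRUE

power_at_fdr(run$report[, c("id", "score")], sim$truth, sim$genotypes)$power
#> 0.333
power_at_fdr(data.frame(id = scan$id, score = scan$p), sim$truth,
             sim$genotypes, max_rank = 1000)$power
#> 0.167
```

Reading the output: the scan's genomic inflation (1.09) says the
single-marker test is calibrated, so penalized fitting is safe to
apply. The pipeline screened 4,994 markers down to 101, examined 2,507
penalized fits (14 distinct marker sets) over the rate-by-shape grid
with reorderings, selected an 11-marker model by bounded AIC, and
assigned post-hoc scores; 3 markers clear the 1e-7 reporting threshold,
the diagnostic inflation of 1.07 shows the selected model has not
overfit, and the `score` column ranks markers by confidence (drop-one
LRT p-values after correlation pruning — heuristic ranks, not
calibrated p-values). At a 5% FDR the joint model recovers twice the
causal loci the single-marker scan does (2/6 vs 1/6 here).

A thin command-line front end with the same verbs
(`simulate`, `scan`, `conditional`, `pmr`, `evaluate`) is installed as
`exec/pmrgwas`.

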