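small_cfg <- function(...) {
  do.call(sim_config, modifyList(
    list(n_cases = 150, n_controls = 150, p = 600, m = 5, h2 = 0.5,
         block_len = c(5, 15)), list(...)))
}

test_that("the simulator is fully deterministic under a seed", {
  s1 <- simulate_gwas(small_cfg(seed = 61))
  s2 <- simulate_gwas(small_cfg(seed = 61))
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(as.numeric(s1$phenotype), as.numeric(s2$phenotype))
  expect_identical(s1$truth$causal, s2$truth$causal)
  # byte-identical transposed-text output
  f1 <- write_tped_fixture(s1$genotypes, s1$phenotype)
  f2 <- write_tped_fixture(s2$genotypes, s2$phenotype)
  expect_identical(readLines(f1$tped), readLines(f2$tped))
})

test_that("LD lives within blocks and dies between them", {
  cfg <- small_cfg(seed = 62)
  g <- generate_genotypes(cfg, n = 3000)
  pool <- attr(g, "pool")
  blk <- pool$block
  r <- cor(g$dosages)
  adj <- abs(r[cbind(1:(ncol(r) - 1), 2:ncol(r))])
  same_block <- blk[-length(blk)] == blk[-1]
  expect_gt(mean(adj[same_block]^2), 0.3)
  # between-block adjacent pairs are uncorrelated
  expect_lt(mean(adj[!same_block]^2), 0.02)
})

test_that("marker frequencies respect the configured bounds", {
  cfg <- small_cfg(seed = 63)
  g <- generate_genotypes(cfg, n = 5000)
  maf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  expect_gte(min(maf), 0.04)
  expect_lte(max(maf), 0.5)
})

test_that("effect assignment respects the MAF floor and the variance decomposition", {
  cfg <- small_cfg(seed = 64)
  g <- generate_genotypes(cfg, n = 500)
  truth <- assign_effects(g, cfg)
  expect_true(all(truth$causal$maf >= cfg$maf_floor))
  expect_equal(nrow(truth$causal), cfg$m)
  # marginal heritabilities of unlinked loci sum to ~ h2
  expect_lt(abs(sum(truth$causal$marginal_h2) - cfg$h2) / cfg$h2, 0.25)
  # empirical genetic share of liability variance matches h2
  big <- generate_genotypes(cfg, n = 10000, pool = attr(g, "pool"))
  gen <- drop(big$dosages[, truth$causal$index] %*% truth$causal$beta)
  liab <- draw_liabilities(big$dosages, truth)
  expect_lt(abs(var(gen) / var(liab$liability) - cfg$h2), 0.02)
})

test_that("zero effects give zero marginal heritability and null phenotypes", {
  cfg <- small_cfg(seed = 65, h2 = 0)
  sim <- simulate_gwas(cfg)
  expect_true(all(sim$truth$causal$beta == 0))
  expect_true(all(sim$truth$causal$marginal_h2 == 0))
  scan <- single_marker_scan(sim$genotypes, sim$phenotype)
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("causal markers are hidden from the emitted dataset but kept in truth", {
  sim <- simulate_gwas(small_cfg(seed = 66))
  expect_length(intersect(sim$truth$causal$id, sim$genotypes$map$id), 0)
  expect_equal(ncol(sim$genotypes$dosages), 600 - 5)
  expect_equal(colnames(sim$truth$causal_dosages), sim$truth$causal$id)
  expect_equal(nrow(sim$truth$causal_dosages), 300)
})

test_that("ascertainment hits the requested case/control counts", {
  cfg <- small_cfg(seed = 67, prevalence = 0.3)
  sim <- simulate_gwas(cfg)
  expect_equal(sum(sim$phenotype == 1), 150)
  expect_equal(sum(sim$phenotype == 0), 150)
})

test_that("population prevalence tracks the configured K out of sample", {
  cfg <- small_cfg(seed = 68, prevalence = 0.3)
  g <- generate_genotypes(cfg, n = 2)
  truth <- assign_effects(g, cfg)
  fresh <- generate_genotypes(cfg, n = 8000, pool = attr(g, "pool"))
  liab <- draw_liabilities(fresh$dosages, truth)
  expect_lt(abs(mean(liab$case) - 0.3), 3 * sqrt(0.3 * 0.7 / 8000))
})

test_that("the strongest causal locus dominates the scan", {
  pw <- replicate(3, {
    cfg <- sim_config(n_cases = 400, n_controls = 400, p = 1500, m = 4,
                      h2 = 0.6, block_len = c(5, 15),
                      seed = sample.int(1e6, 1))
    sim <- simulate_gwas(cfg)
    scan <- single_marker_scan(sim$genotypes, sim$phenotype)
    top_locus <- sim$truth$causal$id[which.max(sim$truth$causal$marginal_h2)]
    r2 <- cor(sim$genotypes$dosages,
              sim$truth$causal_dosages[, top_locus])^2
    best_tag <- which.max(r2)
    rank_of_tag <- rank(scan$p)[best_tag]
    rank_of_tag <= 20
  })
  expect_gte(sum(pw), 2)
})

test_that("truth sidecar is written as readable text", {
  sim <- simulate_gwas(small_cfg(seed = 69))
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 5)
  expect_true(all(c("id", "beta", "marginal_h2") %in% names(tab)))
})
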