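#' Simulation configuration
#'
#' Describes a case/control GWAS simulation: LD-blocked genotypes drawn
#' from a haplotype pool and an additive liability-threshold phenotype.
#' Haplotypes follow a first-order Markov copying model within LD blocks
#' (blocks are mutually independent), which reproduces the tagging
#' structure the evaluation relies on. Causal markers are drawn uniformly
#' among markers with minor allele frequency at least `maf_floor`, with
#' effects from a standard normal independent of allele frequency, and
#' are removed from the emitted analysis dataset so associations must be
#' found through linkage disequilibrium.
#'
#' @param n_cases,n_controls ascertained sample sizes (default 1000 each).
#' @param p total marker count before causal removal.
#' @param m number of causal markers.
#' @param h2 total liability heritability in (0,1); 0 gives a null
#'   phenotype.
#' @param prevalence population disease prevalence K (default 0.5).
#' @param maf_floor minimum causal minor allele frequency (default 0.05).
#' @param block_len range of LD block lengths in markers (default 5-50).
#' @param copy_prob range of the within-block adjacent-allele copying
#'   probability for ordinary marker pairs (default 0.65-0.95, giving
#'   adjacent r2 of roughly 0.4-0.9).
#' @param tight_pair_frac fraction of adjacent pairs that are
#'   near-duplicates (`tight_copy_prob` applies; default 0.5). Real
#'   haplotype blocks mix near-identical markers between recombination
#'   hotspots with weaker block-level decay; this mixture gives a
#'   genotyping-array-like ~80% chance that a causal variant has a proxy
#'   at r2 >= 0.8.
#' @param tight_copy_prob copying-probability range for near-duplicate
#'   pairs (default 0.95-0.999).
#' @param n_haplotypes size of the haplotype pool (default 200).
#' @param marker_spacing_bp distance between adjacent markers (default
#'   5000 bp); the genetic map is a constant 1 cM per Mb.
#' @param seed RNG seed for full determinism.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 1000, n_controls = 1000, p = 20000, m = 10,
                       h2 = 0.5, prevalence = 0.5, maf_floor = 0.05,
                       block_len = c(5, 50), copy_prob = c(0.65, 0.95),
                       tight_pair_frac = 0.5, tight_copy_prob = c(0.95, 0.999),
                       n_haplotypes = 200, marker_spacing_bp = 5000,
                       seed = NULL) {
  stopifnot(m < p, h2 >= 0, h2 < 1, prevalence > 0, prevalence < 1,
            n_cases >= 1, n_controls >= 1, maf_floor >= 0, maf_floor < 0.5,
            tight_pair_frac >= 0, tight_pair_frac <= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls, p = p, m = m,
                 h2 = h2, prevalence = prevalence, maf_floor = maf_floor,
                 block_len = block_len, copy_prob = copy_prob,
                 tight_pair_frac = tight_pair_frac,
                 tight_copy_prob = tight_copy_prob,
                 n_haplotypes = n_haplotypes,
                 marker_spacing_bp = marker_spacing_bp, seed = seed),
            class = "sim_config")
}

# haplotype pool over LD blocks; allele frequencies kept inside [0.05, 0.5]
make_pool <- function(cfg) {
  p <- cfg$p
  lens <- integer(0)
  while (sum(lens) < p) {
    lens <- c(lens, sample(cfg$block_len[1]:cfg$block_len[2], 1))
  }
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - p)
  lens <- lens[lens > 0]
  block <- rep(seq_along(lens), lens)

  H <- cfg$n_haplotypes
  pool <- matrix(0L, H, p)
  freqs <- numeric(p)
  pos <- 1L
  for (b in seq_along(lens)) {
    L <- lens[b]
    base <- runif(1, 0.10, 0.45)
    f <- pmin(pmax(base + runif(L, -0.05, 0.05), 0.05), 0.5)
    cols <- pos:(pos + L - 1L)
    pool[, cols[1]] <- rbinom(H, 1, f[1])
    for (j in seq_len(L - 1L)) {
      # per-pair copying probability: a fraction of pairs are
      # near-duplicates, the rest decay at the ordinary block rate
      rho <- if (runif(1) < cfg$tight_pair_frac) {
        runif(1, cfg$tight_copy_prob[1], cfg$tight_copy_prob[2])
      } else {
        runif(1, cfg$copy_prob[1], cfg$copy_prob[2])
      }
      copy <- runif(H) < rho
      fresh <- rbinom(H, 1, f[j + 1])
      pool[, cols[j + 1]] <- ifelse(copy, pool[, cols[j]], fresh)
    }
    freqs[cols] <- f
    pos <- pos + L
  }
  map <- data.frame(chrom = "1", id = sprintf("snp%05d", seq_len(p)),
                    cM = seq_len(p) * cfg$marker_spacing_bp / 1e6,
                    bp = seq_len(p) * cfg$marker_spacing_bp,
                    stringsAsFactors = FALSE)
  list(pool = pool, map = map, block = block,
       block_cols = split(seq_len(p), block))
}

# haplotype pairs are drawn independently per LD block ("free recombination"
# between blocks), so only within-block allelic correlation survives
draw_block_pairs <- function(H, n, n_blocks) {
  list(h1 = matrix(sample.int(H, n * n_blocks, replace = TRUE), n, n_blocks),
       h2 = matrix(sample.int(H, n * n_blocks, replace = TRUE), n, n_blocks))
}

# materialize dosages for the requested blocks given per-block pair indices
assemble_dosages <- function(pool, pairs, blocks = NULL) {
  n <- nrow(pairs$h1)
  if (is.null(blocks)) blocks <- seq_along(pool$block_cols)
  dos <- matrix(0L, n, length(unlist(pool$block_cols[blocks])))
  at <- 1L
  for (b in blocks) {
    cols <- pool$block_cols[[b]]
    idx <- at:(at + length(cols) - 1L)
    dos[, idx] <- pool$pool[pairs$h1[, b], cols, drop = FALSE] +
                  pool$pool[pairs$h2[, b], cols, drop = FALSE]
    at <- at + length(cols)
  }
  dos
}

draw_dosages <- function(pool, n, cols = NULL) {
  H <- nrow(pool$pool)
  nb <- length(pool$block_cols)
  if (is.null(cols)) {
    pairs <- draw_block_pairs(H, n, nb)
    return(assemble_dosages(pool, pairs))
  }
  # materialize only the blocks covering the requested columns
  blocks <- unique(pool$block[cols])
  pairs <- draw_block_pairs(H, n, nb)
  dos <- assemble_dosages(pool, pairs, blocks)
  dos[, match(cols, unlist(pool$block_cols[blocks])), drop = FALSE]
}

#' Generate LD-blocked genotypes
#'
#' Builds the haplotype pool for `cfg` (if not supplied) and draws `n`
#' individuals as unordered pairs of pool haplotypes. The returned dataset
#' contains all `p` markers, causal candidates included; the pool is
#' attached so further individuals can be drawn consistently.
#'
#' @param cfg a [sim_config()].
#' @param n number of individuals (default `n_cases + n_controls`).
#' @param pool internal haplotype pool to reuse.
#' @return A [genotype_dataset()] with attribute `pool`.
#' @export
generate_genotypes <- function(cfg, n = cfg$n_cases + cfg$n_controls,
                               pool = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(pool)) pool <- make_pool(cfg)
  dos <- draw_dosages(pool, n)
  g <- genotype_dataset(dos, pool$map)
  attr(g, "pool") <- pool
  g
}

#' Assign causal effects and liability variance components
#'
#' Samples `m` causal markers uniformly among markers whose pool allele
#' frequency is at least `maf_floor`, draws their liability effects from
#' a standard normal (independent of frequency), and calibrates the
#' liability scale: environmental variance is set to
#' `Var(genetic) * (1 - h2) / h2` so the genetic share of liability
#' variance equals `h2`, and the case threshold is the `(1 - K)` quantile
#' of the liability distribution, estimated from an independent
#' Monte-Carlo calibration draw. Per-locus marginal heritabilities are
#' `2 f (1 - f) beta^2 / Var(liability)`.
#'
#' @param g a [genotype_dataset()] from [generate_genotypes()] (pool
#'   attached).
#' @param cfg a [sim_config()].
#' @param n_calibration size of the threshold-calibration draw.
#' @return A `sim_truth` list: `causal` (data.frame id, index, beta, maf,
#'   marginal_h2), `threshold`, `var_genetic`, `var_env`,
#'   `var_liability`, and the haplotype pool.
#' @export
assign_effects <- function(g, cfg, n_calibration = 20000) {
  pool <- attr(g, "pool")
  if (is.null(pool)) stop("genotypes must come from generate_genotypes()")
  freq <- colMeans(pool$pool)
  maf <- pmin(freq, 1 - freq)
  eligible <- which(maf >= cfg$maf_floor)
  if (length(eligible) < cfg$m) {
    stop("fewer than m markers pass the causal MAF floor")
  }
  causal_idx <- sort(sample(eligible, cfg$m))
  beta <- rnorm(cfg$m)

  if (cfg$h2 > 0) {
    cal <- draw_dosages(pool, n_calibration, cols = causal_idx)
    gen_cal <- drop(cal %*% beta)
    var_g <- var(gen_cal)
    var_e <- var_g * (1 - cfg$h2) / cfg$h2
    liab_cal <- gen_cal + rnorm(n_calibration, 0, sqrt(var_e))
    threshold <- quantile(liab_cal, 1 - cfg$prevalence, names = FALSE, type = 8)
    var_l <- var(liab_cal)
  } else {
    beta <- rep(0, cfg$m)
    var_g <- 0; var_e <- 1; var_l <- 1
    threshold <- qnorm(1 - cfg$prevalence)
  }
  f <- freq[causal_idx]
  marginal_h2 <- if (var_l > 0) 2 * f * (1 - f) * beta^2 / var_l else rep(0, cfg$m)
  structure(list(causal = data.frame(id = pool$map$id[causal_idx],
                                     index = causal_idx, beta = beta,
                                     maf = maf[causal_idx],
                                     marginal_h2 = marginal_h2,
                                     bp = pool$map$bp[causal_idx],
                                     chrom = pool$map$chrom[causal_idx],
                                     stringsAsFactors = FALSE),
                 threshold = threshold, var_genetic = var_g, var_env = var_e,
                 var_liability = var_l, pool = pool, cfg = cfg),
            class = "sim_truth")
}

#' Liabilities and case status for a genotype draw
#'
#' @param dosages dosage matrix restricted to the causal markers (columns
#'   in `truth$causal` order), or a full-dataset matrix.
#' @param truth a `sim_truth`.
#' @return data.frame with `liability` and logical `case`.
#' @export
draw_liabilities <- function(dosages, truth) {
  m <- nrow(truth$causal)
  if (ncol(dosages) != m) dosages <- dosages[, truth$causal$index, drop = FALSE]
  gen <- drop(dosages %*% truth$causal$beta)
  liab <- gen + rnorm(nrow(dosages), 0, sqrt(truth$var_env))
  data.frame(liability = liab, case = liab > truth$threshold)
}

#' Simulate an ascertained case/control phenotype
#'
#' Draws individuals from the haplotype pool until `n_cases` cases and
#' `n_controls` controls are collected under the liability-threshold
#' model, then emits the analysis dataset with the causal columns
#' removed. The causal dosages of the ascertained individuals are kept in
#' the truth object for LD-based evaluation.
#'
#' @param truth a `sim_truth` from [assign_effects()].
#' @param cfg a [sim_config()].
#' @param max_batches draw-budget guard (error when exceeded).
#' @return List: `genotypes` (analysis [genotype_dataset()], causal
#'   markers removed), `phenotype` ([phenotype_vector()], 1 = case),
#'   `truth` (with `causal_dosages` filled in).
#' @export
simulate_phenotypes <- function(truth, cfg, max_batches = 60) {
  pool <- truth$pool
  need_ca <- cfg$n_cases; need_co <- cfg$n_controls
  H <- nrow(pool$pool)
  nb <- length(pool$block_cols)
  causal_cols <- truth$causal$index
  causal_blocks <- unique(pool$block[causal_cols])
  # which position each causal column occupies inside the causal-block slice
  causal_slice_pos <- match(causal_cols, unlist(pool$block_cols[causal_blocks]))
  # ascertain on the causal blocks only; the remaining (independent) blocks
  # are drawn once for the kept individuals
  kept_ca <- kept_co <- NULL
  batch <- ceiling(1.3 * (need_ca + need_co))
  for (b in seq_len(max_batches)) {
    pr <- draw_block_pairs(H, batch, nb)
    cd <- assemble_dosages(pool, pr, causal_blocks)[, causal_slice_pos,
                                                    drop = FALSE]
    liab <- draw_liabilities(cd, truth)
    ca <- head(which(liab$case), need_ca - nrow0(kept_ca))
    co <- head(which(!liab$case), need_co - nrow0(kept_co))
    take <- function(i) cbind(pr$h1[i, causal_blocks, drop = FALSE],
                              pr$h2[i, causal_blocks, drop = FALSE])
    kept_ca <- rbind(kept_ca, take(ca))
    kept_co <- rbind(kept_co, take(co))
    if (nrow0(kept_ca) >= need_ca && nrow0(kept_co) >= need_co) break
    if (b == max_batches) {
      stop("case/control collection exceeded the draw budget; ",
           "prevalence too extreme for the requested sample size")
    }
  }
  kp <- rbind(kept_ca, kept_co)
  yv <- c(rep(1, need_ca), rep(0, need_co))
  ord <- sample.int(nrow(kp))  # interleave cases and controls
  kp <- kp[ord, , drop = FALSE]
  yv <- yv[ord]
  n_out <- nrow(kp)
  ncb <- length(causal_blocks)
  pairs <- draw_block_pairs(H, n_out, nb)
  pairs$h1[, causal_blocks] <- kp[, seq_len(ncb), drop = FALSE]
  pairs$h2[, causal_blocks] <- kp[, ncb + seq_len(ncb), drop = FALSE]
  dos <- matrix(0L, n_out, cfg$p)
  for (b in seq_len(nb)) {
    cols <- pool$block_cols[[b]]
    dos[, cols] <- pool$pool[pairs$h1[, b], cols, drop = FALSE] +
                   pool$pool[pairs$h2[, b], cols, drop = FALSE]
  }

  causal_idx <- truth$causal$index
  truth$causal_dosages <- dos[, causal_idx, drop = FALSE]
  colnames(truth$causal_dosages) <- truth$causal$id
  keep <- setdiff(seq_len(ncol(dos)), causal_idx)
  g <- genotype_dataset(dos[, keep, drop = FALSE],
                        pool$map[keep, , drop = FALSE])
  truth$pool <- NULL  # drop the pool from the emitted truth (bulky)
  list(genotypes = g, phenotype = phenotype_vector(yv, "logistic"),
       truth = truth)
}

nrow0 <- function(x) if (is.null(x)) 0L else nrow(x)

#' Empirical population prevalence of the simulated disease
#'
#' Draws `n` fresh individuals from the haplotype pool (causal markers
#' only), assigns liabilities, and returns the case fraction before any
#' case/control ascertainment. With the threshold calibrated at the
#' `(1 - K)` liability quantile this estimates the configured prevalence
#' `K` up to Monte-Carlo error.
#'
#' @param truth a `sim_truth` from [assign_effects()] (pool still
#'   attached).
#' @param n number of individuals to draw (default 10000).
#' @return Scalar case fraction.
#' @export
population_prevalence <- function(truth, n = 10000) {
  if (is.null(truth$pool)) stop("truth no longer carries the haplotype pool")
  cd <- draw_dosages(truth$pool, n, cols = truth$causal$index)
  mean(draw_liabilities(cd, truth)$case)
}

#' One-call GWAS simulation
#'
#' Convenience wrapper: [generate_genotypes()], [assign_effects()],
#' [simulate_phenotypes()] under the config's seed.
#'
#' @param cfg a [sim_config()].
#' @return As [simulate_phenotypes()].
#' @export
simulate_gwas <- function(cfg) {
  g <- generate_genotypes(cfg, n = 2)  # pool construction; individuals unused
  truth <- assign_effects(g, cfg)
  simulate_phenotypes(truth, cfg)
}

#' Write / read the simulation truth sidecar
#'
#' The sidecar is tab-separated text: the causal-marker table, and
#' (optionally) the causal dosages of the analyzed individuals, which
#' LD-based evaluation needs.
#'
#' @param truth a `sim_truth`.
#' @param path output path for the causal table.
#' @param dosages_path optional output path for the causal dosage matrix.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path, dosages_path = NULL) {
  write.table(truth$causal[, c("id", "chrom", "bp", "beta", "maf", "marginal_h2")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dosages_path) && !is.null(truth$causal_dosages)) {
    write.table(truth$causal_dosages, dosages_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns a `sim_truth` skeleton sufficient for
#'   [classify_hits()] and [power_at_fdr()].
#' @export
read_truth <- function(path, dosages_path = NULL) {
  causal <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  cd <- NULL
  if (!is.null(dosages_path)) {
    cd <- as.matrix(read.table(dosages_path, header = TRUE, sep = "\t",
                               check.names = FALSE))
  }
  structure(list(causal = causal, causal_dosages = cd), class = "sim_truth")
}
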