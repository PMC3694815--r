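# Small in-code fixtures shared across test files.

# genotype_dataset with independent markers, dosage frequencies < 0.5
make_test_geno <- function(n, p, seed = 1, chrom = "1", spacing = 5000) {
  set.seed(seed)
  f <- runif(p, 0.1, 0.45)
  dos <- sapply(f, function(ff) rbinom(n, 2, ff))
  # keep the in-sample minor allele strictly minor (round trips depend on it)
  for (j in seq_len(p)) {
    while (mean(dos[, j]) >= 1) dos[, j] <- rbinom(n, 2, f[j])
  }
  map <- data.frame(chrom = chrom, id = sprintf("m%04d", seq_len(p)),
                    cM = seq_len(p) * spacing / 1e6, bp = seq_len(p) * spacing,
                    stringsAsFactors = FALSE)
  genotype_dataset(dos, map)
}

# correlated dosage blocks: latent MVN with exchangeable within-block
# correlation, binned at Hardy-Weinberg quantiles to dosages 0/1/2
make_corr_geno <- function(n, block_sizes, block_rho, n_indep = 0, seed = 1,
                           maf = 0.3) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(block_sizes)) {
    k <- block_sizes[b]; rho <- block_rho[b]
    z0 <- rnorm(n)
    Z <- sqrt(rho) * matrix(z0, n, k) + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    cols[[b]] <- Z
  }
  if (n_indep > 0) cols[[length(cols) + 1L]] <- matrix(rnorm(n * n_indep), n, n_indep)
  Z <- do.call(cbind, cols)
  q0 <- qnorm((1 - maf)^2); q1 <- qnorm(1 - maf^2)
  dos <- matrix(0, n, ncol(Z))
  dos[Z > q0] <- 1
  dos[Z > q1] <- 2
  p <- ncol(dos)
  map <- data.frame(chrom = "1", id = sprintf("c%04d", seq_len(p)),
                    cM = seq_len(p) * 0.2, bp = seq_len(p) * 200000,
                    stringsAsFactors = FALSE)
  genotype_dataset(dos, map)
}

# linear phenotype from chosen marker effects
make_linear_pheno <- function(g, idx, beta, sigma = 1, seed = 2) {
  set.seed(seed)
  eta <- drop(g$dosages[, idx, drop = FALSE] %*% beta)
  phenotype_vector(eta + rnorm(nrow(g$dosages), 0, sigma), "linear")
}

# brute-force maximizer of the univariate surrogate, dense grid + refine
brute_coordinate_update <- function(z, d, spec) {
  f <- function(b) -(d / 2) * (b - z)^2 - penalty_value(abs(b), spec)
  grid <- seq(-abs(z), abs(z), length.out = 20001)
  b0 <- grid[which.max(vapply(grid, f, numeric(1)))]
  o <- optimize(f, c(b0 - 1e-3, b0 + 1e-3), maximum = TRUE, tol = 1e-12)
  if (f(0) >= o$objective) 0 else o$maximum
}

# TPED/TFAM fixture writer: dosages to allele pairs with A = minor
write_tped_fixture <- function(g, y, dir = tempfile("tped")) {
  dir.create(dir)
  tped <- file.path(dir, "data.tped"); tfam <- file.path(dir, "data.tfam")
  write_tped_tfam(g, y, tped, tfam)
  list(tped = tped, tfam = tfam)
}
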