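test_that("fit_glm matches closed forms and a generic optimizer", {
  # intercept-only logistic: intercept = log(cases/controls)
  y <- phenotype_vector(rep(c(1, 0), c(30, 70)), "logistic")
  f <- fit_glm(y)
  expect_equal(unname(f$coefficients[1]), log(30 / 70), tolerance = 1e-8)

  # noiseless linear fit recovers the slope exactly
  x <- rnorm(50)
  yl <- phenotype_vector(2 * x, "linear")
  fl <- fit_glm(yl, X = cbind(x))
  expect_equal(unname(fl$coefficients[2]), 2, tolerance = 1e-10)

  # logistic MLE agrees with direct numerical maximization
  set.seed(3)
  n <- 500; x1 <- rnorm(n)
  yb <- phenotype_vector(rbinom(n, 1, plogis(0.3 + 0.7 * x1)), "logistic")
  fb <- fit_glm(yb, X = cbind(x1))
  nll <- function(b) {
    eta <- b[1] + b[2] * x1
    -sum(yb * eta - log1p(exp(eta)))
  }
  o <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fb$coefficients), o$par, tolerance = 1e-6)
  expect_equal(fb$loglik, -o$value, tolerance = 1e-8)
})

test_that("fit_glm flags separation and rank deficiency", {
  y <- phenotype_vector(rep(c(0, 1), each = 20), "logistic")
  x <- as.numeric(y)  # perfect separation
  f <- fit_glm(y, X = cbind(sep = x))
  expect_false(f$converged)
  expect_true(all(abs(f$coefficients) <= 30))
  expect_error(fit_glm(y, X = cbind(a = x, b = 2 * x)), "collinear")
})

test_that("single-marker scan gives p = 1 for covariate-duplicate markers and top rank to a perfect predictor", {
  set.seed(8)
  n <- 100
  g <- make_test_geno(n, 6, seed = 8)
  y <- phenotype_vector(as.numeric(g$dosages[, 3] > 0), "logistic")
  # marker identical to a covariate column adds no likelihood
  C <- covariate_matrix(n, cbind(cov1 = g$dosages[, 1]))
  scan <- single_marker_scan(g, y, C)
  expect_gt(scan$p[1], 0.99)
  # perfect predictor has the smallest p-value
  expect_equal(which.min(scan$p), 3L)
  expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("monomorphic markers are reported null with a warning", {
  g <- make_test_geno(60, 4, seed = 9)
  g$dosages[, 2] <- 1
  y <- phenotype_vector(rbinom(60, 1, 0.5), "logistic")
  expect_warning(scan <- single_marker_scan(g, y), "monomorphic")
  expect_equal(scan$p[2], 1)
  expect_equal(scan$effect[2], 0)
})

test_that("scan p-values are uniform under the null", {
  set.seed(10)
  n <- 600
  g <- make_test_geno(n, 1500, seed = 10)
  y <- phenotype_vector(sample(rep(c(0, 1), each = n / 2)), "logistic")
  scan <- single_marker_scan(g, y)
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # retained fraction under pre-screening matches the cutoff binomially
  keep <- prescreen(scan, 0.05)
  expect_lt(abs(length(keep) / 1500 - 0.05), 3 * sqrt(0.05 * 0.95 / 1500))
})

test_that("prescreen filters by threshold and errors when empty", {
  scan <- structure(data.frame(chrom = "1", id = c("a", "b", "c"),
                               bp = 1:3, effect = 0, stat = 0,
                               p = c(0.5, 0.005, 0.02)),
                    class = c("scan_result", "data.frame"))
  expect_equal(as.integer(suppressMessages(prescreen(scan, 0.01))), 2L)
  expect_equal(length(suppressMessages(prescreen(scan, 1))), 3L)
  scan$p <- c(0.5, 0.6, 0.7)
  expect_error(suppressMessages(prescreen(scan, 0.01)), "relax")
})

test_that("LRT statistics are non-negative and the scan is order-invariant", {
  set.seed(11)
  g <- make_test_geno(120, 30, seed = 11)
  y <- phenotype_vector(rbinom(120, 1, plogis(g$dosages[, 5] - 1)), "logistic")
  scan <- single_marker_scan(g, y)
  expect_true(all(scan$stat >= 0))
  perm <- sample(30)
  g2 <- subset_markers(g, perm)
  scan2 <- single_marker_scan(g2, y)
  expect_equal(scan2$p, scan$p[perm], tolerance = 1e-10)
  # affine recoding of covariates leaves p-values unchanged
  cov <- rnorm(120)
  s3 <- single_marker_scan(g, y, covariate_matrix(120, cbind(c1 = cov)))
  s4 <- single_marker_scan(g, y, covariate_matrix(120, cbind(c1 = 3 * cov + 7)))
  expect_equal(s3$p, s4$p, tolerance = 1e-6)
})

test_that("conditional scan recovers a masked second locus and degenerates gracefully", {
  set.seed(12)
  n <- 400
  # two negatively correlated markers with opposite-sign effects:
  # marginal signal of B is masked, conditional signal is strong
  zA <- rbinom(n, 2, 0.4)
  zB <- pmax(pmin(2 - zA + sample(c(-1, 0, 1), n, TRUE, c(.2, .6, .2)), 2), 0)
  filler <- sapply(runif(8, .2, .4), function(f) rbinom(n, 2, f))
  dos <- cbind(zA, zB, filler)
  map <- data.frame(chrom = "1", id = paste0("s", 1:10), cM = 1:10,
                    bp = (1:10) * 1e6)
  g <- genotype_dataset(dos, map)
  # asymmetric effects: the weaker locus is the one masked marginally
  y <- make_linear_pheno(g, c(1, 2), c(1.2, 0.6), sigma = 1, seed = 12)
  s1 <- single_marker_scan(g, y)
  # cutoff chosen strictly between the two loci's marginal p-values so only
  # the stronger locus enters the stage-1 covariate set
  expect_lt(s1$p[1], s1$p[2])
  cutoff <- exp(mean(log(s1$p[1:2])))
  cs <- conditional_scan(g, y, stage1_cutoff = cutoff)
  # manual two-step fit: test B given A
  C2 <- covariate_matrix(n, cbind(zA = dos[, 1]))
  s2_manual <- single_marker_scan(subset_markers(g, 2), y, C2)
  expect_equal(cs$p[2], min(s1$p[2], s2_manual$p[1]), tolerance = 1e-8)
  expect_lt(cs$p[2], s1$p[2])  # conditioning reveals the masked locus
  # no stage-1 hits: output equals the stage-1 scan
  ynull <- phenotype_vector(rnorm(n), "linear")
  expect_message(cs0 <- conditional_scan(g, ynull, stage1_cutoff = 1e-12),
                 "no stage-1")
  expect_equal(cs0$p, single_marker_scan(g, ynull)$p)
})

test_that("genomic inflation is calibrated, exact at the null median, and scale-equivariant", {
  set.seed(13)
  p_unif <- runif(10000)
  expect_lt(abs(genomic_inflation(p_unif) - 1), 0.05)
  expect_equal(genomic_inflation(rep(0.5, 200)), 1, tolerance = 1e-12)
  q <- rchisq(500, df = 1)
  l1 <- genomic_inflation(pchisq(q, 1, lower.tail = FALSE))
  l2 <- genomic_inflation(pchisq(2 * q, 1, lower.tail = FALSE))
  expect_equal(l2 / l1, 2, tolerance = 1e-8)
})
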