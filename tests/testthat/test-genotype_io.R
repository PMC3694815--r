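test_that("TPED parsing recodes alleles to minor-allele dosages", {
  dir <- tempfile(); dir.create(dir)
  tped <- file.path(dir, "x.tped"); tfam <- file.path(dir, "x.tfam")
  writeLines(c(
    "1 rs1 0.01 1000 A A A G G G A G",   # freq(G) = 3/8 -> G minor
    "1 rs2 0.02 2000 C C C C C T C C",   # freq(T) = 1/8 -> T minor
    "1 rs3 0.03 3000 T T 0 0 T A A A"),  # missing for individual 2
    tped)
  writeLines(sprintf("F%d I%d 0 0 1 %d", 1:4, 1:4, c(2, 1, 2, 1)), tfam)
  out <- read_tped_tfam(tped, tfam)
  g <- out$genotypes
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2, 1))
  expect_equal(unname(g$dosages[, "rs2"]), c(0, 0, 1, 0))
  expect_true(g$missing[2, "rs3"])
  # freq tie 3/6 vs 3/6 -> alphabetically later allele (T) counted as minor
  expect_equal(unname(g$dosages[, "rs3"]), c(2, NA, 1, 0))
  expect_equal(as.numeric(out$phenotype), c(1, 0, 1, 0))    # 2/1 -> 1/0
  expect_identical(attr(out$phenotype, "family"), "logistic")
  expect_equal(g$map$bp, c(1000, 2000, 3000))
})

test_that("minor-allele ties pick the alphabetically later allele", {
  dir <- tempfile(); dir.create(dir)
  tped <- file.path(dir, "x.tped"); tfam <- file.path(dir, "x.tfam")
  writeLines("1 rs1 0 100 A A A G G G A G", tped)  # freq(A) = freq(G) = 0.5
  writeLines(sprintf("F%d I%d 0 0 1 1", 1:4, 1:4), tfam)
  g <- read_tped_tfam(tped, tfam)$genotypes
  expect_equal(unname(g$dosages[, 1]), c(0, 1, 2, 1))  # G counted as minor
})

test_that("malformed and non-biallelic TPED rows raise informative errors", {
  dir <- tempfile(); dir.create(dir)
  tped <- file.path(dir, "x.tped"); tfam <- file.path(dir, "x.tfam")
  writeLines(sprintf("F%d I%d 0 0 1 1", 1:4, 1:4), tfam)
  writeLines("1 rs1 0 100 A A A G G G", tped)  # 3 genotypes for 4 people
  expect_error(read_tped_tfam(tped, tfam), "malformed")
  writeLines("1 rsbad 0 100 A A C G G G T A", tped)
  expect_error(read_tped_tfam(tped, tfam), "rsbad")
})

test_that("missing phenotypes are dropped with a warning", {
  dir <- tempfile(); dir.create(dir)
  tped <- file.path(dir, "x.tped"); tfam <- file.path(dir, "x.tfam")
  writeLines("1 rs1 0 100 A A A G G G A G", tped)
  writeLines(sprintf("F%d I%d 0 0 1 %s", 1:4, 1:4, c("2", "-9", "1", "0")), tfam)
  expect_warning(out <- read_tped_tfam(tped, tfam), "missing phenotype")
  expect_equal(length(out$phenotype), 2L)
  expect_equal(nrow(out$genotypes$dosages), 2L)
})

test_that("write/read round trip is lossless for dosages, ids, positions", {
  g <- make_test_geno(10, 20, seed = 4)
  y <- phenotype_vector(rbinom(10, 1, 0.5), "logistic")
  fx <- write_tped_fixture(g, y)
  out <- read_tped_tfam(fx$tped, fx$tfam)
  expect_equal(out$genotypes$dosages, g$dosages)
  expect_equal(out$genotypes$map$id, g$map$id)
  expect_equal(out$genotypes$map$bp, g$map$bp)
  expect_equal(as.numeric(out$phenotype), as.numeric(y))
})

test_that("mean imputation fills missing calls and preserves observed values", {
  g <- make_test_geno(6, 3, seed = 5)
  g$dosages[, 1] <- c(0, 2, 2, NA, 1, 0)
  g$dosages[4, 1] <- NA
  g$missing <- is.na(g$dosages)
  gi <- impute_missing_mean(g)
  expect_equal(unname(gi$dosages[4, 1]), mean(c(0, 2, 2, 1, 0)))
  expect_equal(gi$dosages[-4, ], g$dosages[-4, ])
  expect_false(any(gi$missing))
  # per-marker mean preserved
  expect_equal(colMeans(gi$dosages)[1], mean(g$dosages[, 1], na.rm = TRUE),
               ignore_attr = TRUE)
  # no missing -> identity
  expect_identical(impute_missing_mean(gi), gi)
  # all-missing marker errors with its name
  g$dosages[, 2] <- NA; g$missing <- is.na(g$dosages)
  expect_error(impute_missing_mean(g), g$map$id[2])
})

test_that("covariate matrix enforces intercept, rank, constant columns", {
  C <- covariate_matrix(5)
  expect_equal(dim(C), c(5L, 1L))
  expect_true(all(C[, 1] == 1))
  x <- cbind(a = rnorm(5), b = rep(2, 5))
  expect_warning(C2 <- covariate_matrix(5, x), "constant")
  expect_equal(colnames(C2), c("intercept", "a"))
  x3 <- cbind(a = 1:5, b = 2 * (1:5))
  expect_error(covariate_matrix(5, x3), "rank deficient")
})

test_that("covariate files are matched to samples by FID/IID", {
  g <- make_test_geno(4, 2, seed = 6)
  path <- tempfile()
  # shuffled rows; must be re-matched to sample order
  tab <- data.frame(FID = g$samples$fid[c(3, 1, 4, 2)],
                    IID = g$samples$iid[c(3, 1, 4, 2)],
                    age = c(30, 10, 40, 20))
  write.table(tab, path, row.names = FALSE, quote = FALSE)
  C <- read_covariates(path, g)
  expect_equal(unname(C[, "age"]), c(10, 20, 30, 40))
})
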