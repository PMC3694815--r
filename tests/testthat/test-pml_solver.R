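test_that("model size bound follows sqrt(n / log n)", {
  expect_identical(model_size_bound(1000), 13L)
  expect_identical(model_size_bound(5000), 25L)
  n <- round(10^seq(1, 6, length.out = 40))
  expect_true(all(diff(vapply(n, model_size_bound, integer(1))) >= 0))
})

test_that("orthogonal-design lasso equals soft-thresholded least squares", {
  set.seed(31)
  n <- 100; p <- 5
  # columns orthogonal to each other and to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n)
  beta_true <- c(2, -1.5, 0, 0.8, 0)
  y <- phenotype_vector(drop(X %*% beta_true) + rnorm(n, 0, 0.3), "linear")
  rate <- 30
  fit <- fit_pmle(X, y, covariate_matrix(n), penalty_spec("lasso", rate))
  d <- colSums(X^2)
  bls <- drop(crossprod(X, as.numeric(y) - mean(y))) / d
  soft <- sign(bls) * pmax(abs(bls) - rate / d, 0)
  expect_equal(unname(fit$beta), soft, tolerance = 1e-4)
})

test_that("penalized logistic fits match a generic optimizer in objective", {
  set.seed(32)
  n <- 200; p <- 10
  X <- sweep(matrix(rnorm(n * p), n, p), 2, colMeans(matrix(0, 1, p)))
  y <- phenotype_vector(rbinom(n, 1, plogis(X[, 1] - 0.7 * X[, 4])), "logistic")
  C <- covariate_matrix(n)
  sp <- penalty_spec("lasso", 10)
  fit <- fit_pmle(X, y, C, sp)
  Xc <- sweep(X, 2, colMeans(X))
  f <- function(par) -penalized_objective(par[-1], par[1], Xc, C, y, "logistic", sp)
  o <- optim(c(fit$alpha, unname(fit$beta)), f, method = "Nelder-Mead",
             control = list(maxit = 50000, reltol = 1e-13))
  expect_lt(-o$value - penalized_objective(fit$beta, fit$alpha, Xc, C, y,
                                           "logistic", sp), 1e-4)
})

test_that("an overwhelming penalty rate yields the null fit", {
  set.seed(33)
  g <- make_test_geno(150, 12, seed = 33)
  y <- phenotype_vector(rbinom(150, 1, 0.4), "logistic")
  fit <- fit_pmle(g, y, spec = penalty_spec("lasso", 1e6))
  expect_identical(fit$k, 0L)
  # first point of the rate path is the entry threshold: exactly null
  path <- convex_path(g, y, family = "lasso", k_max = 3)
  expect_identical(path$table$k[1], 0L)
})

test_that("MM ascent is monotone for every family (spot check)", {
  set.seed(34)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- phenotype_vector(rbinom(n, 1, plogis(X[, 2])), "logistic")
  for (sp in list(penalty_spec("lasso", 3), penalty_spec("mcp", 3, 2),
                  penalty_spec("log", 3, 0.3), penalty_spec("neg", 3, 0.5))) {
    fit <- fit_pmle(X, y, spec = sp, debug = TRUE)
    tr <- attr(fit, "objective_trace")
    expect_true(all(diff(tr) > -1e-8), info = sp$family)
  }
})

test_that("reorderings: convex fits are unique, duplicated markers split modes, seeds reproduce", {
  set.seed(35)
  n <- 150
  x <- rbinom(n, 2, 0.3)
  dos <- cbind(a = x, b = x, c = rbinom(n, 2, 0.3), d = rbinom(n, 2, 0.4))
  map <- data.frame(chrom = "1", id = colnames(dos), cM = 1:4, bp = (1:4) * 1e6)
  g <- genotype_dataset(dos, map)
  y <- make_linear_pheno(g, 1, 1.2, sigma = 0.8, seed = 35)
  conv <- fit_with_reorderings(g, y, spec = penalty_spec("lasso", 40),
                               n_orders = 10, seed = 1)
  expect_length(conv, 1L)
  fits <- fit_with_reorderings(g, y, spec = penalty_spec("mcp", 40, 3),
                               n_orders = 30, seed = 1)
  sets <- unique(lapply(fits, selected_markers))
  expect_gte(length(sets), 2L)  # order decides which twin enters
  fits2 <- fit_with_reorderings(g, y, spec = penalty_spec("mcp", 40, 3),
                                n_orders = 30, seed = 1)
  expect_identical(lapply(fits, `[[`, "beta"), lapply(fits2, `[[`, "beta"))
})

test_that("convex path reaches k_max with at most transient size drops", {
  set.seed(36)
  g <- make_test_geno(300, 40, seed = 36)
  y <- make_linear_pheno(g, c(3, 11, 25), c(1, -0.8, 0.6), sigma = 1, seed = 36)
  path <- convex_path(g, y, family = "lasso", k_max = 6)
  k <- path$table$k
  expect_gte(max(k), 6)
  expect_true(all(diff(k) >= -1))  # warm-start effect at most a small dip
  sel <- select_model(path, 300)
  adm <- path$table$aic[path$table$k <= model_size_bound(300)]
  expect_lte(sel$aic, min(adm) + 1e-9)
})

test_that("adaptive-lasso path runs the two-step procedure", {
  set.seed(37)
  g <- make_test_geno(250, 30, seed = 37)
  y <- make_linear_pheno(g, c(5, 17), c(1.2, -1), sigma = 1, seed = 37)
  path <- convex_path(g, y, family = "adaptive_lasso", k_max = 5)
  expect_s3_class(path, "model_path")
  sel <- select_model(path, 250)
  expect_true(all(c("m0005", "m0017") %in% selected_markers(sel)))
})

test_that("nonconvex grids reproduce the lasso limit and book-keep models", {
  set.seed(38)
  g <- make_test_geno(200, 25, seed = 38)
  y <- make_linear_pheno(g, c(4, 12), c(1, -0.9), sigma = 1, seed = 38)
  path <- nonconvex_grid(g, y, family = "mcp", k_max = 4, n_orders = 5,
                         mode = "2D", shapes = c(1e6, 3), n_sizes = 2, seed = 2)
  tab <- path$table
  # near-lasso shape column agrees with the pure lasso fit at the same rate
  big <- which(tab$shape == 1e6)
  for (i in head(big, 2)) {
    la <- fit_pmle(g, y, spec = penalty_spec("lasso", tab$rate[i]))
    mc <- path$fits[[i]]
    expect_equal(selected_markers(mc), selected_markers(la))
  }
  expect_lte(n_unique_models(path), nrow(tab))
  sel <- select_model(path, 200)
  expect_lte(sel$k, model_size_bound(200))
  # 1D mode fixes the shape at 30
  p1 <- nonconvex_grid(g, y, family = "mcp", k_max = 4, n_orders = 3,
                       mode = "1D", seed = 3)
  expect_true(all(p1$table$shape[!is.na(p1$table$order_id)] == 30))
})

test_that("select_model respects the bound, AIC order and null fallback", {
  set.seed(39)
  g <- make_test_geno(100, 10, seed = 39)
  y <- make_linear_pheno(g, 2, 1, sigma = 1, seed = 39)
  path <- convex_path(g, y, family = "lasso", k_max = 3)
  # bound 0 admits only k = 0 fits; a bound below any fit returns the null model
  sel0 <- select_model(path, 100, bound = 0)
  expect_identical(sel0$k, 0L)
  # AIC ordering: equal k, loglik difference decides
  tabk <- path$table$k
  if (any(tabk > 0)) {
    sel <- select_model(path, 100)
    adm <- which(tabk <= model_size_bound(100))
    expect_lte(sel$aic, min(path$table$aic[adm]) + 1e-9)
  }
})

test_that("perm-MCP tuning is seeded and self-consistent on null data", {
  set.seed(40)
  g <- make_test_geno(200, 60, seed = 40)
  y <- phenotype_vector(sample(rep(c(0, 1), each = 100)), "logistic")
  lam1 <- perm_mcp_rate(g, y, efpr = 0.05, n_perms = 5, seed = 9)
  lam2 <- perm_mcp_rate(g, y, efpr = 0.05, n_perms = 5, seed = 9)
  expect_identical(as.numeric(lam1), as.numeric(lam2))
  # fitting the real (null) phenotype at the tuned rate selects about
  # efpr * p markers on average
  ks <- replicate(10, {
    yp <- phenotype_vector(sample(as.numeric(y)), "logistic")
    fit_pmle(g, yp, spec = penalty_spec("mcp", as.numeric(lam1), 30))$k
  })
  expect_lt(abs(mean(ks) - 0.05 * 60), 3)
  # unreachably small eFPR returns the largest grid rate with a warning
  expect_warning(perm_mcp_rate(g, y, efpr = 1e-6, n_perms = 3, seed = 9),
                 "resolution|grid")
})

test_that("lasso coefficients cross-check against glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(41)
  n <- 300; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- phenotype_vector(drop(X[, 1:3] %*% c(1, -1, .5)) + rnorm(n), "linear")
  rate <- 60
  fit <- fit_pmle(X, y, spec = penalty_spec("lasso", rate))
  gn <- glmnet::glmnet(X, as.numeric(y), family = "gaussian",
                       lambda = rate / n, standardize = FALSE,
                       intercept = TRUE, thresh = 1e-12)
  expect_equal(unname(fit$beta), as.numeric(gn$beta), tolerance = 1e-4)
})
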