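#' Sample-size bound on selectable model size
#'
#' Sparse-regression theory puts the number of coefficients detectable as
#' nonzero at a sample size of n on the order of sqrt(n / log n); model
#' selection only compares models within this bound.
#'
#' @param n sample size (>= 10).
#' @return Integer bound `ceiling(sqrt(n / log(n)))`.
#' @export
model_size_bound <- function(n) {
  stopifnot(n >= 10)
  as.integer(ceiling(sqrt(n / log(n))))
}

glm_family_code <- function(fam) if (fam == "logistic") 1L else 0L

# centered marker matrix + bookkeeping reused across a whole tuning search
solver_data <- function(g, y, C) {
  X <- if (inherits(g, "genotype_dataset")) g$dosages else as.matrix(g)
  if (anyNA(X)) stop("impute missing genotypes before penalized fitting")
  fam <- pheno_family(y)
  yv <- as.numeric(y)
  if (is.null(C)) C <- covariate_matrix(length(yv))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(X)))
  colnames(Xc) <- ids
  list(X = Xc, C = C, y = yv, family = fam, ids = ids,
       map = if (inherits(g, "genotype_dataset")) g$map else NULL)
}

# gradient of the working log-likelihood at the covariate-only MLE;
# determines the lasso entry threshold lambda_max
null_gradient <- function(sd) {
  nf <- fit_glm(structure(sd$y, family = sd$family), C = sd$C)
  resid <- sd$y - nf$fitted
  list(grad = drop(crossprod(sd$X, resid)), null_fit = nf)
}

make_sparse_fit <- function(res, sd, spec, order_id = NA_integer_) {
  n <- length(sd$y)
  beta <- setNames(drop(res$beta), sd$ids)
  k <- sum(beta != 0)
  if (sd$family == "linear") {
    loglik <- -n / 2 * (log(2 * pi * res$rss / n) + 1)
  } else {
    loglik <- res$loglik_work
  }
  structure(list(beta = beta, alpha = setNames(drop(res$alpha), colnames(sd$C)),
                 loglik = loglik, loglik_work = res$loglik_work,
                 k = k, family = spec$family, rate = spec$rate,
                 shape = spec$shape, order_id = order_id,
                 converged = res$converged, sweeps = res$sweeps,
                 aic = -2 * loglik + 2 * (k + ncol(sd$C)), n = n),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("sparse_fit: %s (rate %.4g), k = %d, loglik %.3f, AIC %.2f%s\n",
              x$family, x$rate, x$k, x$loglik, x$aic,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Selected markers of a sparse fit
#' @param fit a `sparse_fit`.
#' @return Character vector of markers with nonzero coefficients.
#' @export
selected_markers <- function(fit) names(fit$beta)[fit$beta != 0]

# fit without re-deriving/centering the design; workhorse for all searches
fit_pmle_core <- function(sd, spec, order = NULL, warm_start = NULL,
                          tol = 1e-5, max_sweeps = 500, debug = FALSE) {
  p <- ncol(sd$X)
  if (is.null(order)) order <- seq_len(p)
  beta0 <- rep(0, p); alpha0 <- rep(0, ncol(sd$C))
  if (!is.null(warm_start)) {
    if (inherits(warm_start, "sparse_fit")) {
      beta0 <- unname(warm_start$beta); alpha0 <- unname(warm_start$alpha)
    } else beta0 <- as.numeric(warm_start)
  }
  pen <- as_cpp_penalty(spec, p)
  res <- cpp_fit_pmle(sd$X, sd$C, sd$y, glm_family_code(sd$family), pen,
                      as.integer(order) - 1L, beta0, alpha0, tol,
                      max_sweeps, debug)
  fit <- make_sparse_fit(res, sd, spec)
  if (debug) attr(fit, "objective_trace") <- res$objective_trace
  fit
}

#' Penalized maximum-likelihood fit by MM coordinate ascent
#'
#' Maximizes the penalized log-likelihood
#' \eqn{\ell(\beta) - \sum_j P(|\beta_j|)} by cyclic coordinate updates.
#' Each marker update maximizes a quadratic minorant of the coordinate
#' log-likelihood with curvature bound \eqn{d_j = \sum_i x_{ij}^2/4}
#' (logistic) or \eqn{\sum_i x_{ij}^2} (linear), which guarantees the
#' penalized objective never decreases. Covariates are updated without
#' penalty. Marker columns are mean-centered internally; coefficients are
#' reported on the dosage scale.
#'
#' @param g a [genotype_dataset()] (typically pre-screened) or numeric
#'   matrix.
#' @param y a [phenotype_vector()].
#' @param C covariate matrix with intercept; intercept-only when `NULL`.
#' @param spec a [penalty_spec()].
#' @param order marker update order (permutation of `1:p`); natural order
#'   when `NULL`.
#' @param warm_start optional `sparse_fit` or coefficient vector to start
#'   from.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep.
#' @param max_sweeps sweep budget; a non-converged fit is flagged but
#'   still returned.
#' @param debug record the penalized objective after every coordinate
#'   update (attribute `objective_trace`).
#' @return A `sparse_fit`.
#' @export
fit_pmle <- function(g, y, C = NULL, spec, order = NULL, warm_start = NULL,
                     tol = 1e-5, max_sweeps = 500, debug = FALSE) {
  sd <- solver_data(g, y, C)
  fit_pmle_core(sd, spec, order = order, warm_start = warm_start,
                tol = tol, max_sweeps = max_sweeps, debug = debug)
}

#' Penalized objective value
#'
#' Evaluates \eqn{\ell(\beta) - \sum_j P(|\beta_j|)} at an arbitrary
#' coefficient state, using the working log-likelihood the solver
#' maximizes (logistic log-likelihood, or -RSS/2 for linear models).
#'
#' @param beta marker coefficients; `alpha` covariate coefficients.
#' @param X marker design matrix exactly as fitted (i.e. mean-centered).
#' @param C covariate matrix; `y` phenotype; `family` `"linear"` or
#'   `"logistic"`; `spec` a [penalty_spec()].
#' @return Scalar objective value.
#' @export
penalized_objective <- function(beta, alpha, X, C, y, family, spec) {
  pen <- as_cpp_penalty(spec, ncol(X))
  cpp_penalized_objective(as.matrix(X), as.matrix(C), as.numeric(y),
                          glm_family_code(family), pen,
                          as.numeric(beta), as.numeric(alpha))
}

model_path <- function(fits, sd, null_fit_sparse, family) {
  tab <- data.frame(rate = vapply(fits, `[[`, numeric(1), "rate"),
                    shape = vapply(fits, `[[`, numeric(1), "shape"),
                    order_id = vapply(fits, `[[`, integer(1), "order_id"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"))
  structure(list(fits = fits, table = tab, family = family,
                 n = length(sd$y), null_fit = null_fit_sparse),
            class = "model_path")
}

#' @export
print.model_path <- function(x, ...) {
  cat(sprintf("model_path (%s): %d models examined, %d unique marker sets\n",
              x$family, nrow(x$table), n_unique_models(x)))
  invisible(x)
}

#' Number of distinct selected-marker sets in a path
#' @param path a `model_path`.
#' @return Integer count of unique models.
#' @export
n_unique_models <- function(path) {
  keys <- vapply(path$fits, function(f) paste(sort(selected_markers(f)),
                                              collapse = ";"), character(1))
  length(unique(keys))
}

null_sparse_fit <- function(sd, spec) {
  nf <- fit_glm(structure(sd$y, family = sd$family), C = sd$C)
  res <- list(beta = rep(0, ncol(sd$X)), alpha = unname(nf$coefficients),
              loglik_work = if (sd$family == "linear")
                -0.5 * nf$rss else nf$loglik,
              rss = if (sd$family == "linear") nf$rss else NA_real_,
              sweeps = 0L, converged = TRUE)
  make_sparse_fit(res, sd, spec)
}

#' Regularization path for the convex penalties
#'
#' Starts from the entry threshold `lambda_max` (the rate at which the
#' null model is exactly optimal) and decreases the rate on a log-spaced
#' grid, warm-starting each fit from the previous one, until `k_max`
#' markers carry nonzero coefficients. For the adaptive lasso the lasso
#' path is run first, the AIC-selected fit provides the initial estimates
#' for [adaptive_weights()], and the weighted path is then traced.
#'
#' @inheritParams fit_pmle
#' @param family `"lasso"` or `"adaptive_lasso"`.
#' @param k_max stop once this many markers are selected (default
#'   [model_size_bound()]).
#' @param n_rates number of grid points between `lambda_max` and
#'   `0.01 lambda_max`.
#' @return A `model_path`.
#' @export
convex_path <- function(g, y, C = NULL, family = c("lasso", "adaptive_lasso"),
                        k_max = NULL, n_rates = 20, tol = 1e-5) {
  family <- match.arg(family)
  sd <- solver_data(g, y, C)
  if (is.null(k_max)) k_max <- model_size_bound(length(sd$y))
  stopifnot(k_max >= 1)

  run_path <- function(weights) {
    ng <- null_gradient(sd)
    w <- if (is.null(weights)) rep(1, ncol(sd$X)) else weights
    lam_max <- max(abs(ng$grad) / w)
    rates <- exp(seq(log(lam_max), log(0.01 * lam_max), length.out = n_rates))
    fits <- list()
    warm <- NULL
    for (r in rates) {
      spec_r <- penalty_spec(family, rate = r,
                             weights = if (family == "adaptive_lasso") w)
      fit <- fit_pmle_core(sd, spec_r, warm_start = warm, tol = tol)
      fits[[length(fits) + 1L]] <- fit
      warm <- fit
      if (fit$k >= k_max) break
    }
    fits
  }

  if (family == "lasso") {
    fits <- run_path(NULL)
  } else {
    lasso_path <- convex_path(g, y, C, "lasso", k_max = k_max,
                              n_rates = n_rates, tol = tol)
    init <- select_model(lasso_path, length(sd$y))
    if (init$k == 0L) {  # fall back to the densest path fit
      init <- lasso_path$fits[[which.max(lasso_path$table$k)]]
    }
    w <- adaptive_weights(init$beta)
    fits <- run_path(w)
  }
  spec0 <- penalty_spec(family, rate = Inf,
                        weights = if (family == "adaptive_lasso")
                          rep(1, ncol(sd$X)))
  model_path(fits, sd, null_sparse_fit(sd, spec0), family)
}

default_shapes <- function(family) {
  switch(family,
         mcp = c(100, 30, 10, 3, 1.5),
         log = c(100, 10, 1, 0.1, 0.01),
         neg = c(10, 3, 1, 0.3, 0.1))
}

make_orders <- function(p, n_orders, seed) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_orders), function(i) sample.int(p))
}

#' Multimodal exploration via update-order permutations
#'
#' For the non-convex penalties the likelihood surface is multimodal and
#' the mode reached depends on the coordinate update order; refitting
#' under random reorderings explores multiple modes. Convex penalties have
#' a unique optimum, so a single fit is returned.
#'
#' @inheritParams fit_pmle
#' @param n_orders number of random update orders (default 100).
#' @param seed RNG seed for the permutations (reproducible fits).
#' @return List of `sparse_fit`; attribute `unique_sets` holds the
#'   distinct selected-marker sets.
#' @export
fit_with_reorderings <- function(g, y, C = NULL, spec, n_orders = 100,
                                 seed = NULL, warm_start = NULL, tol = 1e-5) {
  sd <- solver_data(g, y, C)
  yv <- structure(sd$y, family = sd$family)
  if (spec$family %in% c("lasso", "adaptive_lasso")) {
    fits <- list(fit_pmle_core(sd, spec, warm_start = warm_start, tol = tol))
  } else {
    orders <- make_orders(ncol(sd$X), n_orders, seed)
    fits <- lapply(seq_along(orders), function(i) {
      f <- fit_pmle_core(sd, spec, order = orders[[i]],
                         warm_start = warm_start, tol = tol)
      f$order_id <- i
      f
    })
  }
  sets <- unique(lapply(fits, selected_markers))
  structure(fits, unique_sets = sets)
}

#' Tuning-parameter grid search for the non-convex penalties
#'
#' Traces the lasso path first (the lasso is the convexity limit of all
#' three families), takes lasso solutions at equally spaced model sizes up
#' to `k_max` as warm starts, and gradually increases the non-convexity of
#' the penalty along the family's shape schedule, refitting under
#' `n_orders` random update orders at every grid cell (warm starts chain
#' per order from the previous shape). `mode = "1D"` instead fixes the
#' shape at its conventional value (MCP gamma = 30) and searches the rate
#' only.
#'
#' @inheritParams fit_with_reorderings
#' @param family `"log"`, `"neg"` or `"mcp"`.
#' @param k_max model-size cap (default [model_size_bound()]).
#' @param mode `"2D"` (rate x shape grid) or `"1D"` (rate only).
#' @param shapes shape schedule, most convex first; family defaults from
#'   the package.
#' @param n_sizes number of lasso warm-start sizes for the 2D grid.
#' @param n_rates rate-grid resolution for the underlying lasso path.
#' @return A `model_path` containing every grid-cell fit.
#' @export
nonconvex_grid <- function(g, y, C = NULL, family = c("mcp", "log", "neg"),
                           k_max = NULL, n_orders = 100, mode = c("2D", "1D"),
                           shapes = NULL, n_sizes = 5, n_rates = 20,
                           seed = NULL, tol = 1e-5) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  sd <- solver_data(g, y, C)
  yv <- structure(sd$y, family = sd$family)
  if (is.null(k_max)) k_max <- model_size_bound(length(sd$y))
  orders <- make_orders(ncol(sd$X), n_orders, seed)

  lasso_path <- convex_path(sd$X, yv, sd$C, "lasso", k_max = k_max,
                            n_rates = n_rates, tol = tol)
  fits <- list()

  if (mode == "1D") {
    shape1 <- switch(family, mcp = 30, log = 1, neg = 1)
    rates <- lasso_path$table$rate
    warm <- vector("list", n_orders)  # per-order warm-start chain
    for (r in rates) {
      spec_r <- penalty_spec(family, rate = r, shape = shape1)
      ks <- integer(n_orders)
      for (o in seq_len(n_orders)) {
        f <- fit_pmle_core(sd, spec_r, order = orders[[o]],
                           warm_start = warm[[o]], tol = tol)
        f$order_id <- o
        warm[[o]] <- f
        ks[o] <- f$k
        fits[[length(fits) + 1L]] <- f
      }
      if (median(ks) >= k_max) break
    }
  } else {
    if (is.null(shapes)) shapes <- default_shapes(family)
    # larger shape = closer to the lasso limit for all three families
    shapes <- sort(shapes, decreasing = TRUE)
    # lasso warm starts at equally spaced model sizes
    targets <- unique(pmax(1L, round(seq(1, k_max, length.out = n_sizes))))
    ks_path <- lasso_path$table$k
    starts <- unique(vapply(targets, function(t) {
      which.min(abs(ks_path - t))
    }, integer(1)))
    for (s in starts) {
      base_fit <- lasso_path$fits[[s]]
      rate_s <- lasso_path$table$rate[s]
      warm <- rep(list(base_fit), n_orders)
      for (sh in shapes) {
        spec_c <- penalty_spec(family, rate = rate_s, shape = sh)
        for (o in seq_len(n_orders)) {
          f <- fit_pmle_core(sd, spec_c, order = orders[[o]],
                             warm_start = warm[[o]], tol = tol)
          f$order_id <- o
          warm[[o]] <- f
          fits[[length(fits) + 1L]] <- f
        }
      }
    }
  }
  all_fits <- c(lasso_path$fits, fits)
  model_path(all_fits, sd, lasso_path$null_fit, family)
}

#' AIC model selection under the model-size bound
#'
#' Among all path fits with at most [model_size_bound()] selected markers,
#' returns the fit with the smallest AIC
#' (\eqn{-2\ell + 2(k + \mathrm{covariates})}); ties go to the smaller
#' model, then to the fit encountered first. If no fit satisfies the
#' bound the null model is returned with a warning.
#'
#' @param path a `model_path`.
#' @param n sample size (sets the bound).
#' @param bound optional explicit model-size bound.
#' @return The selected `sparse_fit`.
#' @export
select_model <- function(path, n, bound = NULL) {
  if (!length(path$fits)) stop("empty model path")
  if (is.null(bound)) bound <- model_size_bound(n)
  tab <- path$table
  ok <- which(tab$k <= bound)
  if (!length(ok)) {
    warning("no path fit satisfies the model-size bound; returning null model")
    return(path$null_fit)
  }
  ord <- ok[order(tab$aic[ok], tab$k[ok], ok)]
  path$fits[[ord[1]]]
}

#' Permutation-based MCP rate tuning
#'
#' Chooses the MCP rate so that, on phenotype permutations (which destroy
#' any genotype-phenotype association), the average number of selected
#' markers equals `efpr * p`, the expected false positive count among the
#' `p` screened markers. The shape is held at its conventional value
#' (gamma = 30).
#'
#' @inheritParams fit_pmle
#' @param shape fixed MCP shape (default 30).
#' @param efpr expected false positive rate over the screened markers
#'   (default 1e-3).
#' @param n_perms number of phenotype permutations.
#' @param seed RNG seed for the permutations.
#' @return The tuned rate (attributes `mean_counts` and `rates` expose the
#'   permutation curve).
#' @export
perm_mcp_rate <- function(g, y, C = NULL, shape = 30, efpr = 1e-3,
                          n_perms = 10, seed = NULL, tol = 1e-5) {
  stopifnot(efpr > 0, efpr < 1)
  sd <- solver_data(g, y, C)
  p <- ncol(sd$X)
  target <- efpr * p
  if (!is.null(seed)) set.seed(seed)
  perms <- lapply(seq_len(n_perms), function(i) sample.int(length(sd$y)))

  lam_max <- 0
  for (pr in perms) {
    sd_p <- sd; sd_p$y <- sd$y[pr]
    lam_max <- max(lam_max, max(abs(null_gradient(sd_p)$grad)))
  }
  rates <- exp(seq(log(lam_max * 1.0001), log(0.2 * lam_max), length.out = 30))
  counts <- matrix(0, n_perms, length(rates))
  for (i in seq_len(n_perms)) {
    warm <- NULL
    sd_i <- sd; sd_i$y <- sd$y[perms[[i]]]
    for (r in seq_along(rates)) {
      spec_r <- penalty_spec("mcp", rate = rates[r], shape = shape)
      f <- fit_pmle_core(sd_i, spec_r, warm_start = warm, tol = tol)
      warm <- f
      counts[i, r] <- f$k
      if (f$k >= max(20, 4 * target)) {  # well past the target; stop this perm
        if (r < length(rates)) counts[i, (r + 1):length(rates)] <- f$k
        break
      }
    }
  }
  mean_k <- colMeans(counts)
  if (target < 1 / n_perms) {
    warning("target eFPR count below permutation-grid resolution; ",
            "returning largest rate")
    return(structure(rates[1], rates = rates, mean_counts = mean_k))
  }
  if (all(mean_k < target)) {
    warning("target eFPR count beyond the rate grid; returning smallest rate")
    lam <- rates[length(rates)]
  } else if (mean_k[1] >= target) {
    warning("target eFPR count below permutation-grid resolution; ",
            "returning largest rate")
    lam <- rates[1]
  } else {
    j <- which(mean_k >= target)[1]
    # linear interpolation in rate between the bracketing grid points
    x0 <- rates[j - 1]; x1 <- rates[j]
    y0 <- mean_k[j - 1]; y1 <- mean_k[j]
    lam <- x0 + (target - y0) / (y1 - y0) * (x1 - x0)
  }
  structure(lam, rates = rates, mean_counts = mean_k)
}
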