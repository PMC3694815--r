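#' Unpenalized generalized linear model fit
#'
#' Maximum likelihood for linear (least squares) or logistic (IRLS)
#' regression of a phenotype on covariates plus optional marker columns.
#' Perfect separation in the logistic case is handled by capping
#' coefficients at +/- 30 and flagging the fit as non-converged; the
#' reported log-likelihood is evaluated at the capped coefficients.
#'
#' @param y a [phenotype_vector()] (or numeric; 0/1 implies logistic).
#' @param X optional numeric matrix of penalizable design columns
#'   (markers); may be `NULL`.
#' @param C covariate matrix including the intercept (see
#'   [covariate_matrix()]).
#' @return An object of class `glm_fit` with elements `coefficients`
#'   (covariates first, then markers), `loglik`, `family`, `converged`,
#'   `iterations`, `fitted`.
#' @export
fit_glm <- function(y, X = NULL, C = covariate_matrix(length(y))) {
  fam <- pheno_family(y)
  y <- as.numeric(y)
  A <- if (is.null(X)) C else cbind(C, X)
  n <- nrow(A)
  if (n <= ncol(A)) stop("more design columns than observations")
  qr_a <- qr(A)
  if (qr_a$rank < ncol(A)) {
    bad <- colnames(A)[-qr_a$pivot[seq_len(qr_a$rank)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (fam == "linear") {
    fit <- lm.fit(A, y)
    rss <- sum(fit$residuals^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    out <- list(coefficients = fit$coefficients, loglik = ll,
                family = "linear", converged = TRUE, iterations = 1L,
                fitted = fit$fitted.values, rss = rss)
  } else {
    fit <- suppressWarnings(glm.fit(A, y, family = binomial()))
    b <- fit$coefficients
    conv <- fit$converged
    if (any(abs(b) > 30)) {  # separation: cap and flag
      b <- pmin(pmax(b, -30), 30)
      conv <- FALSE
    }
    eta <- drop(A %*% b)
    mu <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    out <- list(coefficients = b, loglik = ll, family = "logistic",
                converged = conv, iterations = fit$iter, fitted = mu)
  }
  structure(out, class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit (%s): %d coefficients, loglik %.3f%s\n", x$family,
              length(x$coefficients), x$loglik,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

scan_result <- function(map, effect, stat, p, test) {
  out <- data.frame(chrom = map$chrom, id = map$id, bp = map$bp,
                    effect = effect, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  structure(out, test = test, class = c("scan_result", "data.frame"))
}

#' Single-marker association scan
#'
#' Tests each marker one at a time: `y ~ C + g_j` against `y ~ C`, with an
#' F-test for linear phenotypes and a likelihood-ratio chi-square test for
#' logistic phenotypes. Monomorphic markers get p-value 1 and effect 0
#' with a warning.
#'
#' @param g a [genotype_dataset()] with no missing calls (see
#'   [impute_missing_mean()]).
#' @param y a [phenotype_vector()].
#' @param C covariate matrix including intercept; intercept-only when
#'   `NULL`.
#' @return A `scan_result` data.frame with columns `chrom`, `id`, `bp`,
#'   `effect`, `stat`, `p`.
#' @export
single_marker_scan <- function(g, y, C = NULL) {
  if (any(g$missing)) stop("impute missing genotypes before scanning")
  n <- nrow(g$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  fam <- pheno_family(y)
  yv <- as.numeric(y)
  G <- g$dosages
  mono <- apply(G, 2, function(v) var(v) == 0)

  if (fam == "linear") {
    # residualize y and every marker against C, then per-marker slope/F
    Q <- qr.Q(qr(C))
    ry <- yv - Q %*% crossprod(Q, yv)
    RG <- G - Q %*% crossprod(Q, G)
    sxx <- colSums(RG^2)
    sxy <- drop(crossprod(RG, ry))
    syy <- sum(ry^2)
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    rss1 <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
    df2 <- n - ncol(C) - 1L
    fstat <- (syy - rss1) / (rss1 / df2)
    p <- pf(fstat, 1, df2, lower.tail = FALSE)
    stat <- fstat
    test <- "F"
  } else {
    null_fit <- fit_glm(y, C = C)
    sc <- cpp_scan_logistic(G, C, yv, start = null_fit$coefficients)
    lrt <- pmax(2 * (sc$loglik - null_fit$loglik), 0)
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    beta <- sc$effect
    stat <- lrt
    test <- "LRT"
  }
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s); p-value set to 1")
    p[mono] <- 1; beta[mono] <- 0; stat[mono] <- 0
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  scan_result(g$map, beta, stat, p, test)
}

#' Pre-screen markers on marginal association
#'
#' Keeps markers whose single-marker p-value is at or below the cutoff,
#' preserving marker order. Marginally weak markers are extremely unlikely
#' to enter the joint model, so discarding them changes little while
#' shrinking the problem dramatically.
#'
#' @param scan a `scan_result` from [single_marker_scan()].
#' @param cutoff p-value cutoff (default 0.01).
#' @return Integer vector of retained marker indices (attribute
#'   `retained_fraction`).
#' @export
prescreen <- function(scan, cutoff = 0.01) {
  keep <- which(scan$p <= cutoff)
  if (!length(keep)) {
    stop("no markers pass the pre-screening cutoff ", cutoff,
         "; relax the cutoff")
  }
  frac <- length(keep) / nrow(scan)
  message(sprintf("pre-screen: retained %d / %d markers (%.2f%%)",
                  length(keep), nrow(scan), 100 * frac))
  structure(keep, retained_fraction = frac)
}

# greedy pruning: keep the strongest hit, drop others within `window` bp
prune_hits_by_window <- function(scan, idx, window) {
  ord <- idx[order(scan$p[idx])]
  kept <- integer(0)
  for (i in ord) {
    if (!any(scan$chrom[kept] == scan$chrom[i] &
             abs(scan$bp[kept] - scan$bp[i]) <= window)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Two-stage conditional association scan
#'
#' Stage 1 is a [single_marker_scan()]. Markers passing `stage1_cutoff`
#' are pruned to the single most strongly associated marker per `window`
#' (base pairs), those markers are added to the covariates, and the
#' remaining markers are re-tested. Each marker is reported with the
#' smaller of its stage-1 and stage-2 p-values; stage-1 covariate markers
#' keep their stage-1 p-value.
#'
#' @inheritParams single_marker_scan
#' @param stage1_cutoff p-value cutoff for stage-1 hits (default 1e-5).
#' @param window pruning window in bp (default 100000).
#' @return A `scan_result`; attribute `stage1_markers` lists the markers
#'   conditioned on.
#' @export
conditional_scan <- function(g, y, C = NULL, stage1_cutoff = 1e-5,
                             window = 1e5) {
  n <- nrow(g$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  s1 <- single_marker_scan(g, y, C)
  hits <- which(s1$p <= stage1_cutoff)
  if (!length(hits)) {
    message("conditional scan: no stage-1 hits; returning stage-1 scan")
    attr(s1, "stage1_markers") <- character(0)
    return(s1)
  }
  lead <- prune_hits_by_window(s1, hits, window)
  C2 <- cbind(C, g$dosages[, lead, drop = FALSE])
  rest <- setdiff(seq_len(ncol(g$dosages)), lead)
  s2 <- single_marker_scan(subset_markers(g, rest), y, C2)
  out <- s1
  m2 <- match(s2$id, out$id)
  better <- s2$p < out$p[m2]
  out$p[m2[better]] <- s2$p[better]
  out$effect[m2[better]] <- s2$effect[better]
  out$stat[m2[better]] <- s2$stat[better]
  attr(out, "stage1_markers") <- s1$id[lead]
  out
}

#' Genomic inflation factor
#'
#' Devlin-Roeder genomic control: the median of the one-degree-of-freedom
#' chi-square quantiles of the p-values divided by the null median
#' (0.4549). Values near 1 indicate a calibrated scan.
#'
#' @param scan a `scan_result` or a numeric vector of p-values.
#' @return Scalar inflation factor \eqn{\lambda}.
#' @export
genomic_inflation <- function(scan) {
  p <- if (is.data.frame(scan)) scan$p else as.numeric(scan)
  if (length(p) < 100L) warning("fewer than 100 p-values; inflation estimate is noisy")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}
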