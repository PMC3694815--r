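#' Unpenalized refit with drop-one likelihood-ratio tests
#'
#' Fits a single unpenalized model containing every selected marker plus
#' the covariates, then tests each marker by comparing that full model to
#' the model with the marker omitted (chi-square on one degree of
#' freedom).
#'
#' @param selected marker ids or indices to refit.
#' @param g a [genotype_dataset()] (imputed).
#' @param y a [phenotype_vector()].
#' @param C covariate matrix with intercept; intercept-only when `NULL`.
#' @return data.frame with columns `id`, `coefficient`, `stat`, `p`.
#' @export
refit_and_test <- function(selected, g, y, C = NULL) {
  n <- nrow(g$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  if (is.numeric(selected)) selected <- g$map$id[selected]
  if (anyDuplicated(selected)) stop("duplicated marker in selected set")
  idx <- match(selected, g$map$id)
  if (anyNA(idx)) stop("unknown marker id: ",
                       paste(selected[is.na(idx)], collapse = ", "))
  m <- length(idx)
  if (m > n / 10) stop("selected set too large for a stable refit (> n/10)")
  X <- g$dosages[, idx, drop = FALSE]
  full <- fit_glm(y, X, C)
  coefs <- full$coefficients[ncol(C) + seq_len(m)]
  stat <- p <- numeric(m)
  for (j in seq_len(m)) {
    red <- fit_glm(y, X[, -j, drop = FALSE], C)
    stat[j] <- max(2 * (full$loglik - red$loglik), 0)
    p[j] <- pchisq(stat[j], df = 1, lower.tail = FALSE)
  }
  data.frame(id = selected, coefficient = unname(coefs), stat = stat,
             p = pmax(p, .Machine$double.xmin), stringsAsFactors = FALSE)
}

#' Correlation pruning with minimum-p scoring
#'
#' Selected markers in the same LD block inflate each other's coefficient
#' variance, masking significance. This routine iteratively (1) refits and
#' tests the retained set with [refit_and_test()], (2) finds the marker
#' pair with the largest absolute genotype correlation, and (3) drops the
#' member with the smaller absolute refit coefficient, until no pairwise
#' correlation exceeds `corr_cutoff`. Every marker (including dropped
#' ones) is scored with the smallest p-value it received in any
#' iteration; the scores rank markers by confidence but are heuristic,
#' not strict asymptotic p-values.
#'
#' @inheritParams refit_and_test
#' @param corr_cutoff largest allowed pairwise absolute correlation among
#'   retained markers (default 0.1).
#' @return An `association_report` data.frame: `id`, `chrom`, `bp`,
#'   `coefficient`, `score`, `iteration`, `retained`, sorted by score.
#' @export
prune_and_score <- function(selected, g, y, C = NULL, corr_cutoff = 0.1) {
  n <- nrow(g$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  if (is.numeric(selected)) selected <- g$map$id[selected]
  if (!length(selected)) stop("empty selected set")
  retained <- selected
  score <- setNames(rep(Inf, length(selected)), selected)
  coef_at_best <- setNames(rep(NA_real_, length(selected)), selected)
  iter_at_best <- setNames(rep(NA_integer_, length(selected)), selected)
  retained_flag <- setNames(rep(TRUE, length(selected)), selected)

  # (near-)exact collinearity makes the refit unidentifiable; resolve such
  # pairs up front by the coefficient tie rule (drop the higher index) and
  # give the dropped twin its surviving duplicate's score afterwards
  twin <- character(0)
  if (length(retained) > 1L) {
    cm <- abs(cor(g$dosages[, match(retained, g$map$id), drop = FALSE]))
    diag(cm) <- 0
    while (max(cm) >= 0.9999) {
      pair <- sort(which(cm == max(cm), arr.ind = TRUE)[1, ])
      twin[retained[pair[2]]] <- retained[pair[1]]
      retained_flag[retained[pair[2]]] <- FALSE
      retained <- retained[-pair[2]]
      if (length(retained) < 2L) break
      cm <- cm[-pair[2], -pair[2], drop = FALSE]
    }
  }

  it <- 0L
  repeat {
    rt <- refit_and_test(retained, g, y, C)
    upd <- rt$p < score[rt$id]
    score[rt$id[upd]] <- rt$p[upd]
    coef_at_best[rt$id[upd]] <- rt$coefficient[upd]
    iter_at_best[rt$id[upd]] <- it
    if (length(retained) < 2L) break
    D <- g$dosages[, match(retained, g$map$id), drop = FALSE]
    cm <- abs(cor(D))
    diag(cm) <- 0
    if (max(cm) <= corr_cutoff) break
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    b <- abs(rt$coefficient[match(retained[pair], rt$id)])
    # smaller |coefficient| dropped; ties drop the higher-index marker
    drop_pos <- if (b[1] < b[2]) pair[1]
                else if (b[2] < b[1]) pair[2]
                else max(pair)
    retained_flag[retained[drop_pos]] <- FALSE
    retained <- retained[-drop_pos]
    it <- it + 1L
    stopifnot(it <= length(selected) - 1L)  # one drop per iteration
  }
  for (d in names(twin)) {  # follow duplicate chains to a scored survivor
    s <- twin[[d]]
    while (s %in% names(twin)) s <- twin[[s]]
    score[d] <- score[s]
    coef_at_best[d] <- coef_at_best[s]
    iter_at_best[d] <- iter_at_best[s]
  }
  out <- data.frame(id = selected,
                    chrom = g$map$chrom[match(selected, g$map$id)],
                    bp = g$map$bp[match(selected, g$map$id)],
                    coefficient = unname(coef_at_best[selected]),
                    score = unname(score[selected]),
                    iteration = unname(iter_at_best[selected]),
                    retained = unname(retained_flag[selected]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$score), ]
  rownames(out) <- NULL
  structure(out, iterations = it, corr_cutoff = corr_cutoff,
            class = c("association_report", "data.frame"))
}

#' Residual-QQ overfitting diagnostic
#'
#' Fits the selected markers unpenalized, computes residuals (response
#' scale for linear models, deviance residuals for logistic), regresses
#' every non-selected marker against those residuals, and reports the
#' resulting p-values with their genomic inflation factor. A slight tail
#' inflation is expected when real signal remains; marked deflation is
#' the signature of an overfit selected model. Purely descriptive - no
#' decision is taken.
#'
#' @param selected marker ids or indices in the selected model (may be
#'   empty, in which case residuals are the centered phenotype).
#' @param g_all full [genotype_dataset()] (imputed).
#' @inheritParams refit_and_test
#' @return List with `p` (named p-values for non-selected markers) and
#'   `lambda` (genomic inflation on them).
#' @export
residual_qq_diagnostic <- function(selected, g_all, y, C = NULL) {
  n <- nrow(g_all$dosages)
  if (is.null(C)) C <- covariate_matrix(n)
  if (is.numeric(selected)) selected <- g_all$map$id[selected]
  yv <- as.numeric(y)
  if (length(selected)) {
    idx <- match(selected, g_all$map$id)
    fit <- fit_glm(y, g_all$dosages[, idx, drop = FALSE], C)
    if (pheno_family(y) == "linear") {
      r <- yv - fit$fitted
    } else {
      mu <- fit$fitted
      r <- sign(yv - mu) * sqrt(-2 * (yv * log(mu) + (1 - yv) * log1p(-mu)))
    }
    rest <- setdiff(seq_len(ncol(g_all$dosages)), idx)
  } else {
    r <- yv - mean(yv)
    rest <- seq_len(ncol(g_all$dosages))
  }
  G <- g_all$dosages[, rest, drop = FALSE]
  rc <- r - mean(r)
  # implicit centering: crossprod(Gc, rc) = crossprod(G, rc) for centered rc
  mu_g <- colMeans(G)
  sxx <- colSums(G^2) - n * mu_g^2
  sxy <- drop(crossprod(G, rc))
  syy <- sum(rc^2)
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), 0)
  tstat <- sqrt(pmax(r2, 0) * (n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  names(p) <- g_all$map$id[rest]
  list(p = p, lambda = genomic_inflation(p))
}
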