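#' Specify a sparsity penalty
#'
#' All five families share a rate parameter `rate` (the slope of the
#' penalty near the origin, in log-likelihood units per unit coefficient).
#' The non-convex families carry a second, shape parameter:
#'
#' * `lasso`: \eqn{P(b) = \lambda b} (no shape).
#' * `adaptive_lasso`: \eqn{P_j(b) = \lambda w_j b} with per-marker
#'   weights from [adaptive_weights()].
#' * `mcp`: \eqn{P(b) = \lambda b - b^2/(2\gamma)} for
#'   \eqn{b \le \gamma\lambda}, constant \eqn{\gamma\lambda^2/2} beyond;
#'   the derivative reaches exactly zero at \eqn{b = \gamma\lambda}.
#'   `shape` is \eqn{\gamma > 1}.
#' * `log`: \eqn{P(b) = \lambda \log(1 + b/\eta)/\log(1 + 1/\eta)};
#'   `shape` is \eqn{\eta > 0}, with the lasso recovered as
#'   \eqn{\eta \to \infty}.
#' * `neg`: the negative log marginal density of the
#'   normal-exponential-gamma distribution, a function of
#'   \eqn{b/\gamma} alone, rescaled so its slope at the origin equals
#'   `rate`; `shape` is the NEG shape parameter \eqn{a > 0} (smaller
#'   values give heavier tails). Its derivative involves a ratio of
#'   parabolic cylinder functions and is tabulated internally.
#'
#' @param family one of `"lasso"`, `"adaptive_lasso"`, `"log"`, `"neg"`,
#'   `"mcp"`.
#' @param rate non-negative penalty rate \eqn{\lambda}.
#' @param shape second tuning parameter (ignored for the convex families);
#'   defaults: mcp 30, log 1, neg 1.
#' @param weights strictly positive per-marker multipliers
#'   (adaptive_lasso only).
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "adaptive_lasso", "log", "neg", "mcp"),
                         rate, shape = NULL, weights = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (is.null(shape)) {
    shape <- switch(family, mcp = 30, log = 1, neg = 1, 1)
  }
  if (family == "mcp" && shape <= 1) stop("mcp shape (gamma) must exceed 1")
  if (family %in% c("log", "neg") && shape <= 0) stop("shape must be positive")
  if (!is.null(weights)) {
    if (family != "adaptive_lasso") stop("weights apply to adaptive_lasso only")
    if (any(weights <= 0)) stop("weights must be strictly positive")
  }
  structure(list(family = family, rate = rate, shape = shape, weights = weights),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("penalty_spec: %s (rate %.4g%s)\n", x$family, x$rate,
              if (x$family %in% c("mcp", "log", "neg"))
                sprintf(", shape %.4g", x$shape) else ""))
  invisible(x)
}

family_code <- function(family) {
  match(family, c("lasso", "adaptive_lasso", "log", "neg", "mcp")) - 1L
}

# ---- NEG penalty internals -------------------------------------------------
#
# The NEG marginal density is kappa * exp(b^2/(4 gamma^2)) D_{-2a-1}(b/gamma)
# with parabolic cylinder function D. The penalty -log density depends on b
# only through u = b/gamma, and its derivative is
#   P'(b) = ((2a+1)/gamma) * D_{-2a-2}(u) / D_{-2a-1}(u).
# Via D_nu(z) = 2^(nu/2) exp(-z^2/4) U(-nu/2, 1/2, z^2/2) the ratio reduces
# to Tricomi U functions, which we evaluate from the integral representation
#   U(q, 1/2, x) = (1/Gamma(q)) Int_0^inf exp(-x t) t^(q-1) (1+t)^(-q-1/2) dt.

# generalized Gauss-Laguerre rule (weight t^alpha e^-t) via Golub-Welsch
gauss_laguerre <- local({
  cache <- new.env(parent = emptyenv())
  function(n, alpha) {
    key <- sprintf("%d_%.10g", n, alpha)
    if (is.null(cache[[key]])) {
      i <- seq_len(n) - 1
      J <- diag(2 * i + alpha + 1)
      off <- sqrt(seq_len(n - 1) * (seq_len(n - 1) + alpha))
      J[cbind(1:(n - 1), 2:n)] <- off
      J[cbind(2:n, 1:(n - 1))] <- off
      e <- eigen(J, symmetric = TRUE)
      cache[[key]] <- list(nodes = e$values,
                           weights = gamma(alpha + 1) * e$vectors[1, ]^2)
    }
    cache[[key]]
  }
})

tricomi_u_half <- function(q, x) {
  if (x > 1e4) {  # large-argument asymptotic, relative error O(x^-2)
    return(x^(-q) * (1 - q * (q + 0.5) / x))
  }
  if (x > 1) {
    # substitute s = x t: x^-q Int s^(q-1) e^-s (1 + s/x)^(-q-1/2) ds
    gl <- gauss_laguerre(96, q - 1)
    return(x^(-q) * sum(gl$weights * (1 + gl$nodes / x)^(-q - 0.5)) / gamma(q))
  }
  # substitute t = tan^2(theta): bounded smooth integrand on (0, pi/2);
  # split at the e^(-x tan^2) shoulder so quadrature resolves both pieces
  f <- function(th) 2 * sin(th)^(2 * q - 1) * exp(-x * tan(th)^2)
  cut <- atan(1 / sqrt(max(x, 1e-12)))
  val <- tryCatch(
    stats::integrate(f, 0, cut, rel.tol = 1e-9, subdivisions = 500L)$value +
      stats::integrate(f, cut, pi / 2, rel.tol = 1e-9,
                       subdivisions = 500L)$value,
    error = function(e)
      stats::integrate(f, 0, pi / 2, rel.tol = 1e-7,
                       subdivisions = 1000L, stop.on.error = FALSE)$value)
  val / gamma(q)
}

# D_{-2a-2}(u) / D_{-2a-1}(u): decreasing in u, drives the shrinkage
neg_pcf_ratio <- function(a, u) {
  x <- u^2 / 2
  tricomi_u_half(a + 1, x) / tricomi_u_half(a + 0.5, x) / sqrt(2)
}

# slope of the unit-scale NEG penalty Q_a(u) at the origin
neg_slope0 <- function(a) (2 * a + 1) * gamma(a + 1) / (sqrt(2) * gamma(a + 1.5))

# Tabulate P'(b) and P(b) for a NEG spec on a b-grid, for interpolation in
# the solver. Beyond the grid the derivative follows its exact (2a+1)/b
# asymptote; the evaluation saturates rather than overflowing.
neg_table <- function(rate, a, b_max = 150) {
  gam <- neg_slope0(a) / rate  # scale chosen so P'(0) = rate
  b <- c(0, 10^seq(-5, log10(b_max), length.out = 400))
  dp <- vapply(b, function(bb) {
    if (bb == 0) return(rate)
    (2 * a + 1) / gam * neg_pcf_ratio(a, bb / gam)
  }, numeric(1))
  # cumulative trapezoid for the penalty value
  pv <- c(0, cumsum((dp[-1] + dp[-length(dp)]) / 2 * diff(b)))
  list(b = b, dp = dp, pv = pv, c = 2 * a + 1, scale = gam)
}

neg_cache <- new.env(parent = emptyenv())

neg_table_cached <- function(rate, a) {
  key <- sprintf("%.12g_%.12g", rate, a)
  if (is.null(neg_cache[[key]])) neg_cache[[key]] <- neg_table(rate, a)
  neg_cache[[key]]
}

# Translate a penalty_spec into the list the C++ routines expect. For NEG
# the rate is baked into the tabulated values, so the C++ multiplier is 1.
as_cpp_penalty <- function(spec, p = NULL) {
  out <- list(family_code = family_code(spec$family),
              rate = spec$rate, shape = spec$shape,
              weights = NULL, neg_b = numeric(0), neg_dp = numeric(0),
              neg_pv = numeric(0), neg_c = 0)
  if (spec$family == "adaptive_lasso") {
    w <- spec$weights
    if (is.null(w)) stop("adaptive_lasso requires weights (see adaptive_weights())")
    if (!is.null(p)) {
      if (length(w) == 1L) w <- rep(w, p)
      if (length(w) != p) stop("weights length must match marker count")
    }
    out$weights <- as.numeric(w)
  }
  if (spec$family == "neg") {
    if (spec$rate > 0) {
      tab <- neg_table_cached(spec$rate, spec$shape)
      out$neg_b <- tab$b; out$neg_dp <- tab$dp; out$neg_pv <- tab$pv
      out$neg_c <- tab$c
    } else {
      out$neg_b <- c(0, 1); out$neg_dp <- c(0, 0); out$neg_pv <- c(0, 0)
      out$neg_c <- 0
    }
    out$rate <- 1.0
  }
  out
}

#' Evaluate a penalty function
#'
#' @param b non-negative coefficient magnitude(s).
#' @param spec a [penalty_spec()].
#' @param weight optional adaptive-lasso weight (scalar, default 1).
#' @return \eqn{P(b)} in log-likelihood units; vectorized over `b`.
#' @export
penalty_value <- function(b, spec, weight = 1) {
  if (any(b < 0)) stop("coefficient magnitude must be non-negative")
  pen <- as_cpp_penalty(spec)
  vapply(b, cpp_penalty_value, numeric(1), pen = pen, w = weight)
}

#' Derivative of a penalty function
#'
#' @inheritParams penalty_value
#' @return \eqn{P'(b)}; vectorized over `b`.
#' @export
penalty_deriv <- function(b, spec, weight = 1) {
  if (any(b < 0)) stop("coefficient magnitude must be non-negative")
  pen <- as_cpp_penalty(spec)
  vapply(b, cpp_penalty_deriv, numeric(1), pen = pen, w = weight)
}

#' Penalized univariate coordinate update
#'
#' Maximizes the MM quadratic surrogate
#' \eqn{-(d/2)(\beta - z)^2 - P(|\beta|)} over \eqn{\beta}, where `z` is
#' the unpenalized univariate optimum and `d` an upper bound on the
#' negative second derivative of the coordinate log-likelihood. For the
#' lasso this is soft thresholding, for MCP firm thresholding; the LOG and
#' NEG updates solve the stationarity condition and compare against the
#' exact zero.
#'
#' @param z unpenalized univariate optimum (any sign); vectorized.
#' @param d positive curvature bound.
#' @param spec a [penalty_spec()].
#' @param weight optional adaptive-lasso weight (scalar, default 1).
#' @return Updated coefficient(s), exactly zero below the family's
#'   threshold.
#' @export
coordinate_update <- function(z, d, spec, weight = 1) {
  if (any(d <= 0)) stop("curvature bound d must be positive")
  pen <- as_cpp_penalty(spec)
  if (length(d) == 1L) d <- rep(d, length(z))
  vapply(seq_along(z), function(i) cpp_cd_update(z[i], d[i], pen, weight),
         numeric(1))
}

#' Adaptive-lasso weights from an initial fit
#'
#' Weights the lasso penalty by the inverse square root of the initial
#' coefficient estimates, \eqn{w_j = 1/\sqrt{|\hat\beta_j|}}. Markers with
#' a zero initial estimate stay penalizable and receive the largest
#' assigned weight, \eqn{1/\sqrt{\min_{j: \hat\beta_j \ne 0} |\hat\beta_j|}}.
#'
#' @param beta_init numeric vector of first-stage (lasso) estimates.
#' @return Strictly positive weight vector of the same length.
#' @export
adaptive_weights <- function(beta_init) {
  ab <- abs(beta_init)
  nz <- ab[ab > 0]
  if (!length(nz)) {
    stop("all initial estimates are zero; relax the first-stage penalty")
  }
  w <- ifelse(ab > 0, 1 / sqrt(ab), 1 / sqrt(min(nz)))
  as.numeric(w)
}
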