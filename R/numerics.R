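# Numerical kernels: MVN rectangle probabilities, Gaussian quadrature,
# monotone root finding.  All inference and observer computations reduce
# to these three primitives.

.ratdecide_env <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights for E[f(X)], X ~ N(0,1):
# E[f(X)] = sum(w_i f(sqrt(2) x_i)) / sqrt(pi), memoized by order.
gh_rule <- function(n = 64L) {
  key <- paste0("gh", n)
  rule <- .ratdecide_env[[key]]
  if (is.null(rule)) {
    q <- statmod::gauss.quad(n, kind = "hermite")
    rule <- list(x = q$nodes * sqrt(2), w = q$weights / sqrt(pi))
    .ratdecide_env[[key]] <- rule
  }
  rule
}

#' Multivariate normal rectangle probability
#'
#' Probability that a multivariate normal vector falls in an axis-aligned
#' rectangle \eqn{\prod_j (l_j, u_j)}.  Dimensions 1-3 use exact
#' deterministic algorithms (closed form / Miwa recursion); higher
#' dimensions use the Genz-Bretz quasi-Monte-Carlo algorithm run under a
#' fixed internal seed, so repeated calls are bit-reproducible and do not
#' disturb the caller's random number stream.  Absolute accuracy is
#' better than 1e-6 up to the supported dimension (about 12).
#'
#' @param lower,upper Numeric vectors of rectangle bounds; `-Inf`/`Inf`
#'   allowed.  Must satisfy `lower < upper` elementwise.
#' @param mean Mean vector (default zero).
#' @param sigma Covariance matrix (symmetric PSD).
#' @return A single probability in \[0, 1\].
#' @examples
#' mvn_rectangle_probability(c(0, 0), c(Inf, Inf),
#'   sigma = matrix(c(1, 0.5, 0.5, 1), 2)) # 1/4 + asin(0.5)/(2*pi)
#' @export
mvn_rectangle_probability <- function(lower, upper, mean = rep(0, length(lower)),
                                      sigma) {
  d <- length(lower)
  if (length(upper) != d || length(mean) != d)
    stop("'lower', 'upper' and 'mean' must have equal length", call. = FALSE)
  if (!is.matrix(sigma) || nrow(sigma) != d || ncol(sigma) != d)
    stop("'sigma' must be a square matrix matching the bound dimension", call. = FALSE)
  if (any(lower >= upper))
    stop("'lower' must be strictly below 'upper' in every dimension", call. = FALSE)

  if (d == 1L) {
    s <- sqrt(sigma[1, 1])
    return(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s))
  }

  sd <- sqrt(diag(sigma))
  corr <- sigma / tcrossprod(sd)
  lo <- (lower - mean) / sd
  hi <- (upper - mean) / sd

  p <- if (d <= 4L) {
    res <- tryCatch(
      suppressWarnings(mvtnorm::pmvnorm(
        lower = lo, upper = hi, corr = corr,
        algorithm = mvtnorm::Miwa(steps = if (d <= 3L) 512L else 1024L)
      )[1]),
      error = function(e) NA_real_
    )
    if (is.na(res)) genz_prob(lo, hi, corr) else res
  } else {
    genz_prob(lo, hi, corr)
  }
  min(max(p, 0), 1)
}

# Genz-Bretz under a fixed internal seed; restores the caller's RNG state.
genz_prob <- function(lo, hi, corr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(180904L)
  mvtnorm::pmvnorm(
    lower = lo, upper = hi, corr = corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-7, maxpts = 1e5)
  )[1]
}

#' Expectation of a function under a Gaussian
#'
#' Computes \eqn{E[f(X)]} for \eqn{X \sim N(\mathrm{mean},\mathrm{sd}^2)}
#' by Gauss-Hermite quadrature after standardizing by the Gaussian
#' envelope.  Intended for smooth bounded-growth integrands such as
#' multivariate-normal rectangle factors times polynomials.
#'
#' @param f Function of a single numeric argument; need not be
#'   vectorized.
#' @param mean,sd Parameters of the Gaussian weight (sd > 0).
#' @param nodes Number of quadrature nodes (default 64).
#' @return The scalar expectation.
#' @examples
#' expectation_over_gaussian(function(u) u^2, mean = 0, sd = 2) # = 4
#' @export
expectation_over_gaussian <- function(f, mean, sd, nodes = 64L) {
  check_noise(sd, "sd")
  rule <- gh_rule(nodes)
  u <- mean + sd * rule$x
  fv <- vapply(u, f, numeric(1))
  if (any(!is.finite(fv)))
    stop("integrand returned non-finite values", call. = FALSE)
  sum(rule$w * fv)
}

#' Root of a strictly increasing function
#'
#' Finds the root of a strictly increasing scalar function by geometric
#' bracket expansion from \[-1, 1\] followed by Brent's method.  Used for
#' the critical-value equation, whose left side (the posterior expected
#' utility as a function of the private estimate) is strictly increasing.
#'
#' @param f Strictly increasing function of one numeric argument.
#' @param tol Absolute tolerance on the root location.
#' @return The root, a single number.
#' @examples
#' monotone_root(function(u) u - 1)
#' @export
monotone_root <- function(f, tol = 1e-8) {
  lo <- -1; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  while (flo > 0 || fhi < 0) {
    if (abs(lo) >= 50 || abs(hi) >= 50)
      stop("no sign change in [-50, 50]: function not monotone through zero or degenerate",
           call. = FALSE)
    if (flo > 0) { lo <- lo * 2; flo <- f(lo) }
    if (fhi < 0) { hi <- hi * 2; fhi <- f(hi) }
  }
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}
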