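# Agent-side Bayesian machinery.
#
# The focal agent k has prior U_k ~ N(0,1), private estimate
# Uhat_k = U_k + N(0, eps^2), and has observed the choices C_1..C_{k-1}.
# Its posterior over U_k is
#
#   p(U_k | Uhat_k, C_1..C_{k-1})
#     \propto phi(U_k) phi((Uhat_k - U_k)/eps) P(C_1..C_{k-1} | U_k)
#
# where the social likelihood P(history | U_k) is the probability that
# (Uhat_1, .., Uhat_{k-1}) fell in the rectangle determined by each
# previous agent's own critical value (above it for A, below for B),
# under the exact conditional law of the joint Gaussian given U_k.  The
# first two factors form a conjugate Gaussian envelope
# N(u/(1+eps^2), eps^2/(1+eps^2)); posterior moments are Gauss-Hermite
# sums of the social likelihood against that envelope.
#
# All conditional means/covariances are derived mechanically from the
# joint covariance (Schur complement), never hand-copied.

# posterior mean of U against envelope N(m0, s0^2) reweighted by L(U);
# evaluates L once per node.
posterior_mean_quad <- function(L, m0, s0, nodes = 64L) {
  rule <- gh_rule(nodes)
  u <- m0 + s0 * rule$x
  Lv <- vapply(u, L, numeric(1))
  den <- sum(rule$w * Lv)
  if (!is.finite(den) || den <= 0)
    stop("degenerate posterior: social likelihood vanished at all quadrature nodes",
         call. = FALSE)
  sum(rule$w * u * Lv) / den
}

# social likelihood for an undifferentiated group: P(history | U_k)
# as a function of U_k.  Previous agents' Uhat | U_k is MVN with mean
# rho * U_k and covariance (R + eps^2 I) - rho^2 J.
social_likelihood_hom <- function(model, signs) {
  m <- length(signs)
  rho <- model$rho; eps <- model$eps
  thr <- prefix_thresholds(model, signs)
  Suu <- matrix(rho, m, m)
  diag(Suu) <- 1 + eps^2
  cvec <- rep(rho, m)
  Sc <- Suu - tcrossprod(cvec)
  lo <- ifelse(signs > 0, thr, -Inf)
  hi <- ifelse(signs > 0, Inf, thr)
  function(U) mvn_rectangle_probability(lo, hi, mean = cvec * U, sigma = Sc)
}

# social likelihood for a cryptic-subtype population, marginalized over
# the type sequence s of previous deciders with weight
# gamma^{n_alpha} (1-gamma)^{n_beta}; the focal agent conditions on its
# own type only.
social_likelihood_subtype <- function(model, signs, focal_type) {
  m <- length(signs)
  eps <- model$eps; gamma <- model$gamma
  seqs <- type_sequences(m, gamma)
  terms <- lapply(seqs, function(ts) {
    R_full <- subtype_correlation_matrix(c(ts$types, focal_type),
                                         model$rho_high, model$rho_low)
    cvec <- R_full[seq_len(m), m + 1L]
    Suu <- R_full[seq_len(m), seq_len(m), drop = FALSE] + diag(eps^2, m)
    Sc <- Suu - tcrossprod(cvec)
    thr <- vapply(seq_len(m), function(j)
      thr_get(model, signs[seq_len(j - 1L)], ts$types[j]), numeric(1))
    list(w = ts$w, cvec = cvec, Sc = Sc,
         lo = ifelse(signs > 0, thr, -Inf),
         hi = ifelse(signs > 0, Inf, thr))
  })
  function(U) {
    s <- 0
    for (tm in terms)
      s <- s + tm$w * mvn_rectangle_probability(tm$lo, tm$hi,
                                                mean = tm$cvec * U,
                                                sigma = tm$Sc)
    s
  }
}

# enumerate type sequences of length m with their prior weights,
# dropping zero-weight sequences (gamma 0 or 1)
type_sequences <- function(m, gamma) {
  if (m == 0L) return(list(list(types = character(0), w = 1)))
  labs <- character(0)
  if (gamma > 0) labs <- c(labs, "alpha")
  if (gamma < 1) labs <- c(labs, "beta")
  g <- expand.grid(rep(list(labs), m), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    types <- as.character(g[i, ])
    na <- sum(types == "alpha")
    list(types = types, w = gamma^na * (1 - gamma)^(m - na))
  })
}

agent_posterior_mean <- function(model, u_hat, signs, focal_type = NULL) {
  eps <- model$eps
  m0 <- u_hat / (1 + eps^2)
  s0 <- eps / sqrt(1 + eps^2)
  m <- length(signs)
  if (m == 0L) return(m0)
  if (inherits(model, "subtype_decision_model")) {
    L <- social_likelihood_subtype(model, signs, focal_type)
  } else {
    # rho = 0: previous estimates are independent of U_k, the social
    # factor is exactly constant, posterior stays conjugate
    if (model$rho == 0) return(m0)
    L <- social_likelihood_hom(model, signs)
  }
  posterior_mean_quad(L, m0, s0)
}

# memoized critical value for the agent facing `signs`; mirrored
# histories are computed once and negated (exact antisymmetry)
thr_get <- function(model, signs, type = NULL) {
  if (length(signs) == 0L) return(0)
  key <- paste0(if (is.null(type)) "" else paste0(type, ":"),
                history_string(signs))
  val <- model$cache[[key]]
  if (!is.null(val)) return(val)
  val <- if (signs[1L] < 0) {
    -thr_get(model, -signs, type)
  } else {
    monotone_root(function(u) agent_posterior_mean(model, u, signs, type),
                  tol = 1e-8)
  }
  assign(key, val, envir = model$cache)
  val
}

prefix_thresholds <- function(model, signs, type = NULL) {
  vapply(seq_along(signs), function(j)
    thr_get(model, signs[seq_len(j - 1L)], type), numeric(1))
}

check_focal_type <- function(model, focal_type) {
  if (inherits(model, "subtype_decision_model")) {
    if (is.null(focal_type) || !focal_type %in% c("alpha", "beta"))
      stop("'focal_type' must be \"alpha\" or \"beta\" for subtype models",
           call. = FALSE)
  }
  invisible(focal_type)
}

check_history_length <- function(model, signs) {
  if (length(signs) > model$n_agents - 1L)
    stop(sprintf(
      "history of length %d cannot condition a further decision in a group of %d agents",
      length(signs), model$n_agents), call. = FALSE)
  invisible(signs)
}

#' Posterior expected utility given private estimate and observed choices
#'
#' The focal agent's posterior mean \eqn{E(U_k \mid \hat U_k = u,
#' C_1 \ldots C_{k-1})}: its best estimate of the utility difference
#' between options A and B after combining prior, private estimate and
#' the social information carried by the observed choice sequence.
#' Strictly increasing in `u_hat`, which makes the critical value
#' ([critical_value()]) the unique zero crossing.
#'
#' @param model A [decision_model()] or [subtype_decision_model()].
#' @param u_hat Private utility estimate(s), numeric vector.
#' @param history Observed choice history, e.g. `"AAB"` (chronological,
#'   most recent last); `""` for the first decider.
#' @param focal_type For subtype models, the focal agent's own type
#'   (`"alpha"` or `"beta"`).
#' @return Numeric vector of posterior means, one per `u_hat`.
#' @examples
#' m <- decision_model(3, rho = 0.9, eps = 1)
#' posterior_mean(m, u_hat = 0, history = "A") # pulled above 0 by the A
#' @export
posterior_mean <- function(model, u_hat, history = "", focal_type = NULL) {
  stopifnot(inherits(model, "decision_model"), is.numeric(u_hat))
  signs <- parse_history(history)
  check_history_length(model, signs)
  check_focal_type(model, focal_type)
  vapply(u_hat, function(u) agent_posterior_mean(model, u, signs, focal_type),
         numeric(1))
}

#' Critical value of the private estimate
#'
#' The threshold \eqn{\hat U^*} at which the focal agent's posterior
#' expected utility is zero given the observed history: the agent
#' chooses A exactly when its private estimate strictly exceeds this
#' value.  The first decider's threshold is exactly 0; a history
#' favouring A drives the threshold negative (for positively correlated
#' preferences), and mirrored histories have thresholds of opposite sign
#' and equal magnitude.
#'
#' @inheritParams posterior_mean
#' @param history One or more history strings (vectorized).
#' @return Numeric vector of critical values, named by history.
#' @examples
#' m <- decision_model(3, rho = 0.9, eps = 1)
#' critical_value(m, c("", "A", "B"))
#' @export
critical_value <- function(model, history, focal_type = NULL) {
  stopifnot(inherits(model, "decision_model"))
  check_focal_type(model, focal_type)
  history <- as.character(history)
  out <- vapply(history, function(h) {
    signs <- parse_history(h)
    check_history_length(model, signs)
    thr_get(model, signs, focal_type)
  }, numeric(1))
  names(out) <- history
  out
}

#' Build the full table of critical values
#'
#' Forces computation of the critical value for every history up to
#' `max_len` choices (all \eqn{2^0 + 2^1 + \cdots + 2^{max\_len}}
#' histories), in prefix order, and returns them as a named vector.  For
#' subtype models the table is computed for both focal types, with names
#' `"alpha:AAB"` etc.
#'
#' @inheritParams posterior_mean
#' @param max_len Longest history to tabulate; defaults to
#'   `n_agents - 1` (everything a member of the group can face).
#' @return Named numeric vector of thresholds; the empty history is
#'   named `""` (or `"alpha:"`, `"beta:"`).
#' @examples
#' m <- decision_model(3, rho = 0.9, eps = 1)
#' build_threshold_table(m)
#' @export
build_threshold_table <- function(model, max_len = model$n_agents - 1L) {
  stopifnot(inherits(model, "decision_model"))
  max_len <- max(0L, min(max_len, model$n_agents - 1L))
  hs <- c("", if (max_len >= 1L) all_histories(max_len))
  if (inherits(model, "subtype_decision_model")) {
    out <- c(
      stats::setNames(critical_value(model, hs, "alpha"), paste0("alpha:", hs)),
      stats::setNames(critical_value(model, hs, "beta"), paste0("beta:", hs))
    )
  } else {
    out <- critical_value(model, hs)
  }
  out
}

#' Currently cached critical values
#'
#' @param model A decision model.
#' @return Named numeric vector of thresholds computed so far (keys as
#'   in [build_threshold_table()]).
#' @export
thresholds <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  keys <- ls(model$cache)
  out <- vapply(keys, function(k) model$cache[[k]], numeric(1))
  out[order(nchar(keys), keys)]
}
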