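# Observer-side quantities.  The observer watches the group under the
# experimental noise level eta, while agents keep applying thresholds
# calibrated to the habitual noise eps.  Every sequence probability is a
# single MVN rectangle probability of (Uhat_1..Uhat_m) under the
# observer's generative joint -- covariance rho + delta (1 + eta^2 - rho)
# -- with each coordinate bounded at that agent's own threshold, above
# it if the agent chose A, below if B.

#' Probability of an observed choice sequence
#'
#' Marginal probability, from the external observer's viewpoint, that
#' the first \eqn{m} deciders produce the given ordered choice sequence.
#' Computed as one multivariate-normal rectangle probability under the
#' observer's generative model (experimental noise `eta`), with bounds
#' at the `eps`-calibrated critical values.  For subtype models the
#' probability additionally marginalizes the (cryptic) types of the
#' deciders with prior weights \eqn{\gamma^{n_\alpha}(1-\gamma)^{n_\beta}}.
#'
#' @inheritParams posterior_mean
#' @param history Choice sequence, e.g. `"BBA"`; may be a vector.
#' @return Numeric vector of probabilities.
#' @examples
#' m <- decision_model(4, rho = 0.9, eps = 1)
#' sum(sequence_probability(m, c("AA", "AB", "BA", "BB"))) # partitions to 1
#' @export
sequence_probability <- function(model, history) {
  stopifnot(inherits(model, "decision_model"))
  history <- as.character(history)
  out <- vapply(history, function(h) {
    signs <- parse_history(h)
    if (length(signs) > model$n_agents)
      stop("sequence longer than the group", call. = FALSE)
    seq_prob_signs(model, signs)
  }, numeric(1))
  names(out) <- history
  out
}

seq_prob_signs <- function(model, signs) {
  m <- length(signs)
  if (m == 0L) return(1)
  if (inherits(model, "subtype_decision_model")) {
    seqs <- type_sequences(m, model$gamma)
    p <- 0
    for (ts in seqs) {
      R <- subtype_correlation_matrix(ts$types, model$rho_high, model$rho_low)
      thr <- vapply(seq_len(m), function(j)
        thr_get(model, signs[seq_len(j - 1L)], ts$types[j]), numeric(1))
      p <- p + ts$w * mvn_rectangle_probability(
        ifelse(signs > 0, thr, -Inf), ifelse(signs > 0, Inf, thr),
        sigma = R + diag(model$eta^2, m)
      )
    }
    p
  } else {
    thr <- prefix_thresholds(model, signs)
    Sig <- matrix(model$rho, m, m)
    diag(Sig) <- 1 + model$eta^2
    mvn_rectangle_probability(
      ifelse(signs > 0, thr, -Inf), ifelse(signs > 0, Inf, thr),
      sigma = Sig
    )
  }
}

#' Conditional probability that the next decider chooses A
#'
#' Observer-side probability that the next agent chooses option A given
#' the observed history, computed as the ratio of two sequence
#' probabilities \eqn{P(h, A)/P(h)}.  For subtype models the focal
#' agent's own type must be given; previous deciders' types are
#' marginalized in both the thresholds and the generative joint.
#'
#' @inheritParams sequence_probability
#' @param focal_type For subtype models: `"alpha"` or `"beta"`.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' m <- decision_model(4, rho = 0.9, eps = 1)
#' conditional_choice_probability(m, "BBA")
#' @export
conditional_choice_probability <- function(model, history, focal_type = NULL) {
  stopifnot(inherits(model, "decision_model"))
  check_focal_type(model, focal_type)
  history <- as.character(history)
  out <- vapply(history, function(h) {
    signs <- parse_history(h)
    check_history_length(model, signs)
    m <- length(signs)
    if (inherits(model, "subtype_decision_model")) {
      num <- cond_joint_prob_subtype(model, signs, focal_type)
      den <- if (m == 0L) 1 else seq_prob_signs(model, signs)
    } else {
      num <- seq_prob_signs(model, c(signs, 1L))
      den <- if (m == 0L) 1 else seq_prob_signs(model, signs)
    }
    if (den < 1e-12)
      stop(sprintf("history '%s' has probability below 1e-12; conditional undefined", h),
           call. = FALSE)
    num / den
  }, numeric(1))
  names(out) <- history
  out
}

# P(history, next = A | focal type): joint over the m previous deciders
# (types marginalized) and the focal agent of known type.
cond_joint_prob_subtype <- function(model, signs, focal_type) {
  m <- length(signs)
  thr_f <- thr_get(model, signs, focal_type)
  if (m == 0L)
    return(stats::pnorm(thr_f, sd = sqrt(1 + model$eta^2), lower.tail = FALSE))
  seqs <- type_sequences(m, model$gamma)
  p <- 0
  for (ts in seqs) {
    R <- subtype_correlation_matrix(c(ts$types, focal_type),
                                    model$rho_high, model$rho_low)
    thr <- c(
      vapply(seq_len(m), function(j)
        thr_get(model, signs[seq_len(j - 1L)], ts$types[j]), numeric(1)),
      thr_f
    )
    sgn <- c(signs, 1L)
    p <- p + ts$w * mvn_rectangle_probability(
      ifelse(sgn > 0, thr, -Inf), ifelse(sgn > 0, Inf, thr),
      sigma = R + diag(model$eta^2, m + 1L)
    )
  }
  p
}

#' Social response curve of the focal agent
#'
#' The probability that a focal agent chooses option A when *presented*
#' with a given choice history as a stimulus, with its private estimate
#' drawn from its unconditional distribution \eqn{N(0, 1 + \eta^2)}:
#' \deqn{P(A \mid h) = \Phi\!\left(-\hat U^*(h) / \sqrt{1 + \eta^2}\right).}
#' This is the quantity an experimenter measures by manipulating the
#' apparent choices of others (e.g. with replica conspecifics) and is
#' the one plotted in figure-style sweeps.  It differs from
#' [conditional_choice_probability()], the conditional frequency in
#' freely deciding groups, where the observed history additionally
#' carries information about the correlated utilities: the response
#' curve returns exactly to 1/2 as the habitual noise (hence the
#' threshold) vanishes, and its \eqn{P = 1/2} contour (threshold zero)
#' does not depend on the experimental noise at all.
#'
#' @inheritParams conditional_choice_probability
#' @return Numeric vector of probabilities.
#' @examples
#' m <- decision_model(4, rho = 0.5, eps = 0.05)
#' response_probability(m, "BBA") # ~0.5: negligible social influence
#' @export
response_probability <- function(model, history, focal_type = NULL) {
  stopifnot(inherits(model, "decision_model"))
  check_focal_type(model, focal_type)
  history <- as.character(history)
  s <- sqrt(1 + model$eta^2)
  out <- vapply(history, function(h) {
    signs <- parse_history(h)
    check_history_length(model, signs)
    stats::pnorm(-thr_get(model, signs, focal_type) / s)
  }, numeric(1))
  names(out) <- history
  out
}

#' @rdname conditional_choice_probability
#' @param object A decision model.
#' @param type `"response"` for the social response curve
#'   ([response_probability()], the figure-style quantity), or
#'   `"conditional"` for the generative conditional frequency.
#' @param ... Unused.
#' @export
predict.decision_model <- function(object, history = "", focal_type = NULL,
                                   type = c("response", "conditional"), ...) {
  type <- match.arg(type)
  switch(type,
    response = response_probability(object, history, focal_type),
    conditional = conditional_choice_probability(object, history, focal_type)
  )
}

#' Relative social weighting
#'
#' The ratio of the weight a rational second decider puts on the first
#' decision to the weight it puts on its own private information,
#' \deqn{RSW = \frac{\rho\epsilon}{\sqrt{1 + \epsilon^2 - \rho^2}}.}
#' Equal to 1 for identical preferences (\eqn{\rho = 1}), 0 for
#' uncorrelated preferences, close to 0 when private information is
#' reliable (\eqn{\epsilon \ll 1}), and close to \eqn{\rho} when it is
#' not (\eqn{\epsilon \gg 1}).
#'
#' @param rho Preference correlation(s), \eqn{|\rho| \le 1}.
#' @param eps Habitual environmental noise level(s), > 0.
#' @return Numeric vector of RSW values in \[-1, 1\].
#' @examples
#' rsw(1, 0.7)   # 1
#' rsw(0.5, 100) # ~0.5
#' @export
rsw <- function(rho, eps) {
  if (any(abs(rho) > 1)) stop("|rho| must not exceed 1", call. = FALSE)
  d <- 1 + eps^2 - rho^2
  if (any(d <= 0))
    stop("degenerate denominator: 1 + eps^2 - rho^2 must be positive", call. = FALSE)
  rho * eps / sqrt(d)
}

#' Consensus score of a collective outcome
#'
#' \eqn{|n_A - n_B| / (n_A + n_B)}: 1 when all individuals chose the
#' same option, 0 for an equal split.
#'
#' @param n_a,n_b Non-negative counts of individuals choosing A and B.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' consensus_score(8, 0) # 1
#' consensus_score(4, 4) # 0
#' @export
consensus_score <- function(n_a, n_b) {
  if (any(n_a < 0 | n_b < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(n_a + n_b == 0)) stop("empty group: n_a + n_b must be positive", call. = FALSE)
  abs(n_a - n_b) / (n_a + n_b)
}

#' Exact distribution of collective outcomes
#'
#' Enumerates all \eqn{2^N} ordered choice sequences of the full group,
#' computes each sequence's observer-side probability, and sums them by
#' the final count \eqn{n_A} of individuals choosing A.  Restricted to
#' groups of at most 10 (exhaustive enumeration).
#'
#' @inheritParams posterior_mean
#' @return An object of class `"outcome_distribution"`: a data frame
#'   with columns `n_A`, `n_B`, `probability` and `consensus`, with the
#'   model parameters attached as attributes.  Use
#'   [expected_consensus()] for the probability-weighted mean consensus
#'   score.
#' @examples
#' m <- decision_model(4, rho = 0, eps = 1)
#' outcome_distribution(m) # Binomial(4, 1/2)
#' @export
outcome_distribution <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  if (inherits(model, "subtype_decision_model"))
    stop("outcome enumeration is implemented for undifferentiated groups only",
         call. = FALSE)
  n <- model$n_agents
  if (n > 10L)
    stop("group too large for exhaustive enumeration (n_agents <= 10)", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  prob <- numeric(n + 1L) # index n_A + 1
  for (i in seq_len(nrow(grid))) {
    signs <- grid[i, ]
    na <- sum(signs > 0)
    prob[na + 1L] <- prob[na + 1L] + seq_prob_signs(model, signs)
  }
  out <- data.frame(
    n_A = 0:n, n_B = n:0,
    probability = prob,
    consensus = consensus_score(0:n, n:0)
  )
  attr(out, "params") <- coef(model)
  class(out) <- c("outcome_distribution", "data.frame")
  out
}

#' Expected consensus score
#'
#' @param x An [outcome_distribution()].
#' @return The probability-weighted mean consensus score.
#' @export
expected_consensus <- function(x) {
  stopifnot(inherits(x, "outcome_distribution"))
  sum(x$probability * x$consensus)
}

#' @export
print.outcome_distribution <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Collective outcome distribution (N = %d, rho = %g, eps = %g, eta = %g)\n",
              p["n_agents"], p["rho"], p["eps"], p["eta"]))
  print.data.frame(cbind(x[, c("n_A", "n_B")],
                         probability = signif(x$probability, 6),
                         consensus = round(x$consensus, 4)),
                   row.names = FALSE)
  cat(sprintf("Expected consensus: %.6f   (total probability %.6f)\n",
              expected_consensus(x), sum(x$probability)))
  invisible(x)
}
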