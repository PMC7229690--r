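#' Rational sequential decision model for an undifferentiated group
#'
#' Constructs the model object for a group of `n_agents` rational agents
#' choosing sequentially between two options A and B.  Each agent's
#' utility difference \eqn{U_k} is standard normal a priori, pairwise
#' correlated at `rho` across agents; the agent observes a private
#' estimate \eqn{\hat U_k = U_k + } noise of scale `eps` (the habitual
#' environmental noise its decision rule is calibrated to) and the
#' ordered choices of all previous deciders, and chooses A exactly when
#' \eqn{\hat U_k} exceeds a history-dependent critical value.  An
#' external observer records behaviour under the experimental noise
#' `eta`, which may differ from `eps` (laboratory conditions); agents
#' keep applying the `eps`-calibrated rule regardless.
#'
#' Critical values are computed on demand by recursive Bayesian inference
#' and memoized inside the object; [build_threshold_table()] forces the
#' whole table.
#'
#' @param n_agents Group size N (positive integer).
#' @param rho Preference correlation in \eqn{[-1/(N-1), 1]}.
#' @param eps Habitual environmental noise \eqn{\epsilon > 0}
#'   (noise-to-signal, utility units).
#' @param eta Experimental noise \eqn{\eta > 0}; defaults to `eps`
#'   (natural conditions).
#' @return An object of class `"decision_model"`.
#' @seealso [predict.decision_model()], [critical_value()],
#'   [simulate.decision_model()], [outcome_distribution()]
#' @examples
#' m <- decision_model(4, rho = 0.9, eps = 1)
#' predict(m, c("A", "AB", "BBA"))
#' @export
decision_model <- function(n_agents, rho, eps, eta = eps) {
  n_agents <- check_n_agents(n_agents)
  check_rho(rho, n_agents)
  check_noise(eps, "eps")
  check_noise(eta, "eta")
  structure(
    list(n_agents = n_agents, rho = rho, eps = eps, eta = eta,
         cache = new.env(parent = emptyenv())),
    class = "decision_model"
  )
}

#' Rational sequential decision model with two cryptic preference subtypes
#'
#' As [decision_model()], but the population consists of two preference
#' types, alpha (frequency `gamma`) and beta: utilities of same-type
#' agents correlate at `rho_high`, different-type agents at `rho_low`.
#' Types are cryptic: an agent knows its own type and the population
#' frequencies, but can infer others' types only from their choices, so
#' every posterior marginalizes over the possible type sequences of the
#' previous deciders with prior weight
#' \eqn{\gamma^{n_\alpha}(1-\gamma)^{n_\beta}}.
#'
#' @inheritParams decision_model
#' @param gamma Proportion of type alpha in the population, in \[0, 1\].
#' @param rho_high Within-type utility correlation.
#' @param rho_low Between-type utility correlation.
#' @return An object of class `c("subtype_decision_model",
#'   "decision_model")`.
#' @examples
#' m <- subtype_decision_model(4, gamma = 0.5, rho_high = 1, rho_low = 0,
#'                             eps = 0.25)
#' predict(m, "AAA", focal_type = "alpha")
#' @export
subtype_decision_model <- function(n_agents, gamma, rho_high, rho_low,
                                   eps, eta = eps) {
  n_agents <- check_n_agents(n_agents)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("'gamma' must be a single number in [0, 1]", call. = FALSE)
  check_noise(eps, "eps")
  check_noise(eta, "eta")
  # every type assignment must give a PSD correlation matrix; up to
  # permutation these are indexed by the count of alpha agents
  for (na in 0:n_agents) {
    types <- rep(c("alpha", "beta"), c(na, n_agents - na))
    subtype_correlation_matrix(types, rho_high, rho_low)
  }
  structure(
    list(n_agents = n_agents, gamma = gamma,
         rho_high = rho_high, rho_low = rho_low,
         eps = eps, eta = eta,
         cache = new.env(parent = emptyenv())),
    class = c("subtype_decision_model", "decision_model")
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat("Rational sequential decision model\n")
  cat(sprintf("  agents: %d   rho = %g   eps = %g   eta = %g%s\n",
              x$n_agents, x$rho, x$eps, x$eta,
              if (x$eta == x$eps) " (natural conditions)" else ""))
  cat(sprintf("  relative social weighting (RSW): %.4f\n", rsw(x$rho, x$eps)))
  cat(sprintf("  cached thresholds: %d\n", length(ls(x$cache))))
  invisible(x)
}

#' @export
print.subtype_decision_model <- function(x, ...) {
  cat("Rational sequential decision model with cryptic subtypes\n")
  cat(sprintf("  agents: %d   gamma = %g   rho_high = %g   rho_low = %g\n",
              x$n_agents, x$gamma, x$rho_high, x$rho_low))
  cat(sprintf("  eps = %g   eta = %g%s\n", x$eps, x$eta,
              if (x$eta == x$eps) " (natural conditions)" else ""))
  cat(sprintf("  cached thresholds: %d\n", length(ls(x$cache))))
  invisible(x)
}

#' @export
coef.decision_model <- function(object, ...) {
  c(n_agents = object$n_agents, rho = object$rho,
    eps = object$eps, eta = object$eta)
}

#' @export
coef.subtype_decision_model <- function(object, ...) {
  c(n_agents = object$n_agents, gamma = object$gamma,
    rho_high = object$rho_high, rho_low = object$rho_low,
    eps = object$eps, eta = object$eta)
}

#' @export
summary.decision_model <- function(object, max_len = min(object$n_agents - 1L, 3L), ...) {
  h <- all_histories(max_len)
  out <- list(
    model = object,
    thresholds = vapply(h, function(s) critical_value(object, s), numeric(1)),
    p_a = stats::setNames(predict(object, h), h),
    rsw = rsw(object$rho, object$eps)
  )
  class(out) <- "summary.decision_model"
  out
}

#' @export
summary.subtype_decision_model <- function(object,
                                           max_len = min(object$n_agents - 1L, 3L),
                                           ...) {
  h <- all_histories(max_len)
  both <- lapply(c(alpha = "alpha", beta = "beta"), function(ft) {
    list(thr = vapply(h, function(s) critical_value(object, s, ft), numeric(1)),
         p_a = stats::setNames(predict(object, h, focal_type = ft), h))
  })
  out <- list(model = object,
              thresholds = cbind(alpha = both$alpha$thr, beta = both$beta$thr),
              p_a = cbind(alpha = both$alpha$p_a, beta = both$beta$p_a))
  class(out) <- "summary.subtype_decision_model"
  out
}

#' @export
print.summary.subtype_decision_model <- function(x, ...) {
  print(x$model)
  df <- data.frame(history = rownames(x$thresholds),
                   thr_alpha = round(x$thresholds[, "alpha"], 4),
                   thr_beta = round(x$thresholds[, "beta"], 4),
                   p_A_alpha = round(x$p_a[, "alpha"], 4),
                   p_A_beta = round(x$p_a[, "beta"], 4), row.names = NULL)
  cat("\nCritical values and next-choice probabilities by focal type:\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.summary.decision_model <- function(x, ...) {
  print(x$model)
  df <- data.frame(history = names(x$p_a),
                   threshold = round(x$thresholds, 4),
                   p_choose_A = round(x$p_a, 4), row.names = NULL)
  cat("\nCritical values and next-choice probabilities by observed history:\n")
  print(df, row.names = FALSE)
  invisible(x)
}
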