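#' Utility correlation matrix for an undifferentiated population
#'
#' Builds the N x N prior correlation matrix of the agents' utility
#' differences \eqn{U_1, \ldots, U_N}.  Every utility has unit prior
#' variance (the utility scale is fixed to one), and every pair of agents
#' shares the same preference correlation \eqn{\rho}.
#'
#' A homogeneous negative correlation is only possible in small groups:
#' positive semidefiniteness requires \eqn{\rho \ge -1/(N-1)}, so values
#' below zero are admissible only for pairs (and, weakly, small N).
#'
#' @param n_agents Number of agents (positive integer).
#' @param rho Preference correlation, a single number in
#'   \eqn{[-1/(N-1), 1]}.
#' @return An `n_agents` x `n_agents` symmetric PSD matrix with unit
#'   diagonal.
#' @seealso [subtype_correlation_matrix()], [joint_covariance()]
#' @examples
#' utility_correlation_matrix(3, 0.5)
#' @export
utility_correlation_matrix <- function(n_agents, rho) {
  n_agents <- check_n_agents(n_agents)
  check_rho(rho, n_agents)
  R <- matrix(rho, n_agents, n_agents)
  diag(R) <- 1
  R
}

#' Utility correlation matrix for a two-type population
#'
#' Builds the utility correlation matrix implied by an assignment of
#' agents to two preference types: agents of the same type are correlated
#' at `rho_high`, agents of different types at `rho_low`.
#'
#' @param types Character vector of type labels, one per agent; exactly
#'   two distinct labels are meaningful (canonically `"alpha"` and
#'   `"beta"`).
#' @param rho_high Within-type utility correlation.
#' @param rho_low Between-type utility correlation.
#' @return A symmetric PSD matrix with unit diagonal.
#' @examples
#' subtype_correlation_matrix(c("alpha", "beta", "alpha"), 0.9, 0.25)
#' @export
subtype_correlation_matrix <- function(types, rho_high, rho_low) {
  stopifnot(length(types) >= 1L, is.numeric(rho_high), is.numeric(rho_low))
  same <- outer(types, types, "==")
  R <- ifelse(same, rho_high, rho_low)
  diag(R) <- 1
  check_psd(R, sprintf(
    "correlation matrix for types (%s) with rho_high = %g, rho_low = %g is not positive semidefinite",
    paste(types, collapse = ","), rho_high, rho_low
  ))
  R
}

#' Joint covariance of true and privately estimated utilities
#'
#' Returns the 2N x 2N covariance matrix of
#' \eqn{(U_1, \ldots, U_N, \hat U_1, \ldots, \hat U_N)}, where
#' \eqn{\hat U_k = U_k + } independent Gaussian noise of standard
#' deviation `noise`.  The blocks are
#' \deqn{\mathrm{cov}(U_k, U_l) = \mathrm{cov}(\hat U_k, U_l)
#'   = \rho_{k,l} + \delta_{k,l}(1 - \rho_{k,l}),}
#' \deqn{\mathrm{cov}(\hat U_k, \hat U_l)
#'   = \rho_{k,l} + \delta_{k,l}(1 + \mathrm{noise}^2 - \rho_{k,l}).}
#' Pass the habitual noise \eqn{\epsilon} for the agents' internal model,
#' or the experimental noise \eqn{\eta} for the observer's generative
#' model.
#'
#' @param n_agents Number of agents, or `NULL` when `corr` is supplied.
#' @param rho Homogeneous preference correlation (ignored when `corr`
#'   is supplied).
#' @param noise Noise-to-signal ratio (> 0), in utility units.
#' @param corr Optional explicit utility correlation matrix (e.g. from
#'   [subtype_correlation_matrix()]), overriding `n_agents`/`rho`.
#' @return A 2N x 2N symmetric PSD matrix; rows/cols 1..N are the true
#'   utilities, rows/cols N+1..2N the private estimates.
#' @examples
#' joint_covariance(2, rho = 0.5, noise = 1)
#' @export
joint_covariance <- function(n_agents = NULL, rho = NULL, noise, corr = NULL) {
  if (!is.numeric(noise) || length(noise) != 1L || !is.finite(noise) || noise <= 0)
    stop("'noise' must be a single positive number", call. = FALSE)
  R <- if (is.null(corr)) utility_correlation_matrix(n_agents, rho) else corr
  n <- nrow(R)
  rbind(
    cbind(R, R),
    cbind(R, R + diag(noise^2, n))
  )
}

## ---- validation helpers (internal) ----

check_n_agents <- function(n_agents) {
  if (!is.numeric(n_agents) || length(n_agents) != 1L ||
      n_agents < 1 || n_agents != round(n_agents))
    stop("'n_agents' must be a single positive integer", call. = FALSE)
  as.integer(n_agents)
}

check_rho <- function(rho, n_agents) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho))
    stop("'rho' must be a single finite number", call. = FALSE)
  if (rho > 1)
    stop("'rho' must not exceed 1", call. = FALSE)
  lb <- if (n_agents >= 2L) -1 / (n_agents - 1L) else -1
  if (rho < lb - 1e-12)
    stop(sprintf(
      "rho = %g violates positive semidefiniteness for %d agents: need rho >= -1/(n_agents - 1) = %g",
      rho, n_agents, lb
    ), call. = FALSE)
  invisible(rho)
}

check_noise <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_psd <- function(M, msg, tol = 1e-10) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(msg, call. = FALSE)
  invisible(M)
}
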