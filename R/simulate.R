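# Generative Monte-Carlo simulator.  Serves as the brute-force oracle
# for every exact quantity: simulated choice frequencies must agree with
# the observer-side rectangle probabilities, and rejection-sampled
# posterior means with the quadrature posterior means, within
# Monte-Carlo error.

# PSD matrix square root (handles rho = 1 and other singular cases)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

draw_mvn <- function(n, S) {
  d <- nrow(S)
  matrix(stats::rnorm(n * d), n, d) %*% t(psd_sqrt(S))
}

# sequential threshold rule applied to a matrix of private estimates;
# types NULL for homogeneous models, else a character matrix of
# "alpha"/"beta" aligned with uhat
apply_decision_rule <- function(model, uhat, types = NULL) {
  n <- nrow(uhat); N <- ncol(uhat)
  hist_str <- character(n)
  choices <- matrix("B", n, N)
  for (k in seq_len(N)) {
    if (is.null(types)) {
      keys <- hist_str
      thr_of <- function(h) thr_get(model, parse_history(h))
    } else {
      keys <- paste(types[, k], hist_str, sep = ":")
      thr_of <- function(key) {
        sp <- strsplit(key, ":", fixed = TRUE)[[1]]
        thr_get(model, parse_history(if (length(sp) > 1L) sp[2L] else ""), sp[1L])
      }
    }
    uk <- unique(keys)
    thr <- vapply(uk, thr_of, numeric(1))
    a <- uhat[, k] > thr[match(keys, uk)] # tie resolved as B: strict ineq. for A
    choices[a, k] <- "A"
    hist_str <- paste0(hist_str, choices[, k])
  }
  hist_str
}

#' Simulate sequential group decisions
#'
#' Draws replicate groups from the generative model -- true utilities
#' from the multivariate normal prior, private estimates by adding
#' independent noise of scale `eta` (the experimental noise actually
#' governing behaviour) -- and applies the sequential threshold rule,
#' in which each agent compares its private estimate against the
#' `eps`-calibrated critical value for the history it has observed.
#'
#' @param object A [decision_model()] or [subtype_decision_model()].
#' @param nsim Number of replicate groups.
#' @param seed Integer seed; if supplied the simulation is
#'   bit-reproducible.
#' @param ... Unused.
#' @return A data frame with one row per replicate: column `sequence`
#'   (the full choice string, chronological) and, for subtype models,
#'   `types` (string of `a`/`b`, one letter per agent).
#' @examples
#' m <- decision_model(2, rho = 0, eps = 1)
#' sim <- simulate(m, nsim = 1000, seed = 1)
#' mean(sim$sequence == "AA") # ~0.25
#' @export
simulate.decision_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$n_agents
  R <- utility_correlation_matrix(N, object$rho)
  U <- draw_mvn(nsim, R)
  uhat <- U + object$eta * matrix(stats::rnorm(nsim * N), nsim, N)
  out <- data.frame(sequence = apply_decision_rule(object, uhat))
  attr(out, "seed") <- seed
  out
}

#' @rdname simulate.decision_model
#' @export
simulate.subtype_decision_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$n_agents
  types <- matrix(ifelse(stats::runif(nsim * N) < object$gamma, "alpha", "beta"),
                  nsim, N)
  pat <- apply(types, 1L, paste, collapse = ",")
  uhat <- matrix(NA_real_, nsim, N)
  for (p in unique(pat)) {
    idx <- which(pat == p)
    ty <- strsplit(p, ",", fixed = TRUE)[[1]]
    R <- subtype_correlation_matrix(ty, object$rho_high, object$rho_low)
    U <- draw_mvn(length(idx), R)
    uhat[idx, ] <- U + object$eta * matrix(stats::rnorm(length(idx) * N),
                                           length(idx), N)
  }
  out <- data.frame(
    sequence = apply_decision_rule(object, uhat, types),
    types = apply(types, 1L, function(t) paste(substr(t, 1L, 1L), collapse = ""))
  )
  attr(out, "seed") <- seed
  out
}

#' Monte-Carlo conditional choice probability
#'
#' Empirical estimate of \eqn{P(\mathrm{next} = A \mid \mathrm{history})}
#' from a simulation run: replicates whose first \eqn{m} choices match
#' the history are retained and the fraction in which the next agent
#' chose A is returned with its binomial standard error.  The oracle
#' counterpart of [conditional_choice_probability()].
#'
#' @inheritParams posterior_mean
#' @param nreps Number of simulated groups.
#' @param seed Integer seed.
#' @param sim Optionally, a precomputed result of `simulate()` to reuse
#'   across histories.
#' @return A list with `estimate`, `se` and `n` (matching replicates).
#' @export
mc_conditional_probability <- function(model, history, nreps = 1e5, seed = NULL,
                                       focal_type = NULL, sim = NULL) {
  check_focal_type(model, focal_type)
  signs <- parse_history(history)
  check_history_length(model, signs)
  m <- length(signs)
  if (is.null(sim)) sim <- simulate(model, nsim = nreps, seed = seed)
  keep <- substr(sim$sequence, 1L, m) == history_string(signs)
  if (!is.null(focal_type))
    keep <- keep & substr(sim$types, m + 1L, m + 1L) == substr(focal_type, 1L, 1L)
  n <- sum(keep)
  if (n == 0L) return(list(estimate = NA_real_, se = NA_real_, n = 0L))
  p <- mean(substr(sim$sequence[keep], m + 1L, m + 1L) == "A")
  list(estimate = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Rejection-sampling posterior mean (oracle)
#'
#' Brute-force check of [posterior_mean()]: samples
#' \eqn{(U_k, \hat U_1, \ldots, \hat U_k)} from the agents' joint model
#' (habitual noise `eps` throughout), keeps draws in which every
#' previous estimate falls on the side of its threshold dictated by the
#' history and the focal estimate lies within `delta` of `u_hat`, and
#' averages the retained \eqn{U_k}.
#'
#' @inheritParams posterior_mean
#' @param delta Half-width of the acceptance window around `u_hat`.
#' @param nreps Number of proposal draws.
#' @param seed Integer seed.
#' @return A list with `estimate`, `se` (standard error of the mean)
#'   and `n` (accepted draws).
#' @export
mc_posterior_mean <- function(model, u_hat, history = "", delta = 0.05,
                              nreps = 1e6, seed = NULL, focal_type = NULL) {
  check_focal_type(model, focal_type)
  if (!is.null(seed)) set.seed(seed)
  signs <- parse_history(history)
  check_history_length(model, signs)
  m <- length(signs)
  k <- m + 1L
  eps <- model$eps
  subtype <- inherits(model, "subtype_decision_model")

  if (subtype) {
    prev <- matrix(ifelse(stats::runif(nreps * m) < model$gamma, "alpha", "beta"),
                   nreps, m)
    pat <- if (m > 0L) apply(prev, 1L, paste, collapse = ",") else rep("", nreps)
  } else {
    pat <- rep("", nreps)
  }
  U_k <- numeric(nreps); ok <- logical(nreps)
  for (p in unique(pat)) {
    idx <- which(pat == p)
    if (subtype) {
      ty <- if (nzchar(p)) strsplit(p, ",", fixed = TRUE)[[1]] else character(0)
      R <- subtype_correlation_matrix(c(ty, focal_type),
                                      model$rho_high, model$rho_low)
      thr <- vapply(seq_len(m), function(j)
        thr_get(model, signs[seq_len(j - 1L)], ty[j]), numeric(1))
    } else {
      R <- utility_correlation_matrix(k, model$rho)
      thr <- prefix_thresholds(model, signs)
    }
    U <- draw_mvn(length(idx), R)
    uhat <- U + eps * matrix(stats::rnorm(length(idx) * k), length(idx), k)
    acc <- abs(uhat[, k] - u_hat) <= delta
    for (j in seq_len(m)) {
      acc <- acc & (if (signs[j] > 0) uhat[, j] > thr[j] else uhat[, j] <= thr[j])
    }
    U_k[idx] <- U[, k]
    ok[idx] <- acc
  }
  kept <- U_k[ok]
  n <- length(kept)
  if (n < 2L) return(list(estimate = NA_real_, se = NA_real_, n = n))
  list(estimate = mean(kept), se = stats::sd(kept) / sqrt(n), n = n)
}

#' Factor-level simulation of the utility model
#'
#' Validates the joint covariance structure from first principles.
#' Utilities are built explicitly as weighted sums over `n_factors`
#' standardized environmental factors, \eqn{U_k = \sum_i \alpha_{i,k}
#' x_i}, with unit-norm weight vectors constructed as
#' \eqn{\alpha_k = \sqrt{\rho}\, a_0 + \sqrt{1 - \rho}\, a_k} for
#' mutually orthonormal \eqn{a_0, a_1, \ldots}, so every pair of agents
#' has weight-vector dot product exactly \eqn{\rho}.  Private estimates
#' add independent factor-level noise of variance `eps^2`.  The returned
#' empirical covariance of \eqn{(U, \hat U)} should match
#' [joint_covariance()] to Monte-Carlo accuracy.
#'
#' @param n_agents Number of agents.
#' @param rho Preference correlation in \[0, 1\].
#' @param eps Noise level (> 0).
#' @param n_factors Number of environmental factors (needs
#'   `n_factors >= n_agents + 1`).
#' @param nreps Number of simulated decision problems.
#' @param seed Integer seed.
#' @return The empirical 2N x 2N covariance matrix of
#'   \eqn{(U_1..U_N, \hat U_1..\hat U_N)}.
#' @export
simulate_factor_level <- function(n_agents, rho, eps, n_factors = 64L,
                                  nreps = 1e5, seed = NULL) {
  n_agents <- check_n_agents(n_agents)
  if (rho < 0 || rho > 1)
    stop("the orthonormal-basis weight construction requires rho in [0, 1]",
         call. = FALSE)
  check_noise(eps, "eps")
  if (n_factors < n_agents + 1L)
    stop("need n_factors >= n_agents + 1 for the orthonormal construction",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # weight vectors: shared direction e_1, idiosyncratic e_{k+1}
  W <- matrix(0, n_factors, n_agents)
  W[1L, ] <- sqrt(rho)
  for (k in seq_len(n_agents)) W[k + 1L, k] <- sqrt(1 - rho)
  x <- matrix(stats::rnorm(nreps * n_factors), nreps, n_factors)
  U <- x %*% W
  Uhat <- U
  for (k in seq_len(n_agents)) {
    nu <- matrix(stats::rnorm(nreps * n_factors, sd = eps), nreps, n_factors)
    Uhat[, k] <- U[, k] + nu %*% W[, k]
  }
  stats::cov(cbind(U, Uhat))
}

#' Exact-versus-Monte-Carlo comparison table
#'
#' Runs one simulation and compares the empirical conditional choice
#' probability for each history with the exact observer-side value,
#' reporting z-scores.  The package's self-diagnostic.
#'
#' @inheritParams mc_conditional_probability
#' @param histories Character vector of histories.
#' @param focal_types For subtype models, the focal types to tabulate
#'   (default both).
#' @return A data frame with columns `history` (and `focal_type` for
#'   subtype models), `exact`, `mc`, `se`, `n`, `z`.
#' @export
compare_exact_mc <- function(model, histories, nreps = 1e5, seed = NULL,
                             focal_types = c("alpha", "beta")) {
  sim <- simulate(model, nsim = nreps, seed = seed)
  subtype <- inherits(model, "subtype_decision_model")
  grid <- if (subtype) {
    expand.grid(history = histories, focal_type = focal_types,
                stringsAsFactors = FALSE)
  } else {
    data.frame(history = histories)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- grid$history[i]
    ft <- if (subtype) grid$focal_type[i] else NULL
    ex <- conditional_choice_probability(model, h, ft)
    mc <- mc_conditional_probability(model, h, focal_type = ft, sim = sim)
    data.frame(history = h,
               focal_type = if (subtype) ft else NA_character_,
               exact = unname(ex), mc = mc$estimate, se = mc$se, n = mc$n,
               z = (mc$estimate - unname(ex)) / mc$se)
  })
  out <- do.call(rbind, rows)
  if (!subtype) out$focal_type <- NULL
  out
}
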