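# Figure-style parameter sweeps, returned as plain data frames with a
# deterministic row order (lexicographic in parameters, then history).
# These power the command-line interface and the reproduction tables.

#' Logarithmic or linear grid helper
#'
#' @param lo,hi Grid end points.
#' @param n Number of points.
#' @param log Logarithmic spacing?
#' @return Numeric vector of length `n`.
#' @export
param_grid <- function(lo, hi, n, log = TRUE) {
  stopifnot(n >= 1, lo <= hi, !log || lo > 0)
  if (n == 1L) return(lo)
  if (log) exp(seq(log(lo), log(hi), length.out = n))
  else seq(lo, hi, length.out = n)
}

default_histories <- function(max_len = 3L) all_histories(max_len)

#' Conditional choice probabilities across noise levels
#'
#' For each habitual noise level, builds the decision model and computes
#' the probability that the focal agent chooses A conditional on every
#' history up to `max_len` previous decisions (14 histories by default).
#'
#' @param rho Preference correlation.
#' @param eps_grid Habitual noise levels to sweep.
#' @param eta_ratio Experimental-to-habitual noise ratio (1 = natural
#'   conditions).
#' @param max_len Longest conditioning history.
#' @return A data frame with columns `rho`, `eps`, `eta`, `history`,
#'   `p_A`.
#' @export
sweep_conditional <- function(rho, eps_grid = param_grid(0.1, 10, 9),
                              eta_ratio = 1, max_len = 3L) {
  hs <- default_histories(max_len)
  rows <- lapply(sort(eps_grid), function(e) {
    m <- decision_model(max_len + 1L, rho, eps = e, eta = e * eta_ratio)
    data.frame(rho = rho, eps = e, eta = e * eta_ratio, history = hs,
               p_A = unname(predict(m, hs)))
  })
  do.call(rbind, rows)
}

#' Recency-versus-majority conflict sweep
#'
#' Probability of following the most recent decision when it conflicts
#' with the majority (history `"BBA"`: two for B, then one for A),
#' across a grid of preference correlations and noise levels, with the
#' relative social weighting attached for the collapse plot.
#'
#' @param rho_grid,eps_grid Parameter grids.
#' @param eta_ratio One or more experimental-to-habitual noise ratios.
#' @return A data frame with columns `rho`, `eps`, `eta_ratio`, `p_A`,
#'   `rsw`.
#' @export
sweep_conflict <- function(rho_grid = seq(0, 0.99, length.out = 5),
                           eps_grid = param_grid(0.1, 10, 9),
                           eta_ratio = c(1, 0.5)) {
  grid <- expand.grid(eta_ratio = sort(eta_ratio), eps = sort(eps_grid),
                      rho = sort(rho_grid))[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    m <- decision_model(4L, g$rho, eps = g$eps, eta = g$eps * g$eta_ratio)
    data.frame(rho = g$rho, eps = g$eps, eta_ratio = g$eta_ratio,
               p_A = unname(predict(m, "BBA")), rsw = rsw(g$rho, g$eps))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected consensus sweep
#'
#' Exact expected consensus score of a sequentially deciding group over
#' a grid of preference correlations and noise levels.
#'
#' @inheritParams sweep_conflict
#' @param n_agents Group size (<= 10; exhaustive enumeration).
#' @return A data frame with columns `rho`, `eps`, `eta_ratio`,
#'   `expected_consensus`, `rsw`.
#' @export
sweep_consensus <- function(rho_grid = seq(0, 0.99, length.out = 4),
                            eps_grid = param_grid(0.25, 4, 5),
                            eta_ratio = 1, n_agents = 8L) {
  grid <- expand.grid(eta_ratio = sort(eta_ratio), eps = sort(eps_grid),
                      rho = sort(rho_grid))[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    m <- decision_model(n_agents, g$rho, eps = g$eps, eta = g$eps * g$eta_ratio)
    data.frame(rho = g$rho, eps = g$eps, eta_ratio = g$eta_ratio,
               expected_consensus = expected_consensus(outcome_distribution(m)),
               rsw = rsw(g$rho, g$eps))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cryptic-subtype conditional probability sweep
#'
#' Conditional choice probabilities for focal agents of each type in a
#' two-type population, across noise levels.  The presets of interest
#' are `gamma = 0.5, rho_high = 1, rho_low = 0` (two equally prevalent
#' types with identical within-type preferences) and `gamma = 0.9,
#' rho_high = 0.9, rho_low = 0.25` (a 90% majority type).
#'
#' @inheritParams sweep_conditional
#' @param gamma,rho_high,rho_low Subtype parameters.
#' @param focal_types Which focal types to tabulate.
#' @return A data frame with columns `gamma`, `rho_high`, `rho_low`,
#'   `focal_type`, `eps`, `eta`, `history`, `p_A`.
#' @export
sweep_subtypes <- function(gamma, rho_high, rho_low,
                           eps_grid = param_grid(0.1, 10, 7),
                           eta_ratio = 1, max_len = 3L,
                           focal_types = c("alpha", "beta")) {
  hs <- default_histories(max_len)
  rows <- lapply(sort(eps_grid), function(e) {
    m <- subtype_decision_model(max_len + 1L, gamma, rho_high, rho_low,
                                eps = e, eta = e * eta_ratio)
    do.call(rbind, lapply(focal_types, function(ft) {
      data.frame(gamma = gamma, rho_high = rho_high, rho_low = rho_low,
                 focal_type = ft, eps = e, eta = e * eta_ratio, history = hs,
                 p_A = unname(predict(m, hs, focal_type = ft)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate the recency-majority crossover
#'
#' For the conflict history `"BBA"` under natural conditions
#' (`eta = eps`), the probability of following the most recent decision
#' rises through 1/2 as the habitual noise level increases.  This
#' function brackets the crossing on a logarithmic scan of `eps` and
#' refines it by root finding, returning the crossing noise level and
#' the relative social weighting there.
#'
#' @param rho Preference correlation (the crossing exists for strongly
#'   aligned preferences, e.g. 0.9).
#' @param eps_range Scan interval for the habitual noise level.
#' @param n_scan Number of scan points used to bracket the crossing.
#' @param tol Relative tolerance on the crossing location.
#' @param eta_ratio Experimental-to-habitual noise ratio.
#' @return A list with `eps` (crossing noise level), `rsw` (the RSW
#'   there) and `p_A` (the conditional probability at the located
#'   crossing, ~0.5).
#' @export
find_recency_crossover <- function(rho = 0.9, eps_range = c(0.05, 3),
                                   n_scan = 9L, tol = 1e-3, eta_ratio = 1) {
  f <- function(e) {
    m <- decision_model(4L, rho, eps = e, eta = e * eta_ratio)
    unname(predict(m, "BBA")) - 0.5
  }
  grid <- param_grid(eps_range[1], eps_range[2], n_scan)
  vals <- vapply(grid, f, numeric(1))
  # crossing from below (majority-following) to above (recency-following)
  i <- which(vals[-length(vals)] < 0 & vals[-1] >= 0)
  if (length(i) == 0L)
    stop("no upward crossing of P(A | BBA) = 0.5 in the scanned range", call. = FALSE)
  i <- i[length(i)]
  root <- stats::uniroot(f, c(grid[i], grid[i + 1L]),
                         f.lower = vals[i], f.upper = vals[i + 1L],
                         tol = tol * grid[i])$root
  list(eps = root, rsw = rsw(rho, root), p_A = f(root) + 0.5)
}
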