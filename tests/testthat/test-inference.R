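test_that("posterior mean is conjugate when social information is uninformative", {
  # empty history: u/(1 + eps^2) for every rho
  for (m in list(m_indep, m_weak, m_strong)) {
    expect_equal(posterior_mean(m, c(-2, 0, 1, 3), ""),
                 c(-2, 0, 1, 3) / 2, tolerance = 1e-9)
  }
  # rho = 0: previous choices carry no information, any history
  expect_equal(posterior_mean(m_indep, 1, "A"), 0.5, tolerance = 1e-9)
  expect_equal(posterior_mean(m_indep, 1, "AB"), 0.5, tolerance = 1e-9)
  m_eps <- decision_model(3, 0, eps = 0.5)
  expect_equal(posterior_mean(m_eps, 2, "BB"), 2 / 1.25, tolerance = 1e-9)
})

test_that("posterior mean respects the sign symmetry of the model", {
  for (u in c(-1.5, 0, 0.8)) {
    expect_equal(posterior_mean(m_strong, u, "B"),
                 -posterior_mean(m_strong, -u, "A"), tolerance = 1e-8)
    expect_equal(posterior_mean(m_strong, u, "BAB"),
                 -posterior_mean(m_strong, -u, "ABA"), tolerance = 1e-8)
  }
})

test_that("observed agreement pulls the posterior harder than disagreement", {
  expect_gt(posterior_mean(m_strong, 0, "A"), 0)
  expect_gt(posterior_mean(m_strong, 0, "AA"), posterior_mean(m_strong, 0, "AB"))
  # increasing in the first choice for positive correlation
  expect_gt(posterior_mean(m_weak, 0.5, "A"), posterior_mean(m_weak, 0.5, "B"))
})

test_that("posterior mean is strictly increasing in the private estimate", {
  grid <- seq(-10, 10, length.out = 21)
  for (m in list(m_weak, m_strong, m_ident)) {
    for (h in c("A", "AB", "BBA")) {
      v <- posterior_mean(m, grid, h)
      expect_true(all(diff(v) > 0),
                  info = sprintf("rho = %g, history %s", m$rho, h))
    }
  }
  v <- posterior_mean(s_major, grid, "AB", focal_type = "beta")
  expect_true(all(diff(v) > 0))
})

test_that("posterior mean agrees with the rejection-sampling oracle", {
  cases <- expand.grid(rho = c(0.3, 0.9), eps = c(0.5, 2),
                       history = c("A", "AB"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    m <- decision_model(3, cs$rho, cs$eps)
    exact <- posterior_mean(m, 0.4, cs$history)
    mc <- mc_posterior_mean(m, 0.4, cs$history, delta = 0.05, nreps = 4e5,
                            seed = 42 + i)
    expect_gt(mc$n, 500)
    # small delta-window bias allowance on top of 3 SE
    expect_true(abs(exact - mc$estimate) < 3 * mc$se + 0.01,
                info = sprintf("rho=%g eps=%g h=%s", cs$rho, cs$eps, cs$history))
  }
})

test_that("critical values: first decider at zero, zero correlation all zero", {
  expect_equal(unname(critical_value(m_strong, "")), 0)
  expect_equal(unname(critical_value(m_indep, c("", "A", "AB", "BBA"))),
               rep(0, 4), tolerance = 1e-6)
})

test_that("critical values are antisymmetric and oriented by the history", {
  expect_lt(critical_value(m_strong, "A"), 0) # an observed A lowers the bar
  expect_gt(critical_value(m_strong, "B"), 0)
  tab <- build_threshold_table(m_strong)      # all histories up to length 3
  expect_length(tab, 1 + 2 + 4 + 8)
  for (h in names(tab)[-1]) {
    expect_equal(tab[[h]], -tab[[mirror_history(h)]], tolerance = 1e-8,
                 info = h)
  }
  expect_equal(length(build_threshold_table(decision_model(1, 0.5, 1))), 1L)
})

test_that("identical-preferences thresholds match an independent quadrature oracle", {
  # roots of E(U_2 | Uhat*, C_1 = A) = 0 at rho = 1, computed externally
  # with adaptive integration of the exact one-predecessor posterior
  frozen <- c(`0.5` = -0.428146, `1` = -0.839429, `2` = -1.634468)
  for (e in names(frozen)) {
    m <- decision_model(2, 1, eps = as.numeric(e))
    expect_equal(unname(critical_value(m, "A")), unname(frozen[[e]]),
                 tolerance = 1e-4)
  }
})

test_that("histories longer than the group are rejected", {
  expect_error(critical_value(decision_model(2, 0.5, 1), "AA"),
               "cannot condition")
  expect_error(posterior_mean(m_strong, 0, "AABB"), "cannot condition")
})

test_that("subtype model degenerates to the homogeneous model", {
  # equal within- and between-type correlation: gamma is irrelevant
  s <- subtype_decision_model(4, gamma = 0.3, rho_high = 0.7, rho_low = 0.7,
                              eps = 1)
  hm <- decision_model(4, 0.7, eps = 1)
  hs <- c("A", "AB", "BBA")
  for (ft in c("alpha", "beta")) {
    expect_equal(unname(critical_value(s, hs, ft)),
                 unname(critical_value(hm, hs)), tolerance = 2e-6)
  }
  # single-type population: focal of the prevalent type sees rho_high
  s1 <- subtype_decision_model(4, gamma = 1, rho_high = 0.9, rho_low = 0.1,
                               eps = 1)
  expect_equal(unname(critical_value(s1, hs, "alpha")),
               unname(critical_value(m_strong, hs)), tolerance = 2e-6)
  s0 <- subtype_decision_model(4, gamma = 0, rho_high = 0.9, rho_low = 0.1,
                               eps = 1)
  expect_equal(unname(critical_value(s0, hs, "beta")),
               unname(critical_value(m_strong, hs)), tolerance = 2e-6)
})

test_that("mixed-type threshold lies between the pure-type extremes", {
  s <- subtype_decision_model(3, gamma = 0.5, rho_high = 1, rho_low = 0, eps = 1)
  th <- critical_value(s, "A", "alpha")
  th1 <- critical_value(decision_model(3, 1, 1), "A")
  th0 <- critical_value(decision_model(3, 0, 1), "A")
  expect_lt(th, th0)
  expect_gt(th, th1)
})

test_that("subtype posterior mean matches the two-type generative oracle", {
  exact <- posterior_mean(s_major, 0, "AA", focal_type = "beta")
  mc <- mc_posterior_mean(s_major, 0, "AA", delta = 0.05, nreps = 6e5,
                          seed = 271, focal_type = "beta")
  expect_gt(mc$n, 500)
  expect_lt(abs(exact - mc$estimate), 3 * mc$se + 0.01)
})

test_that("subtype calls require a valid focal type", {
  expect_error(critical_value(s_major, "A"), "focal_type")
  expect_error(posterior_mean(s_major, 0, "A", focal_type = "gamma"), "focal_type")
})
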