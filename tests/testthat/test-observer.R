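test_that("sequence probabilities: symmetric first choice and independent limit", {
  expect_equal(unname(sequence_probability(m_strong, "A")), 0.5, tolerance = 1e-7)
  expect_equal(unname(sequence_probability(m_indep, "AA")), 0.25, tolerance = 1e-6)
  expect_equal(unname(sequence_probability(m_indep, "BABA")), 0.0625,
               tolerance = 1e-6)
})

test_that("sequence probabilities partition to one over all sequences", {
  seqs4 <- apply(expand.grid(rep(list(c("A", "B")), 4)), 1, paste, collapse = "")
  expect_equal(sum(sequence_probability(m_strong, seqs4)), 1, tolerance = 1e-5)
  # subtype model: the type mixture must still partition
  seqs2 <- c("AA", "AB", "BA", "BB")
  expect_equal(sum(sequence_probability(s_major, seqs2)), 1, tolerance = 1e-5)
})

test_that("conditional and response probabilities respect mirror symmetry", {
  for (h in histories_upto(3)) {
    expect_equal(
      unname(conditional_choice_probability(m_strong, h) +
             conditional_choice_probability(m_strong, mirror_history(h))),
      1, tolerance = 2e-6, info = h)
    expect_equal(
      unname(response_probability(m_weak, h) +
             response_probability(m_weak, mirror_history(h))),
      1, tolerance = 2e-6, info = h)
  }
  expect_equal(unname(predict(m_strong, "")), 0.5, tolerance = 1e-9)
  expect_equal(unname(predict(m_strong, "", type = "conditional")), 0.5,
               tolerance = 1e-6)
})

test_that("positive correlation makes the focal agent follow a single A", {
  for (m in list(m_weak, m_strong)) {
    expect_gt(conditional_choice_probability(m, "A"), 0.5)
    expect_gt(response_probability(m, "A"), 0.5)
  }
})

test_that("the response to BBA crosses 1/2 from majority- to recency-following", {
  lo <- decision_model(4, 0.9, eps = 0.2)
  hi <- decision_model(4, 0.9, eps = 2)
  expect_lt(response_probability(lo, "BBA"), 0.5)
  expect_gt(response_probability(hi, "BBA"), 0.5)
  cr <- find_recency_crossover(0.9, eps_range = c(0.1, 3), n_scan = 7)
  expect_equal(cr$p_A, 0.5, tolerance = 1e-3)
  expect_gt(cr$eps, 0.2); expect_lt(cr$eps, 2)
  # the crossing contour (threshold zero) does not move with eta
  lab <- decision_model(4, 0.9, eps = cr$eps, eta = cr$eps / 2)
  expect_equal(unname(response_probability(lab, "BBA")), 0.5, tolerance = 1e-3)
})

test_that("low experimental noise sharpens the social response", {
  nat <- decision_model(4, 0.9, eps = 1)
  lab <- decision_model(4, 0.9, eps = 1, eta = 0.5)
  for (h in c("A", "AA", "AAA")) {
    expect_gt(response_probability(lab, h), response_probability(nat, h))
  }
  expect_lt(response_probability(lab, "B"), response_probability(nat, "B"))
})

test_that("relative social weighting reproduces its limit cases", {
  expect_equal(rsw(1, 0.7), 1)
  expect_equal(rsw(0, 1.3), 0)
  expect_equal(rsw(0.5, 100), 0.5, tolerance = 1e-3)
  expect_lt(abs(rsw(0.9, 1e-3)), 1e-2)       # vanishes with reliable private info
  expect_lt(rsw(-0.5, 1), 0)                 # opposed preferences weight negatively
  expect_error(rsw(1, 0), "degenerate")
  expect_error(rsw(1.2, 1), "exceed 1")
})

test_that("consensus score is the normalized absolute margin", {
  expect_equal(consensus_score(8, 0), 1)
  expect_equal(consensus_score(4, 4), 0)
  expect_equal(consensus_score(6, 2), 0.5)
  expect_equal(consensus_score(c(3, 5), c(1, 5)), c(0.5, 0))
  expect_error(consensus_score(0, 0), "empty group")
  expect_error(consensus_score(-1, 2), "non-negative")
})

test_that("outcome distribution is binomial for uncorrelated preferences", {
  od <- outcome_distribution(m_indep)
  expect_s3_class(od, "outcome_distribution")
  expect_equal(od$probability, dbinom(0:4, 4, 0.5), tolerance = 1e-5)
  expect_equal(sum(od$probability), 1, tolerance = 1e-6)
  expect_error(outcome_distribution(decision_model(11, 0, 1)), "too large")
  expect_error(outcome_distribution(s_major), "undifferentiated")
})

test_that("expected consensus increases with preference correlation", {
  vals <- vapply(c(0, 0.5, 0.9), function(r) {
    expected_consensus(outcome_distribution(decision_model(5, r, eps = 1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("subtype conditional probabilities are consistent with the marginal sequence law", {
  # mixing the focal-type-conditioned joints with weights (gamma, 1-gamma)
  # must recover the type-marginal sequence probability of history + A
  for (h in c("A", "AB")) {
    num_a <- conditional_choice_probability(s_major, h, "alpha") *
      sequence_probability(s_major, h)
    num_b <- conditional_choice_probability(s_major, h, "beta") *
      sequence_probability(s_major, h)
    mixed <- s_major$gamma * num_a + (1 - s_major$gamma) * num_b
    expect_equal(unname(mixed),
                 unname(sequence_probability(s_major, paste0(h, "A"))),
                 tolerance = 2e-6, info = h)
  }
})

test_that("unanimity dominates any split history for equally prevalent cryptic types", {
  pa <- response_probability(s_equal, c("AAA", "AAB", "ABA", "BAA"), "alpha")
  expect_true(all(pa["AAA"] > pa[c("AAB", "ABA", "BAA")]))
  # same by symmetry for the other type
  expect_equal(unname(pa["AAA"]),
               unname(response_probability(s_equal, "AAA", "beta")),
               tolerance = 2e-6)
})

test_that("majority-type agents respond more strongly to social information", {
  for (h in c("A", "AA", "AAA")) {
    expect_gt(response_probability(s_major, h, "alpha"),
              response_probability(s_major, h, "beta"))
  }
  # degenerate subtype observer matches the homogeneous observer
  sdeg <- subtype_decision_model(4, 0.5, 0.9, 0.9, eps = 1)
  expect_equal(unname(predict(sdeg, c("A", "BA"), focal_type = "beta")),
               unname(predict(m_strong, c("A", "BA"))), tolerance = 2e-6)
  expect_equal(unname(predict(sdeg, "AB", focal_type = "alpha",
                              type = "conditional")),
               unname(predict(m_strong, "AB", type = "conditional")),
               tolerance = 2e-6)
})
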