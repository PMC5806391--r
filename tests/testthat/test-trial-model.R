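hm <- haemophilia_model()

test_that("trial_model validates its parameters and names the offender", {
  expect_s3_class(hm, "trial_model")
  expect_error(
    trial_model(0, 1, 1, 100, rho = 0, c1 = 0, c2 = 0, cf = 0),
    "rho",
    class = "voitrial_domain_error"
  )
  expect_error(
    trial_model(0, -1, 1, 100, rho = 0.5, c1 = 0, c2 = 0, cf = 0),
    "sigma0_sq"
  )
  expect_error(
    trial_model(0, 1, 0, 100, rho = 0.5, c1 = 0, c2 = 0, cf = 0),
    "tau_sq"
  )
  expect_error(
    trial_model(0, 1, 1, 0, rho = 0.5, c1 = 0, c2 = 0, cf = 0),
    "N"
  )
  expect_error(
    trial_model(0, 1, 1, 100, rho = 0.5, c1 = -1, c2 = 0, cf = 0),
    "c1"
  )
})

test_that("prior-predictive sd matches its closed form and limits", {
  # hand evaluation of sqrt(49638^2 + 363202^2 / 46)
  expect_equal(prior_predictive_sd(hm, 46), sqrt(49638^2 + 363202^2 / 46))
  expect_equal(prior_predictive_sd(hm, 46), 73018, tolerance = 1e-4)

  # no sampling noise: tau_sq -> 0 reduces to the prior sd for any n
  m0 <- trial_model(0, sigma0_sq = 4, tau_sq = 1e-12, N = 100, rho = 0.5, c1 = 0, c2 = 0, cf = 0)
  expect_equal(prior_predictive_sd(m0, c(2, 10, 400)), rep(2, 3), tolerance = 1e-6)

  # n -> infinity limit is the prior sd
  expect_equal(prior_predictive_sd(hm, 1e12), 49638, tolerance = 1e-6)

  expect_error(prior_predictive_sd(hm, 0), class = "voitrial_domain_error")
  expect_error(prior_predictive_sd(hm, -2), class = "voitrial_domain_error")
})

test_that("pointwise utility matches direct evaluation of the utility function", {
  # approval: (theta - c2) (N - n/rho + n/2) - c1 n - cf
  expect_equal(
    pointwise_utility(hm, 46, "reject", 96000),
    (96000 - 61032) * (4000 - 230 + 23) - 5000 * 46 - 1e6
  )
  expect_equal(pointwise_utility(hm, 46, "reject", 96000) / 1e6, 131.4, tolerance = 1e-3)

  # non-approval treats only the n/2 trial patients
  expect_equal(
    pointwise_utility(hm, 46, "not_reject", 96000),
    (96000 - 61032) * 23 - 5000 * 46 - 1e6
  )
  expect_equal(pointwise_utility(hm, 46, "not_reject", 96000) / 1e6, -0.426, tolerance = 1e-2)

  # baseline: no trial, no decision costs
  expect_identical(pointwise_utility(hm, 0, "not_reject", 12345), 0)
  # at n = 0 approval hands the whole population the treatment, no fixed cost
  expect_equal(pointwise_utility(hm, 0, "reject", 96000), 4000 * (96000 - 61032))

  # harm is not truncated
  expect_lt(pointwise_utility(hm, 46, "reject", -1e5), pointwise_utility(hm, 46, "reject", 0))

  expect_error(pointwise_utility(hm, 45, "reject", 0), "even", class = "voitrial_domain_error")
  expect_error(pointwise_utility(hm, 802, "reject", 0), class = "voitrial_domain_error")
})

test_that("closed-form expected utility reproduces the case-study values", {
  expect_equal(expected_utility(hm, 46, 0.36876) / 1e6, 141, tolerance = 0.005)
  expect_equal(expected_utility(hm, 268, qnorm(0.975)) / 1e6, 109, tolerance = 0.02)
  # n = 0, approve-on-prior branch
  expect_equal(expected_utility(hm, 0, -Inf), 4000 * (96000 - 61032))
  expect_equal(expected_utility(hm, 0, -0.5), 4000 * (96000 - 61032))
  expect_identical(expected_utility(hm, 0, Inf), 0)
  expect_identical(expected_utility(hm, 0, 0.5), 0)
})

test_that("expected utility agrees with the preposterior quadrature oracle", {
  set.seed(7001)
  for (i in 1:5) {
    m <- random_model()
    d <- random_design(m)
    expect_equal(
      expected_utility(m, d$n, d$z),
      quad_expected_utility(m, d$n, d$z),
      tolerance = 1e-4
    )
  }
  # and on the case study optimum itself
  expect_equal(
    expected_utility(hm, 46, 0.36876),
    quad_expected_utility(hm, 46, 0.36876),
    tolerance = 1e-6
  )
})

test_that("expected utility approaches the always/never-approve limits in z", {
  ns <- c(10, 46, 250)
  # z -> -inf: everyone is approved regardless of the data
  expect_equal(
    expected_utility(hm, ns, -30),
    (hm$N - ns / hm$rho) * (hm$mu0 - hm$c2) + ns / 2 * (hm$mu0 - hm$c2) - hm$c1 * ns - hm$cf,
    tolerance = 1e-9
  )
  # z -> +inf: never approved
  expect_equal(
    expected_utility(hm, ns, 30),
    ns / 2 * (hm$mu0 - hm$c2) - hm$c1 * ns - hm$cf,
    tolerance = 1e-9
  )
  # continuity in z at fixed n
  zs <- seq(-3, 3, by = 0.01)
  g <- expected_utility(hm, rep(46, length(zs)), zs)
  expect_true(all(abs(diff(g)) < 1e6)) # no jumps at this resolution
})

test_that("expected utility is equivariant under monetary rescaling", {
  set.seed(7002)
  for (i in 1:5) {
    m <- random_model()
    d <- random_design(m)
    k <- runif(1, 0.1, 25)
    mk <- trial_model(
      mu0 = k * m$mu0, sigma0_sq = k^2 * m$sigma0_sq, tau_sq = k^2 * m$tau_sq,
      N = m$N, rho = m$rho, c1 = k * m$c1, c2 = k * m$c2, cf = k * m$cf
    )
    expect_equal(expected_utility(mk, d$n, d$z), k * expected_utility(m, d$n, d$z),
      tolerance = 1e-10
    )
    # the standardised threshold Z is scale-free, so optimal z is too
    expect_equal(optimal_z(mk, d$n), optimal_z(m, d$n), tolerance = 1e-10)
  }
})

test_that("no-trial branch returns the prior-only decision", {
  nt <- expected_utility_no_trial(hm)
  expect_equal(nt$utility, 4000 * (96000 - 61032)) # ~ $139.87M
  expect_identical(nt$decision, "approve")

  m_tie <- trial_model(5e4, 1e8, 1e10, 1000, 0.5, 0, c2 = 5e4, cf = 0)
  tie <- expected_utility_no_trial(m_tie)
  expect_identical(tie$utility, 0)
  expect_identical(tie$decision, "indifferent")

  m_neg <- trial_model(5e4, 1e8, 1e10, 1000, 0.5, 0, c2 = 9e4, cf = 0)
  neg <- expected_utility_no_trial(m_neg)
  expect_identical(neg$utility, 0)
  expect_identical(neg$decision, "do_not_approve")
})
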