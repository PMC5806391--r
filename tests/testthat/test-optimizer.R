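hm <- haemophilia_model()

test_that("optimal_z is the stationary point of the expected utility in z", {
  # case-study scale
  for (n in c(10, 46, 268)) {
    z_star <- optimal_z(hm, n)
    d <- num_dg_dz(hm, n, z_star)
    expect_lt(abs(d) / max(abs(expected_utility(hm, n, z_star)), 1), 1e-6)
    # and it is a maximum, not merely stationary
    expect_lt(expected_utility(hm, n, z_star + 0.1), expected_utility(hm, n, z_star))
    expect_lt(expected_utility(hm, n, z_star - 0.1), expected_utility(hm, n, z_star))
  }
  # randomized scenarios
  set.seed(7101)
  for (i in 1:10) {
    m <- random_model()
    d <- random_design(m)
    z_star <- optimal_z(m, d$n)
    if (abs(z_star) < 8) { # derivative is numerically zero far in the tails anyway
      expect_lt(
        abs(num_dg_dz(m, d$n, z_star)) /
          max(abs(expected_utility(m, d$n, z_star)), 1),
        1e-6
      )
    }
  }
})

test_that("optimal_z handles edge cases", {
  # both terms vanish when c2 = 0 and mu0 = 0
  m <- trial_model(0, 1e8, 1e10, 1000, 0.5, 0, c2 = 0, cf = 0)
  expect_equal(optimal_z(m, c(2, 10, 100)), rep(0, 3))
  # degenerate prior
  m_deg <- trial_model(1, 0, 1e10, 1000, 0.5, 0, c2 = 0, cf = 0)
  expect_error(optimal_z(m_deg, 10), "degenerate", class = "voitrial_domain_error")
  expect_error(optimal_z(hm, 0), class = "voitrial_domain_error")
})

test_that("optimize_design recovers the case-study optimum", {
  fit <- optimize_design(hm)
  expect_s3_class(fit, "voi_design")
  expect_identical(fit$n_star, 46)
  expect_false(fit$no_trial)
  expect_equal(fit$z_star, 0.36876, tolerance = 0.02)
  expect_equal(fit$alpha_star, 0.35615, tolerance = 0.01 / 0.35615)
  expect_equal(fit$g_star / 1e6, 141, tolerance = 0.005)
  # continuous optimum sits just below the even projection
  expect_equal(fit$n_continuous, 45.5, tolerance = 0.01)
  # even-n reporting convention re-evaluates z at n* = 46
  fit_even <- optimize_design(hm, z_convention = "even")
  expect_identical(fit_even$n_star, 46L + 0) # same projection
  expect_equal(fit_even$z_star, optimal_z(hm, 46))

  tg <- tidy(fit)
  expect_s3_class(tg, "tbl_df")
  expect_identical(tg$n_star, 46)
  gl <- glance(fit)
  expect_true(all(c("g_no_trial", "n_continuous", "z_convention") %in% names(gl)))
})

test_that("optimizer output dominates the grid and the no-trial branch", {
  set.seed(7102)
  for (i in 1:8) {
    m <- random_model()
    fit <- optimize_design(m)
    expect_gte(fit$g_star, expected_utility_no_trial(m)$utility - 1e-6)
    n_max <- 2 * floor(m$rho * m$N / 2)
    if (n_max >= 2) {
      grid <- seq(2, min(n_max, 400), by = 2)
      g_grid <- expected_utility(m, grid, optimal_z(m, grid))
      expect_gte(fit$g_star, max(g_grid) - 1e-6 * max(abs(g_grid), 1))
    }
  }
})

test_that("optimize_design agrees with the exhaustive (n, z) grid oracle", {
  set.seed(7103)
  found_trial <- 0L
  for (i in 1:6) {
    m <- random_model()
    # shrink to a small population so the oracle is exhaustive
    m <- trial_model(m$mu0, m$sigma0_sq, m$tau_sq,
      N = sample(50:400, 1),
      rho = runif(1, 0.3, 1), c1 = m$c1, c2 = m$c2, cf = runif(1, 0, 1e6)
    )
    oracle <- brute_force_optimum(m)
    fit <- optimize_design(m)
    expect_equal(fit$g_star, oracle$g,
      tolerance = 1e-6,
      label = sprintf("scenario %d g_star", i)
    )
    if (oracle$n > 0 && fit$n_star > 0) {
      found_trial <- found_trial + 1L
      expect_equal(fit$n_star, oracle$n, tolerance = 2.1) # adjacent even n can tie
    }
  }
})

test_that("no-trial boundaries are reported with the approval decision", {
  # small population, favourable prior: approve without a trial
  m_small <- trial_model(96000, 49638^2, 363202^2,
    N = 2000, rho = 0.2,
    c1 = 5000, c2 = 61032, cf = 1e6
  )
  fit <- optimize_design(m_small)
  expect_identical(fit$n_star, 0)
  expect_true(fit$no_trial)
  expect_identical(fit$approve_without_trial, "approve")
  expect_identical(fit$z_star, -Inf)
  expect_identical(fit$alpha_star, 1)
  expect_equal(fit$g_star, 2000 * (96000 - 61032))

  # cost exceeds the prior mean and the population is tiny: keep the standard
  m_neg <- trial_model(96000, 49638^2, 363202^2,
    N = 100, rho = 0.2,
    c1 = 5000, c2 = 120819, cf = 1e6
  )
  fit_neg <- optimize_design(m_neg)
  expect_identical(fit_neg$n_star, 0)
  expect_identical(fit_neg$approve_without_trial, "do_not_approve")
  expect_identical(fit_neg$z_star, Inf)
  expect_identical(fit_neg$g_star, 0)

  # empty feasible set (rho * N < 2) falls back to the prior-only decision
  m_empty <- trial_model(1000, 1e6, 1e8, N = 5, rho = 0.2, c1 = 0, c2 = 0, cf = 0)
  fit_empty <- optimize_design(m_empty)
  expect_true(fit_empty$no_trial)
  expect_match(fit_empty$note, "no feasible trial")
})

test_that("optimal sample size grows like sqrt(N) for large populations", {
  Ns <- round(10^seq(4, 7, by = 0.5))
  n_stars <- vapply(
    Ns,
    function(N) {
      m <- trial_model(96000, 49638^2, 363202^2,
        N = N, rho = 0.2,
        c1 = 5000, c2 = 61032, cf = 1e6
      )
      optimize_design(m, coarse_step = 2)$n_star
    },
    numeric(1)
  )
  expect_true(all(n_stars > 0))
  slope <- coef(lm(log(n_stars) ~ log(Ns)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1 / 0.5)
})

test_that("conventional sample size matches the closed-form formula", {
  # case-study comparator
  expect_identical(conventional_sample_size(0.025, 0.8, theta_a = 24819, tau = 363202), 268L)
  # smallest even n >= (z_{0.975} + z_{0.9})^2 when theta_a = tau
  expect_identical(conventional_sample_size(0.025, 0.1, theta_a = 1, tau = 1), 12L)
  # quadratic scaling in the alternative
  n1 <- conventional_sample_size(0.025, 0.2, theta_a = 10000, tau = 363202)
  n2 <- conventional_sample_size(0.025, 0.2, theta_a = 20000, tau = 363202)
  expect_equal(n1 / n2, 4, tolerance = 0.02)
  # infeasible error-rate pair
  expect_error(conventional_sample_size(0.6, 0.6, theta_a = 1, tau = 1),
    class = "voitrial_domain_error"
  )
})

test_that("conventional comparator design evaluates its expected utility", {
  conv <- conventional_design(hm, alpha = 0.025, beta = 0.8)
  expect_identical(conv$n, 268L)
  expect_equal(conv$theta_a, 24819)
  expect_equal(conv$g / 1e6, 109, tolerance = 0.02)
  # the VOI optimum dominates it by construction
  expect_gt(optimize_design(hm)$g_star, conv$g)
})
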