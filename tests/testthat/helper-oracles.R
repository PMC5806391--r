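# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form/optimizer code paths: quadrature of the preposterior
# double integral, exhaustive grid search, and finite differences.

# Preposterior expected utility by nested numerical quadrature: integrate the
# pointwise utility over the posterior of theta given xbar, then over the
# prior predictive of xbar. Oracle for expected_utility().
quad_expected_utility <- function(model, n, z_alpha) {
  stopifnot(n > 0)
  tau_sq <- model$tau_sq
  sig0 <- sqrt(model$sigma0_sq)
  sx <- sqrt(model$sigma0_sq + tau_sq / n)
  threshold <- z_alpha * sqrt(tau_sq / n)
  post_var <- 1 / (1 / model$sigma0_sq + n / tau_sq)
  inner <- function(xbar) {
    post_mean <- post_var * (model$mu0 / model$sigma0_sq + n * xbar / tau_sq)
    d <- if (xbar >= threshold) "reject" else "not_reject"
    stats::integrate(
      function(theta) {
        pointwise_utility(model, n, d, theta) *
          dnorm(theta, post_mean, sqrt(post_var))
      },
      lower = post_mean - 10 * sqrt(post_var),
      upper = post_mean + 10 * sqrt(post_var),
      rel.tol = 1e-9, abs.tol = 0
    )$value
  }
  stats::integrate(
    Vectorize(function(xbar) inner(xbar) * dnorm(xbar, model$mu0, sx)),
    lower = model$mu0 - 10 * sx, upper = model$mu0 + 10 * sx,
    rel.tol = 1e-9, abs.tol = 0, subdivisions = 400L
  )$value
}

# Exhaustive search over every feasible even n and a fine z grid.
# Oracle for optimize_design() on small populations.
brute_force_optimum <- function(model, z_grid = seq(-6, 6, by = 2e-4)) {
  n_max <- 2 * floor(model$rho * model$N / 2)
  best <- list(n = 0, z = NA_real_, g = expected_utility_no_trial(model)$utility)
  if (n_max >= 2) {
    for (n in seq(2, n_max, by = 2)) {
      g <- expected_utility(model, n, z_grid)
      i <- which.max(g)
      if (g[i] > best$g) best <- list(n = n, z = z_grid[i], g = g[i])
    }
  }
  best
}

# Central-difference derivative of the expected utility in z_alpha.
num_dg_dz <- function(model, n, z, h = 1e-4) {
  (expected_utility(model, n, z + h) - expected_utility(model, n, z - h)) / (2 * h)
}

# Random non-degenerate scenario under the master seed of the calling test.
random_model <- function() {
  trial_model(
    mu0 = runif(1, -5e4, 1.5e5),
    sigma0_sq = runif(1, 1e4, 8e4)^2,
    tau_sq = runif(1, 5e4, 5e5)^2,
    N = sample(500:20000, 1),
    rho = runif(1, 0.05, 1),
    c1 = runif(1, 0, 2e4),
    c2 = runif(1, 0, 1.2e5),
    cf = runif(1, 0, 5e6)
  )
}

# A random feasible design (even n >= 2) for a model.
random_design <- function(model) {
  n_max <- max(2, 2 * floor(model$rho * model$N / 2))
  list(
    n = 2 * sample.int(n_max / 2, 1),
    z = runif(1, -2, 3)
  )
}
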