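#' Monte Carlo estimate of a design's expected utility
#'
#' Forward-simulates the preposterior experiment that the closed-form
#' expected utility integrates analytically: draw a true effect from the
#' prior, draw an observed mean difference from the sampling model, apply
#' the approval rule, and score the realised utility. Used as an
#' independent oracle for [expected_utility()]; agreement within Monte
#' Carlo error validates the closed form on any scenario.
#'
#' @param model A [trial_model()].
#' @param n Total trial sample size, a positive even integer
#'   (`n <= rho * N`). For `n = 0` use [expected_utility_no_trial()] — there
#'   is nothing to simulate.
#' @param z_alpha Significance threshold on the standard-normal scale.
#' @param replicates Number of simulated trials (default `1e5`).
#' @param seed Integer seed; results are identical for identical seeds.
#' @return A one-row tibble: `mean_utility`, `std_error` (Monte Carlo
#'   standard error of the mean), `reject_rate` (fraction of replicates
#'   approving), `replicates`, `seed`.
#' @examples
#' m <- haemophilia_model()
#' simulate_expected_utility(m, 46, 0.36876, replicates = 1e4, seed = 1)
#' expected_utility(m, 46, 0.36876) # closed form
#' @export
simulate_expected_utility <- function(model, n, z_alpha, replicates = 1e5, seed = 1) {
  stop_not_model(model)
  check_scalar_num(n, "n", lower = 0)
  if (n == 0) {
    abort(
      "`n` = 0: nothing to simulate; use expected_utility_no_trial().",
      class = "voitrial_domain_error"
    )
  }
  check_design_n(model, n)
  check_scalar_num(z_alpha, "z_alpha")
  check_scalar_num(replicates, "replicates", lower = 1)
  check_scalar_num(seed, "seed")

  set.seed(seed)
  r <- as.integer(replicates)
  theta <- rnorm(r, model$mu0, sqrt(model$sigma0_sq))
  xbar <- rnorm(r, theta, sqrt(model$tau_sq / n))
  reject <- xbar >= z_alpha * sqrt(model$tau_sq / n)
  treated <- ifelse(reject, model$N - n / model$rho + n / 2, n / 2)
  u <- (theta - model$c2) * treated - model$c1 * n - model$cf
  tibble(
    mean_utility = mean(u),
    std_error = sd(u) / sqrt(r),
    reject_rate = mean(reject),
    replicates = r,
    seed = as.integer(seed)
  )
}

#' Monte Carlo rejection rate at a fixed true effect
#'
#' Simulates the trial at a single fixed effect size and returns the
#' fraction of replicates crossing the approval threshold. At `theta = 0`
#' this estimates the type I error `1 - pnorm(z_alpha)`; at an alternative
#' it estimates power, `1 - beta` of [oc_of_design()].
#'
#' @param n Total trial sample size, positive.
#' @param z_alpha Significance threshold on the standard-normal scale.
#' @param tau Sampling standard-deviation scale ($), positive.
#' @param theta Fixed true monetary effect ($).
#' @param replicates Number of simulated trials (default `1e5`).
#' @param seed Integer seed.
#' @return The rejection fraction (numeric scalar in `[0, 1]`).
#' @examples
#' simulate_power(268, qnorm(0.975),
#'   tau = 363202, theta = 24819,
#'   replicates = 1e4, seed = 1
#' ) # ~ 0.20
#' @export
simulate_power <- function(n, z_alpha, tau, theta, replicates = 1e5, seed = 1) {
  check_scalar_num(n, "n", lower = 0, strict = TRUE)
  check_scalar_num(z_alpha, "z_alpha")
  check_scalar_num(tau, "tau", lower = 0, strict = TRUE)
  check_scalar_num(theta, "theta")
  check_scalar_num(replicates, "replicates", lower = 1)
  check_scalar_num(seed, "seed")
  set.seed(seed)
  xbar <- rnorm(as.integer(replicates), theta, tau / sqrt(n))
  mean(xbar >= z_alpha * tau / sqrt(n))
}
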