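#' Frequentist operating characteristics of a design
#'
#' Converts a `(n, z_alpha)` design into one-sided error rates: the type I
#' error `alpha = 1 - pnorm(z_alpha)` (probability of approval when the true
#' effect is zero) and the type II error
#' `beta = pnorm(z_alpha - theta_a * sqrt(n) / tau)` (probability of
#' non-approval when the true effect equals the alternative `theta_a`).
#'
#' For the no-trial design (`n = 0`) the decision is deterministic, so
#' `alpha` is 0 or 1 depending on the sign of `z_alpha` (`NA` at
#' indifference) and `beta` is undefined (`NA`).
#'
#' @param n Total trial sample size (patients), `>= 0`.
#' @param z_alpha Significance threshold on the standard-normal scale;
#'   `+/-Inf` or `NA` encode the no-trial decisions.
#' @param tau Sampling standard-deviation scale ($), positive.
#' @param theta_a Monetary alternative effect ($) at which the type II error
#'   is evaluated.
#' @return A one-row tibble: `alpha`, `beta`, `power` (`1 - beta`),
#'   `theta_a`.
#' @examples
#' oc_of_design(268, qnorm(0.975), tau = 363202, theta_a = 24819)
#' oc_of_design(46, 0.36876, tau = 363202, theta_a = 24819)
#' @export
oc_of_design <- function(n, z_alpha, tau, theta_a) {
  check_scalar_num(n, "n", lower = 0)
  check_scalar_num(tau, "tau", lower = 0, strict = TRUE)
  check_scalar_num(theta_a, "theta_a")
  if (n == 0) {
    alpha <- if (is.na(z_alpha)) NA_real_ else if (z_alpha < 0) 1 else 0
    return(tibble(alpha = alpha, beta = NA_real_, power = NA_real_, theta_a = theta_a))
  }
  if (!is.finite(z_alpha)) {
    alpha <- if (z_alpha < 0) 1 else 0
    beta <- if (z_alpha < 0) 0 else 1
    return(tibble(alpha = alpha, beta = beta, power = 1 - beta, theta_a = theta_a))
  }
  alpha <- 1 - pnorm(z_alpha)
  beta <- pnorm(z_alpha - theta_a * sqrt(n) / tau)
  tibble(alpha = alpha, beta = beta, power = 1 - beta, theta_a = theta_a)
}

#' Sweep the optimal design over population size and treatment cost
#'
#' Re-optimises the design for every combination of population size `N` and
#' per-patient treatment cost `c2`, holding the other scenario parameters at
#' the template's values, and records the optimum together with its
#' operating characteristics. This reproduces the model's characteristic
#' behaviour: below a population threshold no trial is run; beyond it the
#' optimal sample size grows roughly like `sqrt(N)` and, whenever treating
#' future patients carries a cost, the optimal significance level tightens
#' as the population grows.
#'
#' @param model A [trial_model()] used as the template scenario.
#' @param N Vector of population sizes to sweep; defaults to 40
#'   log-spaced values in `[100, 1e7]`.
#' @param c2 Vector of per-patient treatment costs; defaults to the
#'   template's `c2`.
#' @param theta_a Alternative effect for the type II error column; defaults
#'   to `sqrt(sigma0_sq) / 2`.
#' @param ... Passed on to [optimize_design()].
#' @return A tibble of class `voi_sweep`, one row per `(c2, N)` combination,
#'   ordered by `(c2, N)`: columns `N`, `c2`, `n_star`, `z_star`,
#'   `alpha_star`, `beta_star`, `g_star`, `no_trial`,
#'   `approve_without_trial`, `error` (`NA` unless that row's optimisation
#'   failed, in which case the message is recorded and the sweep continues).
#' @examples
#' sweep_designs(haemophilia_model(), N = c(1000, 4000, 16000))
#' @export
sweep_designs <- function(model, N = NULL, c2 = NULL, theta_a = NULL, ...) {
  stop_not_model(model)
  if (is.null(N)) N <- round(10^seq(2, 7, length.out = 40))
  if (is.null(c2)) c2 <- model$c2
  if (length(N) == 0 || length(c2) == 0) {
    abort("`N` and `c2` grids must be non-empty.", class = "voitrial_domain_error")
  }
  if (is.null(theta_a)) theta_a <- sqrt(model$sigma0_sq) / 2
  tau <- sqrt(model$tau_sq)

  grid <- tidyr::expand_grid(c2 = as.numeric(c2), N = as.numeric(N))
  rows <- purrr::pmap(grid, function(c2, N) {
    tryCatch(
      {
        m <- trial_model(
          mu0 = model$mu0, sigma0_sq = model$sigma0_sq, tau_sq = model$tau_sq,
          N = N, rho = model$rho, c1 = model$c1, c2 = c2, cf = model$cf
        )
        fit <- optimize_design(m, ...)
        oc <- oc_of_design(fit$n_star, fit$z_star, tau, theta_a)
        tibble(
          N = N, c2 = c2, n_star = fit$n_star, z_star = fit$z_star,
          alpha_star = fit$alpha_star, beta_star = oc$beta, g_star = fit$g_star,
          no_trial = fit$no_trial,
          approve_without_trial = fit$approve_without_trial,
          error = NA_character_
        )
      },
      error = function(e) {
        tibble(
          N = N, c2 = c2, n_star = NA_real_, z_star = NA_real_,
          alpha_star = NA_real_, beta_star = NA_real_, g_star = NA_real_,
          no_trial = NA, approve_without_trial = NA_character_,
          error = conditionMessage(e)
        )
      }
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), c2, N)
  class(out) <- c("voi_sweep", class(out))
  out
}

#' Smallest population size for which running a trial is optimal
#'
#' For a template scenario with treatment cost `c2`, finds by doubling-then-
#' bisection the smallest integer population size `N` at which
#' [optimize_design()] returns a positive optimal sample size. Below the
#' returned boundary the optimal action is prior-only (approve outright when
#' `mu0 > c2`, keep the standard treatment when `mu0 < c2`); the largest
#' no-trial population is the boundary minus one.
#'
#' @param model A [trial_model()] template; its own `N` is ignored.
#' @param c2 Per-patient treatment cost defining the scenario; defaults to
#'   the template's.
#' @param N_max Upper bound for the bracketing search (default `1e8`).
#' @param ... Passed on to [optimize_design()].
#' @return A one-row tibble: `c2`, `N_first_trial` (smallest N with
#'   `n_star > 0`; `NA` when status is not `"threshold"`),
#'   `N_last_no_trial` (`N_first_trial - 1`), and `status` —
#'   `"threshold"`, `"always"` (a trial is optimal even at `N = 1`) or
#'   `"never"` (no trial is optimal anywhere up to `N_max`).
#' @examples
#' find_population_threshold(haemophilia_model())
#' @export
find_population_threshold <- function(model, c2 = NULL, N_max = 1e8, ...) {
  stop_not_model(model)
  if (is.null(c2)) c2 <- model$c2
  check_scalar_num(c2, "c2")
  check_scalar_num(N_max, "N_max", lower = 1)

  n_star_at <- function(N) {
    m <- trial_model(
      mu0 = model$mu0, sigma0_sq = model$sigma0_sq, tau_sq = model$tau_sq,
      N = N, rho = model$rho, c1 = model$c1, c2 = c2, cf = model$cf
    )
    optimize_design(m, ...)$n_star
  }

  if (n_star_at(1) > 0) {
    return(tibble(
      c2 = c2, N_first_trial = 1, N_last_no_trial = 0, status = "always"
    ))
  }
  lo <- 1
  hi <- 2
  while (hi < N_max && n_star_at(hi) == 0) {
    lo <- hi
    hi <- min(2 * hi, N_max)
  }
  if (n_star_at(hi) == 0) {
    return(tibble(
      c2 = c2, N_first_trial = NA_real_, N_last_no_trial = NA_real_,
      status = "never"
    ))
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (n_star_at(mid) > 0) hi <- mid else lo <- mid
  }
  tibble(
    c2 = c2, N_first_trial = hi, N_last_no_trial = hi - 1,
    status = "threshold"
  )
}
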