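#' Analytically optimal significance threshold for a given sample size
#'
#' For any fixed trial size `n > 0` the expected utility is maximised in
#' `z_alpha` at the stationary point of its derivative,
#' \deqn{z_\alpha^*(n) = c_2 \frac{\sigma_x^2 \sqrt n}{\sigma_0^2 \tau}
#'   - \mu_0 \frac{\tau}{\sigma_0^2 \sqrt n},}
#' with \eqn{\sigma_x^2 = \sigma_0^2 + \tau^2/n}. Larger treatment costs push
#' the threshold up (stronger evidence demanded); a favourable prior mean
#' pulls it down. The formula requires an informative prior
#' (`sigma0_sq > 0`).
#'
#' @param model A [trial_model()].
#' @param n Trial sample size(s), positive, real-valued; vectorised.
#' @return Numeric vector of optimal thresholds on the standard-normal
#'   scale.
#' @examples
#' optimal_z(haemophilia_model(), 46)
#' @export
optimal_z <- function(model, n) {
  stop_not_model(model)
  if (model$sigma0_sq <= 0) {
    abort(
      "`sigma0_sq` = 0: the optimal threshold is undefined under a degenerate prior.",
      class = "voitrial_domain_error"
    )
  }
  if (length(n) == 0 || any(!is.finite(n)) || any(n <= 0)) {
    abort("`n` must be positive.", class = "voitrial_domain_error")
  }
  tau <- sqrt(model$tau_sq)
  sx_sq <- model$sigma0_sq + model$tau_sq / n
  model$c2 * sx_sq * sqrt(n) / (model$sigma0_sq * tau) -
    model$mu0 * tau / (model$sigma0_sq * sqrt(n))
}

## expected utility profile g(n) = G(n, z*(n)), vectorised over n > 0
g_profile <- function(model, n) {
  expected_utility(model, n, optimal_z(model, n))
}

#' Jointly optimal sample size and significance threshold
#'
#' Maximises the closed-form expected utility over the trial sample size,
#' with the significance threshold set to its analytic optimum
#' [optimal_z()] at every candidate `n`, and compares the best trial against
#' the no-trial alternative [expected_utility_no_trial()]. The search scans
#' an even grid over `[2, n_max]`, refines the best bracket over continuous
#' `n` by golden-section search, and projects the continuous maximiser to
#' the better of its two adjacent even integers.
#'
#' Two reporting conventions are offered for the threshold. The default,
#' `"continuous"`, reports `z_star` (and `alpha_star = 1 - pnorm(z_star)`)
#' at the continuous-`n` maximiser, which is where the joint optimum
#' actually sits; `"even"` reports them re-evaluated at the even integer
#' `n_star`. The maximised utility `g_star` is always the utility of the
#' reported even design at its own optimal threshold (or the no-trial
#' utility).
#'
#' When no trial is optimal, `z_star` is `-Inf` (approve: `alpha_star = 1`)
#' or `+Inf` (do not approve: `alpha_star = 0`); at exact indifference
#' (`mu0 == c2`) both are `NA`.
#'
#' @param model A [trial_model()].
#' @param n_max Largest sample size to consider; defaults to the largest
#'   even integer `<= rho * N` (the whole concurrent population).
#' @param coarse_step Even grid step for the coarse scan (default 2, i.e.
#'   every feasible trial size).
#' @param refine_tol Relative utility tolerance used for tie-breaking
#'   (default `1e-9`); within it the smaller trial is preferred.
#' @param z_convention `"continuous"` (default) or `"even"`; see Details.
#'
#' @return An object of class `voi_design`: a list with elements `n_star`,
#'   `z_star`, `alpha_star`, `g_star`, `no_trial`, `approve_without_trial`,
#'   `n_continuous`, `z_continuous`, `g_continuous`, `g_no_trial`,
#'   `z_convention` and `model`. Use [tidy()] / [glance()] for tibble views
#'   and [autoplot()] for the utility profile.
#'
#' @examples
#' fit <- optimize_design(haemophilia_model())
#' fit
#' glance(fit)
#' @export
optimize_design <- function(model, n_max = NULL, coarse_step = 2,
                            refine_tol = 1e-9,
                            z_convention = c("continuous", "even")) {
  stop_not_model(model)
  z_convention <- arg_match(z_convention)
  feasible_max <- 2 * floor(model$rho * model$N / 2)
  if (is.null(n_max)) n_max <- feasible_max
  check_scalar_num(n_max, "n_max", lower = 0)
  n_max <- min(2 * floor(n_max / 2), feasible_max)
  check_scalar_num(coarse_step, "coarse_step", lower = 2)
  if (abs(coarse_step - 2 * round(coarse_step / 2)) > 1e-8) {
    abort("`coarse_step` must be even.", class = "voitrial_domain_error")
  }
  check_scalar_num(refine_tol, "refine_tol", lower = 0, strict = TRUE)

  no_trial <- expected_utility_no_trial(model)

  if (n_max < 2) {
    # no feasible trial at all: report the prior-only decision
    return(new_voi_design(model, no_trial,
      trial = NULL, z_convention = z_convention,
      note = "no feasible trial: rho * N < 2"
    ))
  }

  grid <- seq(2, n_max, by = coarse_step)
  g_grid <- g_profile(model, grid)
  i_best <- which.max(g_grid)

  # refine over continuous n within the bracketing grid interval
  lo <- grid[max(i_best - 1L, 1L)]
  hi <- grid[min(i_best + 1L, length(grid))]
  if (lo < hi) {
    ref <- optimize(function(n) g_profile(model, n),
      interval = c(lo, hi), maximum = TRUE,
      tol = .Machine$double.eps^0.5
    )
    n_cont <- ref$maximum
    g_cont <- ref$objective
  } else {
    n_cont <- grid[i_best]
    g_cont <- g_grid[i_best]
  }
  if (g_grid[i_best] > g_cont) { # refinement can only improve; guard anyway
    n_cont <- grid[i_best]
    g_cont <- g_grid[i_best]
  }

  # project to adjacent even integers (plus the best grid point)
  cand <- unique(pmin(pmax(c(
    2 * floor(n_cont / 2), 2 * ceiling(n_cont / 2), grid[i_best]
  ), 2), n_max))
  g_cand <- g_profile(model, cand)
  # tie-break towards smaller n within refine_tol
  scale <- max(abs(g_cand), 1)
  best <- which(g_cand >= max(g_cand) - refine_tol * scale)
  j <- best[which.min(cand[best])]
  n_even <- cand[j]
  g_even <- g_cand[j]

  # the no-trial branch wins on ties (fewer patients exposed)
  if (g_even <= no_trial$utility + refine_tol * max(abs(no_trial$utility), 1)) {
    return(new_voi_design(model, no_trial, trial = NULL, z_convention = z_convention))
  }

  trial <- list(
    n_star = n_even, g_star = g_even,
    n_continuous = n_cont, g_continuous = g_cont,
    z_continuous = optimal_z(model, n_cont),
    z_even = optimal_z(model, n_even)
  )
  new_voi_design(model, no_trial, trial = trial, z_convention = z_convention)
}

new_voi_design <- function(model, no_trial, trial, z_convention, note = NULL) {
  if (is.null(trial)) {
    z_star <- switch(no_trial$decision,
      approve = -Inf,
      do_not_approve = Inf,
      indifferent = NA_real_
    )
    out <- list(
      n_star = 0, z_star = z_star,
      alpha_star = if (is.na(z_star)) NA_real_ else 1 - pnorm(z_star),
      g_star = no_trial$utility,
      no_trial = TRUE,
      approve_without_trial = no_trial$decision,
      n_continuous = 0, z_continuous = z_star, g_continuous = no_trial$utility,
      g_no_trial = no_trial$utility,
      z_convention = z_convention, note = note, model = model
    )
  } else {
    z_star <- if (z_convention == "continuous") trial$z_continuous else trial$z_even
    out <- list(
      n_star = trial$n_star, z_star = z_star,
      alpha_star = 1 - pnorm(z_star),
      g_star = trial$g_star,
      no_trial = FALSE,
      approve_without_trial = NA_character_,
      n_continuous = trial$n_continuous,
      z_continuous = trial$z_continuous,
      g_continuous = trial$g_continuous,
      g_no_trial = no_trial$utility,
      z_convention = z_convention, note = note, model = model
    )
  }
  structure(out, class = "voi_design")
}

#' @export
print.voi_design <- function(x, ...) {
  cat("<voi_design>  value-of-information optimal trial design\n")
  if (x$no_trial) {
    cat(sprintf(
      "  no trial (n* = 0); prior-only decision: %s\n",
      x$approve_without_trial
    ))
  } else {
    cat(sprintf(
      "  n* = %d patients (%d per arm); z* = %.5f (alpha* = %.5f, %s-n convention)\n",
      as.integer(x$n_star), as.integer(x$n_star / 2),
      x$z_star, x$alpha_star, x$z_convention
    ))
  }
  cat(sprintf(
    "  expected utility: $%.2f million (no-trial alternative: $%.2f million)\n",
    x$g_star / 1e6, x$g_no_trial / 1e6
  ))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @rdname optimize_design
#' @param x A `voi_design` object.
#' @param ... Unused; for generic consistency.
#' @method tidy voi_design
#' @export
tidy.voi_design <- function(x, ...) {
  tibble(
    n_star = x$n_star,
    z_star = x$z_star,
    alpha_star = x$alpha_star,
    g_star = x$g_star,
    no_trial = x$no_trial,
    approve_without_trial = x$approve_without_trial
  )
}

#' @rdname optimize_design
#' @method glance voi_design
#' @export
glance.voi_design <- function(x, ...) {
  tibble(
    n_star = x$n_star,
    z_star = x$z_star,
    alpha_star = x$alpha_star,
    g_star = x$g_star,
    g_no_trial = x$g_no_trial,
    n_continuous = x$n_continuous,
    z_continuous = x$z_continuous,
    g_continuous = x$g_continuous,
    no_trial = x$no_trial,
    z_convention = x$z_convention
  )
}

#' Conventional power-calculation sample size
#'
#' The standard two-arm normal sample-size formula for a one-sided test:
#' the smallest even total `n` with
#' \eqn{n \ge (z_{1-\alpha} + z_{1-\beta})^2 \tau^2 / \theta_A^2}, giving
#' one-sided type I error `alpha` and type II error `beta` at the
#' alternative `theta_a`.
#'
#' @param alpha One-sided type I error rate, in `(0, 1)`.
#' @param beta Type II error rate at the alternative, in `(0, 1)`.
#' @param theta_a Monetary alternative effect ($), non-zero.
#' @param tau Sampling standard-deviation scale ($), positive: the observed
#'   mean difference has standard deviation `tau / sqrt(n)`.
#' @return The smallest adequate even total sample size (integer).
#' @examples
#' conventional_sample_size(0.025, 0.8, theta_a = 24819, tau = 363202)
#' @export
conventional_sample_size <- function(alpha, beta, theta_a, tau) {
  check_scalar_num(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  if (alpha >= 1) abort("`alpha` must be < 1.", class = "voitrial_domain_error")
  check_scalar_num(beta, "beta", lower = 0, upper = 1, strict = TRUE)
  if (beta >= 1) abort("`beta` must be < 1.", class = "voitrial_domain_error")
  check_scalar_num(theta_a, "theta_a")
  if (theta_a == 0) abort("`theta_a` must be non-zero.", class = "voitrial_domain_error")
  check_scalar_num(tau, "tau", lower = 0, strict = TRUE)
  z_sum <- qnorm(1 - alpha) + qnorm(1 - beta)
  if (z_sum <= 0) {
    abort(
      "`alpha` + `beta` too large: the sample-size formula yields a non-positive n.",
      class = "voitrial_domain_error"
    )
  }
  n_raw <- z_sum^2 * tau^2 / theta_a^2
  as.integer(2 * ceiling(n_raw / 2))
}

#' Conventional comparator design and its expected utility
#'
#' Builds the conventional frequentist design for a scenario — sample size
#' from [conventional_sample_size()], threshold `qnorm(1 - alpha)` — and
#' evaluates its decision-theoretic expected utility under the same model,
#' for comparison with [optimize_design()].
#'
#' @inheritParams conventional_sample_size
#' @param model A [trial_model()].
#' @param theta_a Monetary alternative effect; defaults to half the prior
#'   standard deviation, `sqrt(sigma0_sq) / 2`.
#' @return A one-row tibble: `n`, `z_alpha`, `alpha`, `beta`, `theta_a`,
#'   `g` (expected utility, $).
#' @examples
#' conventional_design(haemophilia_model(), alpha = 0.025, beta = 0.8)
#' @export
conventional_design <- function(model, alpha = 0.025, beta = 0.8, theta_a = NULL) {
  stop_not_model(model)
  if (is.null(theta_a)) theta_a <- sqrt(model$sigma0_sq) / 2
  tau <- sqrt(model$tau_sq)
  n <- conventional_sample_size(alpha, beta, theta_a, tau)
  z <- qnorm(1 - alpha)
  tibble(
    n = n, z_alpha = z, alpha = alpha, beta = beta, theta_a = theta_a,
    g = expected_utility(model, n, z)
  )
}
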