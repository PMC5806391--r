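#' Specify a trial design scenario
#'
#' A `trial_model` collects every parameter of the decision-theoretic design
#' problem: the normal prior on the monetary treatment effect, the sampling
#' variance of the observed mean difference, the size of the addressable
#' population, the trial enrollment proportion, and the monetary costs. All
#' monetary quantities share one currency unit (dollars in the bundled case
#' study); the effect \eqn{\theta} is the per-patient benefit of the
#' experimental over the standard treatment on that scale.
#'
#' The sampling model is a 1:1 randomised two-arm trial of total size `n`
#' whose observed mean difference \eqn{\bar x} is normal with mean
#' \eqn{\theta} and variance `tau_sq / n`. The prior is
#' \eqn{\theta \sim N(\mu_0, \sigma_0^2)}. While the trial runs, a proportion
#' `rho` of concurrent patients is enrolled, so a trial of size `n` consumes
#' `n / rho` patients of the population `N`, leaving `N - n / rho` to be
#' treated according to the approval decision.
#'
#' @param mu0 Prior mean of the monetary treatment effect ($).
#' @param sigma0_sq Prior variance of the effect ($^2), `>= 0`.
#' @param tau_sq Sampling variance scale ($^2): `var(xbar) = tau_sq / n`.
#'   Must be positive.
#' @param N Total addressable population size (patients), `>= 1`.
#' @param rho Proportion of concurrent patients enrolled in the trial,
#'   in `(0, 1]`.
#' @param c1 Per-patient trial cost ($/patient), `>= 0`.
#' @param c2 Per-patient non-trial cost (or monetised harm) of the
#'   experimental treatment ($/patient). May be negative in principle.
#' @param cf Fixed trial cost ($), incurred only when a trial is run
#'   (`n > 0`), `>= 0`.
#'
#' @return An object of class `trial_model`: a named list of the validated
#'   parameters.
#'
#' @examples
#' m <- trial_model(
#'   mu0 = 96000, sigma0_sq = 49638^2, tau_sq = 363202^2,
#'   N = 4000, rho = 0.2, c1 = 5000, c2 = 61032, cf = 1e6
#' )
#' m
#' @export
trial_model <- function(mu0, sigma0_sq, tau_sq, N, rho, c1, c2, cf) {
  check_scalar_num(mu0, "mu0")
  check_scalar_num(sigma0_sq, "sigma0_sq", lower = 0)
  check_scalar_num(tau_sq, "tau_sq", lower = 0, strict = TRUE)
  check_scalar_num(N, "N", lower = 1)
  if (abs(N - round(N)) > 1e-8) {
    abort("`N` must be a whole number of patients.", class = "voitrial_domain_error")
  }
  check_scalar_num(rho, "rho", lower = 0, upper = 1, strict = TRUE)
  check_scalar_num(c1, "c1", lower = 0)
  check_scalar_num(c2, "c2")
  check_scalar_num(cf, "cf", lower = 0)
  structure(
    list(
      mu0 = as.numeric(mu0), sigma0_sq = as.numeric(sigma0_sq),
      tau_sq = as.numeric(tau_sq), N = round(as.numeric(N)),
      rho = as.numeric(rho), c1 = as.numeric(c1), c2 = as.numeric(c2),
      cf = as.numeric(cf)
    ),
    class = "trial_model"
  )
}

## scalar numeric validation; `strict` makes `lower` an open bound
check_scalar_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    abort(
      sprintf("`%s` must be a single finite number.", name),
      class = "voitrial_domain_error"
    )
  }
  ok <- if (strict) x > lower && x <= upper else x >= lower && x <= upper
  if (!ok) {
    abort(
      sprintf(
        "`%s` = %g is outside its admissible range %s%g, %g].",
        name, x, if (strict) "(" else "[", lower, upper
      ),
      class = "voitrial_domain_error"
    )
  }
  invisible(x)
}

#' @export
print.trial_model <- function(x, ...) {
  cat("<trial_model>\n")
  cat(sprintf("  effect prior     : theta ~ N(%g, %g^2)  [$]\n", x$mu0, sqrt(x$sigma0_sq)))
  cat(sprintf("  sampling scale   : var(xbar) = %g^2 / n  [$^2]\n", sqrt(x$tau_sq)))
  cat(sprintf("  population       : N = %g patients, enrollment rho = %g\n", x$N, x$rho))
  cat(sprintf(
    "  costs            : c1 = %g, c2 = %g, cf = %g  [$]\n",
    x$c1, x$c2, x$cf
  ))
  invisible(x)
}

is_trial_model <- function(x) inherits(x, "trial_model")

stop_not_model <- function(model) {
  if (!is_trial_model(model)) {
    abort("`model` must be a `trial_model` object.", class = "voitrial_domain_error")
  }
  invisible(model)
}

#' Prior-predictive standard deviation of the observed mean difference
#'
#' Before any data are seen, the observed mean difference of a trial of size
#' `n` is marginally normal with mean `mu0` and standard deviation
#' \eqn{\sigma_x = \sqrt{\sigma_0^2 + \tau^2 / n}}. This scale standardises
#' the approval threshold inside the closed-form expected utility.
#'
#' @param model A [trial_model()].
#' @param n Total trial sample size(s), positive. Vectorised.
#'
#' @return Numeric vector of prior-predictive standard deviations ($).
#' @examples
#' m <- haemophilia_model()
#' prior_predictive_sd(m, 46)
#' @export
prior_predictive_sd <- function(model, n) {
  stop_not_model(model)
  if (length(n) == 0 || any(!is.finite(n)) || any(n <= 0)) {
    abort(
      "`n` must be positive: the prior-predictive scale is undefined at n = 0.",
      class = "voitrial_domain_error"
    )
  }
  sqrt(model$sigma0_sq + model$tau_sq / n)
}

check_design_n <- function(model, n, even = TRUE) {
  if (any(!is.finite(n)) || any(n < 0)) {
    abort("`n` must be a finite non-negative sample size.", class = "voitrial_domain_error")
  }
  if (even && any(abs(n - 2 * round(n / 2)) > 1e-8)) {
    abort(
      "`n` must be even: patients are randomised 1:1, n/2 per arm.",
      class = "voitrial_domain_error"
    )
  }
  if (any(n > model$rho * model$N + 1e-9)) {
    abort(
      sprintf(
        "`n` exceeds rho * N = %g: the trial would consume more than the whole population.",
        model$rho * model$N
      ),
      class = "voitrial_domain_error"
    )
  }
  invisible(n)
}

#' Utility of a trial outcome at a known effect size
#'
#' The realised (pointwise) utility of running a trial of size `n`, reaching
#' decision `d`, when the true monetary effect is `theta`. Utilities are
#' relative to treating everyone with the standard treatment. Approval
#' (`"reject"` of the null) treats the `n/2` trial patients on the
#' experimental arm plus the `N - n/rho` patients remaining after the trial;
#' non-approval treats only the `n/2` trial patients. Per-patient trial costs
#' `c1 * n` always accrue, and the fixed cost `cf` accrues whenever a trial
#' is run at all.
#'
#' @param model A [trial_model()].
#' @param n Total trial sample size: a single even integer `>= 0` with
#'   `n <= rho * N`.
#' @param decision `"reject"` (approve the experimental treatment) or
#'   `"not_reject"`.
#' @param theta True monetary effect size(s) ($); vectorised. Negative values
#'   represent harm and are not truncated.
#'
#' @return Numeric vector of utilities ($), one per `theta`.
#' @examples
#' m <- haemophilia_model()
#' pointwise_utility(m, 46, "reject", 96000)
#' pointwise_utility(m, 46, "not_reject", 96000)
#' @export
pointwise_utility <- function(model, n, decision = c("reject", "not_reject"), theta) {
  stop_not_model(model)
  decision <- arg_match(decision)
  if (length(n) != 1L) abort("`n` must be a single sample size.", class = "voitrial_domain_error")
  check_design_n(model, n)
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    abort("`theta` must be finite numeric.", class = "voitrial_domain_error")
  }
  treated <- if (decision == "reject") {
    model$N - n / model$rho + n / 2
  } else {
    n / 2
  }
  (theta - model$c2) * treated - model$c1 * n - model$cf * (n > 0)
}

#' Closed-form expected utility of a candidate design
#'
#' The preposterior expected utility \eqn{\mathcal{G}(n, z_\alpha)} of a
#' design that runs a trial of size `n` and approves the experimental
#' treatment when the observed mean difference exceeds
#' \eqn{z_\alpha \tau / \sqrt n}. Expectation is over both the prior on the
#' effect and the sampling distribution of the observed difference:
#' \deqn{\mathcal{G}(n, z_\alpha) = (N - n/\rho)\{(\mu_0 - c_2)\Phi(-Z) +
#'   (\sigma_0^2/\sigma_x)\phi(Z)\} + (n/2)(\mu_0 - c_2) - c_1 n - c_f,}
#' with \eqn{Z = (z_\alpha \tau/\sqrt n - \mu_0)/\sigma_x} the threshold
#' standardised on the prior-predictive scale.
#'
#' `n` need not be an even integer here: the continuous relaxation is what
#' the optimiser's refinement step maximises. At `n = 0` no data arrive and
#' the decision is forced by the sign convention on `z_alpha`: any
#' `z_alpha < 0` (including `-Inf`) means the threshold lies at minus
#' infinity, so the treatment is approved on prior belief alone, giving
#' `N * (mu0 - c2)`; `z_alpha >= 0` (including `Inf`) means it is never
#' approved, giving 0. No fixed cost accrues at `n = 0`.
#'
#' @param model A [trial_model()].
#' @param n Trial sample size(s) `>= 0`, real-valued; vectorised (recycled
#'   against `z_alpha`).
#' @param z_alpha Significance threshold(s) on the standard-normal scale;
#'   `+/-Inf` allowed.
#'
#' @return Numeric vector of expected utilities ($).
#' @examples
#' m <- haemophilia_model()
#' expected_utility(m, 46, 0.36876) / 1e6 # ~ $141M
#' expected_utility(m, 268, qnorm(0.975)) / 1e6 # ~ $110M
#' @export
expected_utility <- function(model, n, z_alpha) {
  stop_not_model(model)
  if (length(n) == 0 || length(z_alpha) == 0) {
    abort("`n` and `z_alpha` must be non-empty.", class = "voitrial_domain_error")
  }
  check_design_n(model, n, even = FALSE)
  k <- max(length(n), length(z_alpha))
  n <- rep_len(as.numeric(n), k)
  z_alpha <- rep_len(as.numeric(z_alpha), k)
  out <- numeric(k)

  zero <- n == 0
  if (any(zero)) {
    approve <- z_alpha[zero] < 0
    out[zero] <- ifelse(approve, model$N * (model$mu0 - model$c2), 0)
  }
  if (any(!zero)) {
    np <- n[!zero]
    zp <- z_alpha[!zero]
    sx <- sqrt(model$sigma0_sq + model$tau_sq / np)
    Z <- (zp * sqrt(model$tau_sq / np) - model$mu0) / sx
    future <- model$N - np / model$rho
    out[!zero] <- future * ((model$mu0 - model$c2) * pnorm(-Z) +
      model$sigma0_sq / sx * dnorm(Z)) +
      np / 2 * (model$mu0 - model$c2) - model$c1 * np - model$cf
  }
  out
}

#' Expected utility and decision when no trial is run
#'
#' With no trial the decision rests on the prior alone: approve when the
#' prior mean benefit exceeds the treatment cost (`mu0 > c2`), in which case
#' the whole population is treated for an expected gain of `N * (mu0 - c2)`;
#' otherwise keep the standard treatment for utility 0. At exact indifference
#' (`mu0 == c2`) both actions are worth 0 and the decision is flagged
#' `"indifferent"` (the reporting thresholds are then conventionally
#' `+Inf` or `-Inf`).
#'
#' @param model A [trial_model()].
#' @return A list with elements `utility` (the maximal no-trial expected
#'   utility, `max(N * (mu0 - c2), 0)`) and `decision` (`"approve"`,
#'   `"do_not_approve"`, or `"indifferent"`).
#' @examples
#' expected_utility_no_trial(haemophilia_model())
#' @export
expected_utility_no_trial <- function(model) {
  stop_not_model(model)
  gain <- model$N * (model$mu0 - model$c2)
  decision <- if (model$mu0 > model$c2) {
    "approve"
  } else if (model$mu0 < model$c2) {
    "do_not_approve"
  } else {
    "indifferent"
  }
  list(utility = max(gain, 0), decision = decision)
}
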