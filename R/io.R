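## Scenario configuration files, bundled fixtures, and the report-level
## entry points wrapped by the command-line script in inst/cli/.

# model parameters, all in dollars (or dollars^2) except N and rho
model_keys <- c("mu0", "sigma0_sq", "tau_sq", "N", "rho", "c1", "c2", "cf")
# optional scalar settings
option_scalar_keys <- c(
  "theta_a", "conventional_alpha", "conventional_beta",
  "n", "z_alpha", "mc_replicates", "mc_seed"
)
# optional comma-separated numeric lists
option_list_keys <- c("sweep_N", "sweep_c2", "threshold_c2")

#' Read and write scenario configuration files
#'
#' Scenarios are stored as flat `key: value` text (Debian Control File
#' format, read with [read.dcf()]). The eight [trial_model()] parameters are
#' required; optional keys configure downstream commands: `theta_a`
#' (alternative effect, $), `conventional_alpha` / `conventional_beta`
#' (comparator error rates), `n` / `z_alpha` (an explicit design for
#' validation), `mc_replicates` / `mc_seed` (Monte Carlo settings), and the
#' comma-separated lists `sweep_N`, `sweep_c2`, `threshold_c2`. Unknown keys
#' are rejected by name. Numbers are written in full precision, so a
#' written scenario re-reads to an identical model.
#'
#' @param path File path.
#' @return `read_scenario()` returns a `voi_scenario`: a list with elements
#'   `model` (a validated [trial_model()]) and `options` (named list of the
#'   optional settings present). `write_scenario()` returns `path`
#'   invisibly.
#' @examples
#' path <- tempfile(fileext = ".dcf")
#' write_scenario(haemophilia_model(), path)
#' read_scenario(path)$model
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scenario file not found: %s", path), class = "voitrial_io_error")
  }
  raw <- read.dcf(path)
  if (nrow(raw) != 1L) {
    abort("scenario file must contain exactly one record.", class = "voitrial_io_error")
  }
  kv <- as.list(raw[1, ])
  unknown <- setdiff(names(kv), c(model_keys, option_scalar_keys, option_list_keys))
  if (length(unknown) > 0) {
    abort(
      sprintf("unknown scenario key(s): %s", paste(unknown, collapse = ", ")),
      class = "voitrial_io_error"
    )
  }
  missing <- setdiff(model_keys, names(kv))
  if (length(missing) > 0) {
    abort(
      sprintf("missing required key(s): %s", paste(missing, collapse = ", ")),
      class = "voitrial_io_error"
    )
  }
  num <- function(key, value) {
    x <- suppressWarnings(as.numeric(strsplit(value, ",")[[1]]))
    if (length(x) == 0 || any(is.na(x))) {
      abort(sprintf("key `%s` is not numeric: %s", key, value), class = "voitrial_io_error")
    }
    x
  }
  vals <- Map(num, names(kv), kv)
  model <- inject(trial_model(!!!vals[model_keys]))
  options <- vals[intersect(names(vals), c(option_scalar_keys, option_list_keys))]
  new_scenario(model, options)
}

new_scenario <- function(model, options = list()) {
  structure(list(model = model, options = options), class = "voi_scenario")
}

#' @rdname read_scenario
#' @param x A [trial_model()] or a `voi_scenario`.
#' @export
write_scenario <- function(x, path) {
  scenario <- as_scenario(x)
  fields <- c(
    lapply(unclass(scenario$model), format, digits = 17),
    lapply(scenario$options, function(v) paste(format(v, digits = 17), collapse = ","))
  )
  write.dcf(as.data.frame(fields, check.names = FALSE), file = path)
  invisible(path)
}

as_scenario <- function(x) {
  if (inherits(x, "voi_scenario")) {
    x
  } else if (is_trial_model(x)) {
    new_scenario(x)
  } else if (is.character(x) && length(x) == 1L) {
    read_scenario(x)
  } else {
    abort(
      "expected a trial_model, a voi_scenario, or a path to a scenario file.",
      class = "voitrial_io_error"
    )
  }
}

#' Bundled scenario fixtures
#'
#' `voi_fixtures()` lists the scenario files shipped with the package;
#' `load_fixture(name)` reads one by name. Bundled: `"haemophilia-od-tp"`,
#' the on-demand vs tailored-prophylaxis haemophilia A scenario of
#' [haemophilia_model()] with its sweep/comparator settings, and
#' `"haemophilia-arms"` (a CSV of the arm-level summaries, see
#' [haemophilia_arms()]).
#'
#' @param name Fixture name, without extension.
#' @return `voi_fixtures()`: character vector of names. `load_fixture()`: a
#'   `voi_scenario` for `.dcf` fixtures, a tibble for `.csv` fixtures.
#' @examples
#' voi_fixtures()
#' load_fixture("haemophilia-od-tp")$model
#' @export
voi_fixtures <- function() {
  dir <- system.file("extdata", package = "voitrial")
  sub("\\.(dcf|csv)$", "", list.files(dir, pattern = "\\.(dcf|csv)$"))
}

#' @rdname voi_fixtures
#' @export
load_fixture <- function(name) {
  dir <- system.file("extdata", package = "voitrial")
  dcf <- file.path(dir, paste0(name, ".dcf"))
  csv <- file.path(dir, paste0(name, ".csv"))
  if (file.exists(dcf)) {
    read_scenario(dcf)
  } else if (file.exists(csv)) {
    as_tibble(utils::read.csv(csv))
  } else {
    abort(
      sprintf(
        "unknown fixture `%s`; available: %s", name,
        paste(voi_fixtures(), collapse = ", ")
      ),
      class = "voitrial_io_error"
    )
  }
}

#' Optimise a scenario and report the design
#'
#' High-level wrapper: optimises the design for a scenario and assembles a
#' report with the optimal design, its operating characteristics at
#' `theta_a`, the no-trial alternative, and (when `conventional_alpha` and
#' `conventional_beta` are configured) the conventional power-calculation
#' comparator. This is the engine behind the `optimize` subcommand of the
#' bundled CLI script.
#'
#' @param scenario A [trial_model()], a `voi_scenario`, or a path to a
#'   scenario file.
#' @param ... Passed on to [optimize_design()].
#' @return A `voi_report` list: `parameters`, `theta_a`, `optimal`,
#'   `no_trial`, and optionally `conventional`; all monetary fields in full
#'   precision plus a `*_millions` rendering. Printable; serialise with
#'   [jsonlite::toJSON()].
#' @examples
#' run_optimize(haemophilia_model())
#' @export
run_optimize <- function(scenario, ...) {
  scenario <- as_scenario(scenario)
  model <- scenario$model
  opts <- scenario$options
  theta_a <- opts$theta_a %||% (sqrt(model$sigma0_sq) / 2)
  fit <- optimize_design(model, ...)
  oc <- oc_of_design(fit$n_star, fit$z_star, sqrt(model$tau_sq), theta_a)
  report <- list(
    parameters = unclass(model),
    theta_a = theta_a,
    optimal = list(
      n_star = fit$n_star, z_star = fit$z_star, alpha_star = fit$alpha_star,
      beta_star = oc$beta, g_star = fit$g_star,
      g_star_millions = fit$g_star / 1e6,
      n_continuous = fit$n_continuous, z_continuous = fit$z_continuous,
      no_trial = fit$no_trial, approve_without_trial = fit$approve_without_trial
    ),
    no_trial = expected_utility_no_trial(model)
  )
  if (!is.null(opts$conventional_alpha) && !is.null(opts$conventional_beta)) {
    conv <- conventional_design(
      model,
      alpha = opts$conventional_alpha,
      beta = opts$conventional_beta, theta_a = theta_a
    )
    report$conventional <- c(as.list(conv), list(g_millions = conv$g / 1e6))
  }
  structure(report, class = "voi_report")
}

#' @export
print.voi_report <- function(x, ...) {
  cat("Value-of-information design report\n")
  o <- x$optimal
  if (o$no_trial) {
    cat(sprintf(
      "  optimal: no trial (n* = 0); prior-only decision: %s\n",
      x$no_trial$decision
    ))
  } else {
    cat(sprintf(
      "  optimal: n* = %d (%d/arm), z* = %.5f, alpha* = %.5f, beta*(theta_a) = %.5f\n",
      as.integer(o$n_star), as.integer(o$n_star / 2), o$z_star, o$alpha_star, o$beta_star
    ))
  }
  cat(sprintf("  expected utility: $%.2f million\n", o$g_star_millions))
  cat(sprintf(
    "  no-trial alternative: $%.2f million (%s)\n",
    x$no_trial$utility / 1e6, x$no_trial$decision
  ))
  if (!is.null(x$conventional)) {
    cv <- x$conventional
    cat(sprintf(
      "  conventional (alpha = %g, beta = %g at theta_a = %g): n = %d, utility $%.2f million\n",
      cv$alpha, cv$beta, cv$theta_a, as.integer(cv$n), cv$g_millions
    ))
  }
  invisible(x)
}

#' Sweep a scenario over population sizes and treatment costs
#'
#' Engine behind the CLI `sweep` subcommand: runs [sweep_designs()] with
#' the grids configured in the scenario (`sweep_N`, required; `sweep_c2`,
#' defaulting to the model's `c2`).
#'
#' @inheritParams run_optimize
#' @return A `voi_sweep` tibble (see [sweep_designs()]).
#' @examples
#' run_sweep(haemophilia_model(), N = c(1000, 4000, 16000))
#' @export
run_sweep <- function(scenario, ...) {
  scenario <- as_scenario(scenario)
  dots <- list(...)
  N <- dots$N %||% scenario$options$sweep_N
  if (is.null(N)) {
    abort("`sweep_N` is not configured for this scenario.", class = "voitrial_io_error")
  }
  c2 <- dots$c2 %||% scenario$options$sweep_c2 %||% scenario$model$c2
  theta_a <- dots$theta_a %||% scenario$options$theta_a
  sweep_designs(scenario$model, N = N, c2 = c2, theta_a = theta_a)
}

#' No-trial population thresholds for a scenario
#'
#' Engine behind the CLI `threshold` subcommand: for each treatment cost in
#' `threshold_c2` (or the model's own `c2`), locates the smallest
#' population size at which running a trial becomes optimal.
#'
#' @inheritParams run_optimize
#' @param c2 Optional vector of treatment costs, overriding the scenario's
#'   `threshold_c2`.
#' @return A tibble, one row per cost (see [find_population_threshold()]).
#' @examples
#' run_threshold(haemophilia_model())
#' @export
run_threshold <- function(scenario, c2 = NULL, ...) {
  scenario <- as_scenario(scenario)
  c2 <- c2 %||% scenario$options$threshold_c2 %||% scenario$model$c2
  purrr::map(c2, function(cost) {
    find_population_threshold(scenario$model, c2 = cost, ...)
  }) |> dplyr::bind_rows()
}

#' Validate the closed-form expected utility by simulation
#'
#' Engine behind the CLI `validate` subcommand: simulates the configured
#' design (`n` / `z_alpha` in the scenario options, else the optimal
#' design) and compares the Monte Carlo mean utility with the closed form.
#' The discrepancy is reported as a z-score in Monte Carlo standard errors;
#' agreement within 3 SE passes.
#'
#' @inheritParams run_optimize
#' @param replicates,seed Override the scenario's `mc_replicates` (default
#'   `1e5`) and `mc_seed` (default 1).
#' @return A `voi_validation` list: `n`, `z_alpha`, `closed_form`,
#'   `mc_estimate`, `std_error`, `z_score`, `pass`, `replicates`, `seed`.
#' @examples
#' run_validate(haemophilia_model(), replicates = 1e4)
#' @export
run_validate <- function(scenario, replicates = NULL, seed = NULL) {
  scenario <- as_scenario(scenario)
  model <- scenario$model
  opts <- scenario$options
  replicates <- replicates %||% opts$mc_replicates %||% 1e5
  seed <- seed %||% opts$mc_seed %||% 1
  if (!is.null(opts$n) && !is.null(opts$z_alpha)) {
    n <- opts$n
    z <- opts$z_alpha
  } else {
    fit <- optimize_design(model)
    if (fit$no_trial) {
      abort(
        "the optimal design runs no trial; configure `n` and `z_alpha` to validate a design.",
        class = "voitrial_domain_error"
      )
    }
    n <- fit$n_star
    z <- fit$z_star
  }
  if (n == 0) {
    abort(
      "`n` = 0 cannot be validated by simulation; use expected_utility_no_trial().",
      class = "voitrial_domain_error"
    )
  }
  sim <- simulate_expected_utility(model, n, z, replicates = replicates, seed = seed)
  g <- expected_utility(model, n, z)
  z_score <- (sim$mean_utility - g) / sim$std_error
  structure(
    list(
      n = n, z_alpha = z, closed_form = g,
      mc_estimate = sim$mean_utility, std_error = sim$std_error,
      z_score = z_score, pass = abs(z_score) <= 3,
      replicates = sim$replicates, seed = sim$seed
    ),
    class = "voi_validation"
  )
}

#' @export
print.voi_validation <- function(x, ...) {
  cat("Monte Carlo validation of the closed-form expected utility\n")
  cat(sprintf("  design        : n = %g, z_alpha = %.5f\n", x$n, x$z_alpha))
  cat(sprintf("  closed form   : $%.4f million\n", x$closed_form / 1e6))
  cat(sprintf(
    "  simulation    : $%.4f million (SE $%.4f million, %d replicates, seed %d)\n",
    x$mc_estimate / 1e6, x$std_error / 1e6, x$replicates, x$seed
  ))
  cat(sprintf(
    "  discrepancy   : %.2f SE -> %s\n", x$z_score,
    if (x$pass) "PASS (within 3 SE)" else "FAIL (outside 3 SE)"
  ))
  invisible(x)
}
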