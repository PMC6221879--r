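# Scenario-level population-average interaction coefficients.
.scenario_b_bar <- c(-0.08, -0.05, 0, 0.05, 0.08)

#' Simulation parameters
#'
#' Bundle all population and structural parameters of the model. The defaults
#' are the standard study conditions: mean growth of 10 g per time step,
#' additive genetic variance 1 g^2, permanent and temporary environmental
#' variances 0.4 and 0.6 g^2, and equal direct/indirect genetic and
#' environmental variances of 0.225e-3 for the interaction coefficient b.
#' Five canonical scenarios differ only in the population-average coefficient
#' \code{b_bar}: -0.08, -0.05, 0, 0.05, 0.08 (strong/moderate competition,
#' neutral, moderate/strong cooperation).
#'
#' @param scenario Optional integer 1..5 selecting one of the canonical
#'   scenarios; sets \code{b_bar} accordingly.
#' @param b_bar Population-average interaction coefficient (per g of weight
#'   difference). Negative values mean competition, positive cooperation.
#' @param mu_gr Mean growth rate per time step (g).
#' @param var_a_gr Additive genetic variance of growth rate (g^2).
#' @param var_ep_gr Permanent environmental variance of growth rate (g^2).
#' @param var_et_gr Temporary environmental variance of growth rate (g^2),
#'   redrawn independently at every time step.
#' @param var_ad,var_ai Direct and indirect additive genetic variances of b.
#' @param var_ed,var_ei Direct and indirect environmental variances of b.
#' @param start_weight_mean Mean body weight at time 0 (g).
#' @param start_weight_sd Standard deviation of body weight at time 0 (g).
#'   The default, sqrt(2) g, equals the phenotypic SD of a single growth
#'   step (excluding b), so "an initial difference of ~2 sd" is well defined.
#' @param n_sires,n_dams_per_sire,n_offspring_per_dam Hierarchical half-sib
#'   family design of each generation. The default 100 x 40 x 2 yields 8000
#'   individuals in 4000 pairs with 80 offspring per sire, large enough for
#'   sire-family variability statistics to stabilise over 100 replicates.
#' @param n_time_points Number of growth increments; weights are stored at
#'   time points 0..\code{n_time_points}.
#' @param n_replicates Default number of Monte-Carlo replicates.
#' @param grouping Group-assignment policy, \code{"non_sib"} (default; full
#'   and half sibs may not share a pair) or \code{"random"}.
#' @return An object of class \code{sim_params} (a named list). The derived
#'   fields \code{n_individuals} and \code{n_groups} give the cohort size
#'   and pair count; \code{var_p_gr} is the phenotypic variance of a single
#'   growth step computed excluding b.
#' @export
#' @examples
#' p <- sim_params(scenario = 1)
#' p$b_bar      # -0.08
#' p$n_groups   # 4000
sim_params <- function(scenario = NULL,
                       b_bar = 0,
                       mu_gr = 10,
                       var_a_gr = 1,
                       var_ep_gr = 0.4,
                       var_et_gr = 0.6,
                       var_ad = 0.225e-3,
                       var_ai = 0.225e-3,
                       var_ed = 0.225e-3,
                       var_ei = 0.225e-3,
                       start_weight_mean = 10,
                       start_weight_sd = sqrt(2),
                       n_sires = 100,
                       n_dams_per_sire = 40,
                       n_offspring_per_dam = 2,
                       n_time_points = 10,
                       n_replicates = 100,
                       grouping = c("non_sib", "random")) {
  if (!is.null(scenario)) {
    if (!(is.numeric(scenario) && length(scenario) == 1L &&
          scenario %in% 1:5)) {
      stop("'scenario' must be an integer in 1..5", call. = FALSE)
    }
    b_bar <- .scenario_b_bar[scenario]
  }
  grouping <- match.arg(grouping)
  p <- list(
    b_bar = b_bar, mu_gr = mu_gr,
    var_a_gr = var_a_gr, var_ep_gr = var_ep_gr, var_et_gr = var_et_gr,
    var_ad = var_ad, var_ai = var_ai, var_ed = var_ed, var_ei = var_ei,
    start_weight_mean = start_weight_mean, start_weight_sd = start_weight_sd,
    n_sires = as.integer(n_sires),
    n_dams_per_sire = as.integer(n_dams_per_sire),
    n_offspring_per_dam = as.integer(n_offspring_per_dam),
    n_time_points = as.integer(n_time_points),
    n_replicates = as.integer(n_replicates),
    grouping = grouping,
    scenario = if (is.null(scenario)) NA_integer_ else as.integer(scenario)
  )
  vars <- c("var_a_gr", "var_ep_gr", "var_et_gr",
            "var_ad", "var_ai", "var_ed", "var_ei")
  for (v in vars) {
    if (!is.finite(p[[v]]) || p[[v]] < 0) {
      stop("'", v, "' must be a finite non-negative number", call. = FALSE)
    }
  }
  for (v in c("b_bar", "mu_gr", "start_weight_mean")) {
    if (!is.finite(p[[v]])) stop("'", v, "' must be finite", call. = FALSE)
  }
  if (!is.finite(p$start_weight_sd) || p$start_weight_sd < 0) {
    stop("'start_weight_sd' must be a finite non-negative number",
         call. = FALSE)
  }
  if (p$n_time_points < 1L) stop("'n_time_points' must be >= 1",
                                 call. = FALSE)
  if (p$n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (p$n_sires < 1L || p$n_dams_per_sire < 1L || p$n_offspring_per_dam < 1L) {
    stop("family design counts must all be >= 1", call. = FALSE)
  }
  p$n_individuals <- p$n_sires * p$n_dams_per_sire * p$n_offspring_per_dam
  if (p$n_individuals %% 2L != 0L) {
    stop("family design must produce an even number of offspring ",
         "(got ", p$n_individuals, "); pairs cannot be formed", call. = FALSE)
  }
  p$n_groups <- p$n_individuals %/% 2L
  p$var_p_gr <- p$var_a_gr + p$var_ep_gr + p$var_et_gr
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters",
      if (!is.na(x$scenario)) sprintf("(scenario %d)", x$scenario), "\n")
  cat(sprintf("  b_bar = %g, mu_GR = %g g/step\n", x$b_bar, x$mu_gr))
  cat(sprintf("  growth variances (A, Ep, Et): %g, %g, %g g^2 (P: %g g^2)\n",
              x$var_a_gr, x$var_ep_gr, x$var_et_gr, x$var_p_gr))
  cat(sprintf("  b variances (A_D, A_I, E_D, E_I): %g, %g, %g, %g\n",
              x$var_ad, x$var_ai, x$var_ed, x$var_ei))
  cat(sprintf("  start weight: %g +/- %g g\n",
              x$start_weight_mean, x$start_weight_sd))
  cat(sprintf("  family design: %d sires x %d dams x %d offspring = %d (%d pairs)\n",
              x$n_sires, x$n_dams_per_sire, x$n_offspring_per_dam,
              x$n_individuals, x$n_groups))
  cat(sprintf("  %d time points, %d replicates, grouping = %s\n",
              x$n_time_points, x$n_replicates, x$grouping))
  invisible(x)
}

#' Canonical scenario parameter sets
#'
#' @param scenarios Integer vector of scenario ids (subset of 1..5).
#' @param ... Overrides passed on to [sim_params()] for every scenario.
#' @return Named list of \code{sim_params}, one per scenario.
#' @export
default_scenarios <- function(scenarios = 1:5, ...) {
  out <- lapply(scenarios, function(s) sim_params(scenario = s, ...))
  names(out) <- paste0("scenario_", scenarios)
  out
}

#' Read scenario configurations from a YAML file
#'
#' The file has an optional \code{default} mapping of parameter overrides
#' applied to every scenario, and a \code{scenarios} mapping whose entries
#' hold per-scenario overrides (at minimum \code{b_bar}). The configuration
#' shipped with the package (\code{system.file("extdata", "scenarios.yaml",
#' package = "igevar")}) encodes the five canonical scenarios.
#'
#' @param path Path to the YAML file; defaults to the shipped configuration.
#' @return Named list of \code{sim_params}.
#' @export
read_scenario_config <- function(path = system.file("extdata",
                                                    "scenarios.yaml",
                                                    package = "igevar")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) {
    stop("config file has no 'scenarios' section: ", path, call. = FALSE)
  }
  base <- cfg$default
  out <- lapply(cfg$scenarios, function(sc) {
    args <- utils::modifyList(if (is.null(base)) list() else base,
                              if (is.null(sc)) list() else sc)
    do.call(sim_params, args)
  })
  names(out) <- names(cfg$scenarios)
  out
}

#' Derive a reproducible replicate seed
#'
#' Counter-based derivation so that replicate r of stream s always gets the
#' same seed regardless of execution order. All randomness in scenario and
#' selection runs flows through this function.
#'
#' @param seed Master integer seed.
#' @param replicate Replicate counter (>= 1).
#' @param stream Optional stream id (e.g. scenario number) separating
#'   independent experiment arms.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
replicate_seed <- function(seed, replicate, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(seed) %% m) + 1
  x <- (x * 48271 + as.double(stream) * 104729 +
          as.double(replicate) * 16807) %% m
  as.integer(x %% (m - 1)) + 1L
}
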