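#' Run one scenario of the simulation study
#'
#' For each replicate: sample a base population under the family design,
#' assign pairs, simulate the weight trajectories, and collect the
#' variability statistics ([cohort_stats()]) and sire-level variability
#' correlations ([sire_variability_correlations()]) at the final time point.
#' Replicate r uses \code{replicate_seed(seed, r, stream)}, so results do not
#' depend on execution order.
#'
#' @param params A \code{\link{sim_params}} object, or an integer 1..5
#'   selecting a canonical scenario.
#' @param n_replicates Number of Monte-Carlo replicates; defaults to
#'   \code{params$n_replicates}.
#' @param seed Master integer seed.
#' @param stream RNG stream id; defaults to the scenario number (or 0).
#' @param sire_correlations Set \code{FALSE} to skip the sire-level
#'   statistics (faster).
#' @return An object of class \code{scenario_result}: \code{$replicates} is a
#'   data frame with one row per replicate (within/between/phenotypic
#'   variance, rho, cv, and the four sire correlations), \code{$aggregate}
#'   holds their means and SDs.
#' @export
run_scenario <- function(params, n_replicates = NULL, seed = 1L,
                         stream = NULL, sire_correlations = TRUE) {
  if (is.numeric(params) && length(params) == 1L) {
    params <- sim_params(scenario = params)
  }
  if (is.null(n_replicates)) n_replicates <- params$n_replicates
  if (is.null(stream)) {
    stream <- if (is.na(params$scenario)) 0L else params$scenario
  }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r, stream))
    cohort <- sample_base_population(params)
    cohort <- simulate_trajectories(cohort, params)
    st <- cohort_stats(cohort)
    row <- data.frame(replicate = r, within = st$within,
                      between = st$between, phenotypic = st$phenotypic,
                      rho = st$rho, cv = st$cv)
    if (sire_correlations) {
      sc <- sire_variability_correlations(cohort)
      row <- cbind(row, as.data.frame(as.list(sc)))
    }
    rows[[r]] <- row
  }
  reps <- do.call(rbind, rows)
  stats_cols <- setdiff(names(reps), "replicate")
  agg <- data.frame(
    statistic = stats_cols,
    mean = vapply(reps[stats_cols], mean, 0),
    sd = vapply(reps[stats_cols], stats::sd, 0),
    row.names = NULL)
  structure(list(params = params, b_bar = params$b_bar, seed = seed,
                 n_replicates = n_replicates, replicates = reps,
                 aggregate = agg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "scenario result: b_bar = %g, %d replicates of %d pairs x %d steps\n",
    x$b_bar, x$n_replicates, x$params$n_groups, x$params$n_time_points))
  a <- x$aggregate
  fmt <- function(s) {
    i <- match(s, a$statistic)
    sprintf("%.4g (sd %.3g)", a$mean[i], a$sd[i])
  }
  cat("  within-group variance:", fmt("within"), "g^2\n")
  cat("  phenotypic variance:  ", fmt("phenotypic"), "g^2\n")
  cat("  group-mate correlation:", fmt("rho"), "\n")
  if ("r_ad_off" %in% a$statistic) {
    cat("  r(sire A_D, VarP_off):", fmt("r_ad_off"),
        " r(sire A_I, VarP_gm):", fmt("r_ai_gm"), "\n")
  }
  invisible(x)
}

#' Run several scenarios
#'
#' @param scenarios Integer vector of canonical scenario ids, or a named list
#'   of \code{\link{sim_params}}.
#' @param n_replicates Replicates per scenario (default: from each params).
#' @param seed Master seed; each scenario uses its own RNG stream.
#' @param ... Passed to [run_scenario()].
#' @return An object of class \code{scenario_suite} (list of
#'   \code{scenario_result} plus a cross-scenario summary table
#'   \code{$summary}).
#' @export
run_scenario_suite <- function(scenarios = 1:5, n_replicates = NULL,
                               seed = 1L, ...) {
  if (!is.list(scenarios)) {
    scenarios <- default_scenarios(scenarios)
  }
  results <- vector("list", length(scenarios))
  for (k in seq_along(scenarios)) {
    results[[k]] <- run_scenario(scenarios[[k]], n_replicates = n_replicates,
                                 seed = seed, stream = k, ...)
  }
  names(results) <- names(scenarios)
  summ <- do.call(rbind, lapply(seq_along(results), function(k) {
    a <- results[[k]]$aggregate
    out <- data.frame(scenario = names(results)[k],
                      b_bar = results[[k]]$b_bar)
    for (i in seq_len(nrow(a))) {
      out[[a$statistic[i]]] <- a$mean[i]
      out[[paste0(a$statistic[i], "_sd")]] <- a$sd[i]
    }
    out
  }))
  structure(list(results = results, summary = summ, seed = seed),
            class = "scenario_suite")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat("scenario suite (", length(x$results), " scenarios)\n", sep = "")
  cols <- intersect(c("scenario", "b_bar", "within", "phenotypic", "rho",
                      "r_ad_off"), names(x$summary))
  print(x$summary[, cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write replicate-level scenario results as a delimited table
#'
#' One row per (scenario, replicate), followed by aggregate rows marked
#' \code{"mean"} and \code{"sd"} in the \code{replicate} column.
#'
#' @param x A \code{scenario_result} or \code{scenario_suite}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_scenario_table <- function(x, path) {
  block <- function(res, label) {
    reps <- res$replicates
    reps$replicate <- as.character(reps$replicate)
    agg <- res$aggregate
    for (what in c("mean", "sd")) {
      row <- as.data.frame(as.list(stats::setNames(agg[[what]],
                                                   agg$statistic)))
      row <- cbind(replicate = what, row)
      reps <- rbind(reps, row)
    }
    cbind(scenario = label, b_bar = res$b_bar, reps)
  }
  tab <- if (inherits(x, "scenario_suite")) {
    do.call(rbind, lapply(names(x$results),
                          function(nm) block(x$results[[nm]], nm)))
  } else {
    block(x, if (is.na(x$params$scenario)) "custom"
          else paste0("scenario_", x$params$scenario))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the package version, resolved parameters, master seed,
#' per-replicate seeds and MD5 checksums of the output files; re-running
#' with the same manifest reproduces identical checksums.
#'
#' @param path Manifest output path (.json).
#' @param params A \code{\link{sim_params}} object.
#' @param seed Master seed.
#' @param n_replicates Replicate count.
#' @param stream RNG stream id.
#' @param files Character vector of output files to checksum.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, params, seed, n_replicates,
                               stream = 0L, files = character()) {
  manifest <- list(
    tool = "igevar",
    version = as.character(utils::packageVersion("igevar")),
    seed = seed,
    stream = stream,
    replicate_seeds = vapply(seq_len(n_replicates),
                             function(r) replicate_seed(seed, r, stream),
                             integer(1)),
    params = unclass(params),
    outputs = if (length(files)) {
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
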