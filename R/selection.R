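#' Select parents from a simulated cohort
#'
#' Truncation selection on final weight under three schemes:
#' \code{"individual"} takes the heaviest individuals;
#' \code{"group_mean"} takes all members of the groups with the highest mean
#' weight; \code{"group_variance"} takes all members of the groups with the
#' lowest within-group variance (most uniform pairs). Counts are
#' \code{round(proportion x units)} with a floor of 2 individuals (1 group);
#' ties are broken by id for determinism.
#'
#' @param cohort A simulated, grouped \code{cohort}.
#' @param scheme Selection scheme.
#' @param proportion Fraction of units (individuals or groups) selected.
#' @param time_point Time point used for ranking; \code{NULL} for the last.
#' @return Integer vector of selected row indices into \code{cohort$ind}.
#' @export
select_parents <- function(cohort,
                           scheme = c("individual", "group_mean",
                                      "group_variance"),
                           proportion = 0.11, time_point = NULL) {
  scheme <- match.arg(scheme)
  if (!(is.numeric(proportion) && proportion > 0 && proportion <= 1)) {
    stop("'proportion' must be in (0, 1]", call. = FALSE)
  }
  w <- cohort_weights(cohort, time_point)
  if (scheme == "individual") {
    k <- max(2L, round(proportion * length(w)))
    ord <- order(-w, cohort$ind$id)
    return(sort(ord[seq_len(k)]))
  }
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  first <- which(seq_along(cohort$partner) < cohort$partner)
  crit <- if (scheme == "group_mean") {
    -(w[first] + w[cohort$partner[first]]) / 2
  } else {
    (w[first] - w[cohort$partner[first]])^2 # monotone in pair variance
  }
  kg <- max(1L, round(proportion * length(first)))
  ord <- order(crit, cohort$ind$id[first])
  sel_first <- first[ord[seq_len(kg)]]
  sort(c(sel_first, cohort$partner[sel_first]))
}

# Mate selected parents and produce the next generation at full population
# size. Each selected female is mated to a randomly drawn selected male
# (males may serve several dams); offspring are allocated to dams as evenly
# as possible.
.next_generation <- function(cohort, selected, params, generation) {
  sel <- cohort$ind[selected, ]
  males <- which(sel$sex == "M")
  females <- which(sel$sex == "F")
  if (length(males) < 1L || length(females) < 1L) {
    stop("selection left no ", if (length(males) < 1L) "sires" else "dams",
         " in generation ", generation, call. = FALSE)
  }
  n <- params$n_individuals
  nd <- length(females)
  # even allocation: distribute the remainder over randomly chosen dams
  n_per_dam <- rep(n %/% nd, nd)
  if (n %% nd > 0L) {
    bump <- sample.int(nd, n %% nd)
    n_per_dam[bump] <- n_per_dam[bump] + 1L
  }
  dam_idx <- rep(seq_len(nd), times = n_per_dam)
  sire_of_dam <- sample(males, nd, replace = TRUE)
  sire_idx <- sire_of_dam[dam_idx]
  eff <- .make_offspring_multi(sel, sel, sire_idx, dam_idx, params)
  w0 <- stats::rnorm(n, params$start_weight_mean, params$start_weight_sd)
  max_id <- max(cohort$ind$id)
  make_cohort(eff, w0,
              sire = sel$id[sire_idx], dam = sel$id[dam_idx],
              sex = sample(c("M", "F"), n, replace = TRUE),
              id = max_id + seq_len(n), generation = generation,
              parents = data.frame(id = sel$id, a_gr = sel$a_gr,
                                   e_p_gr = sel$e_p_gr, a_d = sel$a_d,
                                   e_d = sel$e_d, a_i = sel$a_i,
                                   e_i = sel$e_i,
                                   role = ifelse(sel$sex == "M", "sire",
                                                 "dam")))
}

# Per-generation summary used in the selection trajectories.
.generation_stats <- function(cohort) {
  c(mean_weight = mean(cohort_weights(cohort)),
    within_var = within_group_variance(cohort),
    mean_b = mean(cohort$b),
    mean_a_d = mean(cohort$ind$a_d),
    mean_a_i = mean(cohort$ind$a_i),
    mean_a_gr = mean(cohort$ind$a_gr))
}

#' Run a multi-generation selection experiment
#'
#' Per generation: simulate the cohort's weight trajectories, record the
#' population state (mean final weight, within-group variance, realised mean
#' b, mean A_D, A_I, A_GR), select parents under the scheme, and mate them at
#' random to restore the population size. Individuals are sexed 1:1 at
#' birth; selected males serve as sires, selected females as dams. Offspring
#' of selected parents are paired at random (sibs allowed) each generation.
#' Replicates run on independent, order-independent seed streams.
#'
#' @param params A \code{\link{sim_params}} object (base scenario; strong
#'   competition, scenario 1, in the canonical experiment).
#' @param scheme Selection scheme, see [select_parents()].
#' @param proportion Fraction of units selected each generation.
#' @param n_generations Number of selection rounds.
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @param stream RNG stream id (defaults to a scheme-specific offset).
#' @return An object of class \code{selection_experiment}:
#'   \code{$trajectories} is a data frame (replicate, generation, the six
#'   statistics), \code{$mean_trajectory} the per-generation average over
#'   replicates.
#' @export
run_selection_experiment <- function(params = sim_params(scenario = 1),
                                     scheme = c("individual", "group_mean",
                                                "group_variance"),
                                     proportion = 0.11,
                                     n_generations = 10,
                                     n_replicates = params$n_replicates,
                                     seed = 1L, stream = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(stream)) {
    stream <- 100L + match(scheme, c("individual", "group_mean",
                                     "group_variance"))
  }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r, stream))
    cohort <- sample_base_population(params)
    traj <- matrix(NA_real_, n_generations + 1L, 6L)
    for (g in 0:n_generations) {
      cohort <- simulate_trajectories(cohort, params)
      traj[g + 1L, ] <- .generation_stats(cohort)
      if (g == n_generations) break
      sel <- select_parents(cohort, scheme, proportion)
      cohort <- .next_generation(cohort, sel, params, generation = g + 1L)
      cohort <- assign_groups(cohort, params, policy = "random")
    }
    colnames(traj) <- c("mean_weight", "within_var", "mean_b", "mean_a_d",
                        "mean_a_i", "mean_a_gr")
    rows[[r]] <- cbind(data.frame(replicate = r,
                                  generation = 0:n_generations),
                       as.data.frame(traj))
  }
  traj <- do.call(rbind, rows)
  stats_cols <- setdiff(names(traj), c("replicate", "generation"))
  mt <- stats::aggregate(traj[stats_cols],
                         by = list(generation = traj$generation), mean)
  structure(list(scheme = scheme, proportion = proportion,
                 n_generations = n_generations, n_replicates = n_replicates,
                 params = params, seed = seed,
                 trajectories = traj, mean_trajectory = mt),
            class = "selection_experiment")
}

#' @export
print.selection_experiment <- function(x, ...) {
  cat(sprintf(
    "selection experiment: %s scheme, %.0f%% selected, %d generations, %d replicates\n",
    x$scheme, 100 * x$proportion, x$n_generations, x$n_replicates))
  mt <- x$mean_trajectory
  first <- mt[1L, ]
  last <- mt[nrow(mt), ]
  for (s in c("mean_weight", "within_var", "mean_b", "mean_a_d", "mean_a_i",
              "mean_a_gr")) {
    cat(sprintf("  %-11s %10.4g -> %10.4g\n", s, first[[s]], last[[s]]))
  }
  invisible(x)
}

#' Write selection trajectories as a delimited table
#'
#' Replicate-level rows followed by per-generation means (replicate =
#' \code{"mean"}).
#'
#' @param x A \code{selection_experiment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_selection_table <- function(x, path) {
  reps <- x$trajectories
  reps$replicate <- as.character(reps$replicate)
  mt <- cbind(replicate = "mean", x$mean_trajectory)
  tab <- cbind(scheme = x$scheme, rbind(reps, mt))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
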