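# Draw a data frame of independent lifetime effects from the base variances.
.draw_effects <- function(n, params, genetic = TRUE, environmental = TRUE) {
  z <- function(v, on) if (on && v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
  data.frame(
    a_gr   = z(params$var_a_gr, genetic),
    e_p_gr = z(params$var_ep_gr, environmental),
    a_d    = z(params$var_ad, genetic),
    e_d    = z(params$var_ed, environmental),
    a_i    = z(params$var_ai, genetic),
    e_i    = z(params$var_ei, environmental)
  )
}

#' Produce offspring by Mendelian inheritance
#'
#' Each of the three breeding values (growth rate, direct b, indirect b) is
#' the parental midpoint plus an independent Mendelian-sampling deviate
#' ~ Normal(0, half the corresponding base additive variance); the
#' non-inbred, unrelated-parents formula is used throughout. Environmental
#' effects are drawn fresh from the base environmental variances.
#'
#' @param sire,dam Single-row data frames (or named lists) with the parents'
#'   breeding values \code{a_gr, a_d, a_i} and ids (\code{id}).
#' @param params A \code{\link{sim_params}} object.
#' @param n Number of offspring to produce.
#' @return Data frame with one row per offspring: effects, \code{sire},
#'   \code{dam}.
#' @export
#' @examples
#' p <- sim_params(var_a_gr = 0)
#' s <- list(id = 1, a_gr = 0.02, a_d = 0, a_i = 0)
#' d <- list(id = 2, a_gr = 0.04, a_d = 0, a_i = 0)
#' make_offspring(s, d, p)$a_gr  # 0.03 exactly
make_offspring <- function(sire, dam, params, n = 1L) {
  ms <- function(v) if (v > 0) stats::rnorm(n, 0, sqrt(v / 2)) else numeric(n)
  env <- function(v) if (v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
  data.frame(
    a_gr   = (sire$a_gr + dam$a_gr) / 2 + ms(params$var_a_gr),
    e_p_gr = env(params$var_ep_gr),
    a_d    = (sire$a_d + dam$a_d) / 2 + ms(params$var_ad),
    e_d    = env(params$var_ed),
    a_i    = (sire$a_i + dam$a_i) / 2 + ms(params$var_ai),
    e_i    = env(params$var_ei),
    sire   = rep(sire$id, n),
    dam    = rep(dam$id, n)
  )
}

# Vectorised offspring generation: sire_idx/dam_idx are row indices into the
# parent effect tables; one offspring per entry.
.make_offspring_multi <- function(sires, dams, sire_idx, dam_idx, params) {
  n <- length(sire_idx)
  ms <- function(v) if (v > 0) stats::rnorm(n, 0, sqrt(v / 2)) else numeric(n)
  env <- function(v) if (v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
  data.frame(
    a_gr   = (sires$a_gr[sire_idx] + dams$a_gr[dam_idx]) / 2 +
      ms(params$var_a_gr),
    e_p_gr = env(params$var_ep_gr),
    a_d    = (sires$a_d[sire_idx] + dams$a_d[dam_idx]) / 2 + ms(params$var_ad),
    e_d    = env(params$var_ed),
    a_i    = (sires$a_i[sire_idx] + dams$a_i[dam_idx]) / 2 + ms(params$var_ai),
    e_i    = env(params$var_ei)
  )
}

#' Sample a base population
#'
#' Creates unrelated base sires and dams with mutually independent effects
#' (all correlations among the breeding values are zero), mates each sire to
#' \code{n_dams_per_sire} dams (hierarchical half-sib design), produces
#' offspring by [make_offspring()] arithmetic, draws initial weights
#' ~ Normal(\code{start_weight_mean}, \code{start_weight_sd}^2), assigns
#' random sexes 1:1, and pairs the offspring with [assign_groups()] under the
#' policy in \code{params}.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param grouped If \code{FALSE}, skip pair assignment.
#' @return A grouped \code{cohort} of the offspring generation; the parent
#'   effects are kept in \code{$parents} (with \code{role} column) for
#'   sire-level statistics.
#' @export
sample_base_population <- function(params, grouped = TRUE) {
  ns <- params$n_sires
  nd <- ns * params$n_dams_per_sire
  sires <- cbind(id = seq_len(ns), .draw_effects(ns, params))
  dams <- cbind(id = ns + seq_len(nd), .draw_effects(nd, params))
  dam_sire <- rep(seq_len(ns), each = params$n_dams_per_sire)

  n <- params$n_individuals
  off_dam <- rep(seq_len(nd), each = params$n_offspring_per_dam)
  off_sire <- dam_sire[off_dam]
  eff <- .make_offspring_multi(sires, dams, off_sire, off_dam, params)
  w0 <- stats::rnorm(n, params$start_weight_mean, params$start_weight_sd)
  cohort <- make_cohort(
    eff, w0,
    sire = sires$id[off_sire], dam = dams$id[off_dam],
    sex = sample(c("M", "F"), n, replace = TRUE),
    id = ns + nd + seq_len(n), generation = 0L,
    parents = rbind(cbind(sires, role = "sire"), cbind(dams, role = "dam"))
  )
  if (grouped) cohort <- assign_groups(cohort, params) else cohort
}

#' Assign individuals to random 2-member groups
#'
#' Draws a uniform random perfect matching of the cohort. Under policy
#' \code{"non_sib"}, full and half sibs (shared sire or shared dam) may not
#' share a group; conflicting pairs are repaired by bounded re-shuffling.
#' Interaction coefficients b are computed for both members of every pair at
#' assignment time and held constant over the trajectory.
#'
#' @param cohort A \code{cohort} (simulation not yet started).
#' @param params A \code{\link{sim_params}} object (supplies \code{b_bar} and
#'   the default policy).
#' @param policy \code{"random"} or \code{"non_sib"}; defaults to
#'   \code{params$grouping}.
#' @param max_retries Repair iterations before giving up on a non-sib
#'   matching.
#' @return The cohort with groups and b values installed.
#' @export
assign_groups <- function(cohort, params, policy = params$grouping,
                          max_retries = 1000L) {
  policy <- match.arg(policy, c("non_sib", "random"))
  n <- nrow(cohort$ind)
  if (n %% 2L != 0L) {
    stop("cannot pair an odd number of individuals (", n, ")", call. = FALSE)
  }
  if (n_steps_simulated(cohort) > 0L) {
    stop("cohort already has simulated weights; cannot regroup",
         call. = FALSE)
  }
  perm <- sample.int(n)
  if (policy == "non_sib") {
    sire <- cohort$ind$sire
    dam <- cohort$ind$dam
    if (all(is.na(sire)) && all(is.na(dam))) {
      stop("non-sib grouping requires pedigree information", call. = FALSE)
    }
    sib <- function(a, b) {
      (!is.na(sire[a]) & !is.na(sire[b]) & sire[a] == sire[b]) |
        (!is.na(dam[a]) & !is.na(dam[b]) & dam[a] == dam[b])
    }
    for (iter in seq_len(max_retries)) {
      i <- perm[seq(1L, n, 2L)]
      j <- perm[seq(2L, n, 2L)]
      bad <- which(sib(i, j))
      if (length(bad) == 0L) break
      # Re-shuffle the members of conflicting pairs together with an equal
      # number of randomly chosen other individuals, so repairs cannot stall
      # on a small residual clique of sibs.
      stuck <- c(i[bad], j[bad])
      extra <- sample(setdiff(perm, stuck),
                      min(n - length(stuck), 2L * length(bad)))
      pool <- c(stuck, extra)
      perm[match(pool, perm)] <- sample(pool)
      if (iter == max_retries) {
        stop("could not find a non-sib matching after ", max_retries,
             " repair rounds", call. = FALSE)
      }
    }
  }
  gid <- integer(n)
  gid[perm] <- rep(seq_len(n %/% 2L), each = 2L)
  .set_groups(cohort, gid, b_bar = params$b_bar)
}

#' Pairs of a cohort as a data frame
#'
#' One row per group with member ids/rows, both interaction coefficients, the
#' initial weight difference and (if simulated) both final weights.
#'
#' @param cohort A grouped \code{cohort}.
#' @return Data frame with columns \code{group, row_i, row_j, id_i, id_j,
#'   b_ij, b_ji, d0, w_i, w_j}.
#' @export
cohort_groups <- function(cohort) {
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  first <- which(seq_along(cohort$partner) < cohort$partner)
  i <- first
  j <- cohort$partner[first]
  wT <- cohort_weights(cohort)
  data.frame(
    group = cohort$group_id[i],
    row_i = i, row_j = j,
    id_i = cohort$ind$id[i], id_j = cohort$ind$id[j],
    b_ij = cohort$b[i], b_ji = cohort$b[j],
    d0 = cohort$W[i, 1L] - cohort$W[j, 1L],
    w_i = wT[i], w_j = wT[j]
  )
}

# ---------------------------------------------------------------------------
# Delimited-text writers/readers (tab separated, one header line).

#' Write a 3-column pedigree file
#'
#' Tab-delimited \code{id, sire, dam} for parents (0 for unknown) and
#' offspring of a cohort.
#'
#' @param cohort A \code{cohort}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(cohort, path) {
  ped <- data.frame(id = cohort$ind$id,
                    sire = ifelse(is.na(cohort$ind$sire), 0L,
                                  cohort$ind$sire),
                    dam = ifelse(is.na(cohort$ind$dam), 0L, cohort$ind$dam))
  if (!is.null(cohort$parents)) {
    base <- data.frame(id = cohort$parents$id, sire = 0L, dam = 0L)
    ped <- rbind(base, ped)
  }
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort as a tidy delimited table
#'
#' Long format: one row per individual per time point, with pedigree, sex,
#' group, the six lifetime effects and the individual's own b value repeated
#' on every row. The format round-trips through [read_cohort_table()].
#'
#' @param cohort A grouped, simulated \code{cohort}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  n <- nrow(cohort$ind)
  tp <- 0:n_steps_simulated(cohort)
  out <- data.frame(
    generation = cohort$generation,
    id = rep(cohort$ind$id, each = length(tp)),
    sire = rep(ifelse(is.na(cohort$ind$sire), 0L, cohort$ind$sire),
               each = length(tp)),
    dam = rep(ifelse(is.na(cohort$ind$dam), 0L, cohort$ind$dam),
              each = length(tp)),
    sex = rep(cohort$ind$sex, each = length(tp)),
    group = rep(cohort$group_id, each = length(tp)),
    time_point = rep(tp, n),
    weight = as.vector(t(cohort$W)),
    a_gr = rep(cohort$ind$a_gr, each = length(tp)),
    e_p_gr = rep(cohort$ind$e_p_gr, each = length(tp)),
    a_d = rep(cohort$ind$a_d, each = length(tp)),
    e_d = rep(cohort$ind$e_d, each = length(tp)),
    a_i = rep(cohort$ind$a_i, each = length(tp)),
    e_i = rep(cohort$ind$e_i, each = length(tp)),
    b_value = rep(cohort$b, each = length(tp))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort back from a tidy delimited table
#'
#' @param path File written by [write_cohort_table()].
#' @return A \code{cohort} with groups, b values and weight trajectories.
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d <- d[order(d$id, d$time_point), ]
  ids <- unique(d$id)
  first <- d[!duplicated(d$id), ]
  tp <- sort(unique(d$time_point))
  W <- matrix(d$weight, nrow = length(ids), ncol = length(tp), byrow = TRUE)
  cohort <- make_cohort(
    first[, c("a_gr", "e_p_gr", "a_d", "e_d", "a_i", "e_i")],
    W[, 1L],
    sire = ifelse(first$sire == 0L, NA_integer_, first$sire),
    dam = ifelse(first$dam == 0L, NA_integer_, first$dam),
    sex = first$sex, id = first$id,
    generation = first$generation[1L]
  )
  cohort <- .set_groups(cohort, first$group, b_bar = 0,
                        b_values = first$b_value)
  cohort$W <- W
  cohort
}
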