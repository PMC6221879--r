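#' Lifetime effects of an individual
#'
#' The six effects drawn once per individual and constant over its lifetime:
#' breeding value and permanent environmental effect for growth rate, and the
#' direct (own b) and indirect (group mate's b) genetic and environmental
#' effects on the interaction coefficient. The temporary growth effect is not
#' part of this set; it is redrawn at every time step.
#'
#' @param a_gr Breeding value for growth rate (g).
#' @param e_p_gr Permanent environmental effect on growth rate (g).
#' @param a_d Direct breeding value for b (resistance to competition).
#' @param e_d Direct environmental effect on b.
#' @param a_i Indirect breeding value for b (cooperativeness).
#' @param e_i Indirect environmental effect on b.
#' @return An object of class \code{effect_set}.
#' @export
#' @examples
#' effect_set(a_d = 0.03, a_i = 0.03)
effect_set <- function(a_gr = 0, e_p_gr = 0, a_d = 0, e_d = 0,
                       a_i = 0, e_i = 0) {
  x <- list(a_gr = a_gr, e_p_gr = e_p_gr, a_d = a_d, e_d = e_d,
            a_i = a_i, e_i = e_i)
  bad <- !vapply(x, function(v) is.numeric(v) && all(is.finite(v)), TRUE)
  if (any(bad)) {
    stop("non-finite effect value(s): ", paste(names(x)[bad], collapse = ", "),
         call. = FALSE)
  }
  structure(x, class = "effect_set")
}

#' @export
print.effect_set <- function(x, ...) {
  cat(sprintf(
    "effect set: A_GR=%g Ep=%g | A_D=%g E_D=%g A_I=%g E_I=%g\n",
    x$a_gr, x$e_p_gr, x$a_d, x$e_d, x$a_i, x$e_i))
  invisible(x)
}

#' Interaction coefficient of a focal individual
#'
#' The b value acting on the focal individual's growth:
#' \code{b_bar + A_D(focal) + E_D(focal) + A_I(partner) + E_I(partner)}.
#' The coefficient is non-symmetric: swapping focal and partner gives the
#' group mate's coefficient, which in general differs.
#'
#' @param b_bar Population-average interaction coefficient.
#' @param focal,partner \code{\link{effect_set}} objects (or lists with the
#'   same fields) for the focal individual and its group mate.
#' @return The focal individual's b value (dimensionless, per g).
#' @export
#' @examples
#' compute_b(-0.05, effect_set(a_d = 0.03), effect_set(a_i = 0.03)) # 0.01
compute_b <- function(b_bar, focal, partner) {
  vals <- c(b_bar, focal$a_d, focal$e_d, partner$a_i, partner$e_i)
  if (length(vals) != 5L || !all(is.finite(vals))) {
    stop("compute_b: all inputs must be finite scalars", call. = FALSE)
  }
  b_bar + focal$a_d + focal$e_d + partner$a_i + partner$e_i
}

#' One-step growth increment of a focal individual
#'
#' Deterministic growth equation for the step from time t-1 to t:
#' \code{mu_gr + a_gr + e_p + e_t + b * (partner_prev_weight -
#' focal_prev_weight)}. All arguments may be vectors of common length; the
#' function is pure (no randomness).
#'
#' @param mu_gr Mean growth rate (g).
#' @param a_gr Breeding value for growth rate (g).
#' @param e_p Permanent environmental effect (g).
#' @param e_t Temporary environmental effect at this step (g).
#' @param b Interaction coefficient acting on the focal individual.
#' @param partner_prev_weight,focal_prev_weight Body weights at the previous
#'   time point (g).
#' @return Growth increment(s) in g.
#' @export
#' @examples
#' growth_increment(0, 0, 0, 0, b = 0.01,
#'                  partner_prev_weight = 12, focal_prev_weight = 10) # 0.02
growth_increment <- function(mu_gr, a_gr, e_p, e_t, b,
                             partner_prev_weight, focal_prev_weight) {
  args <- list(mu_gr, a_gr, e_p, e_t, b,
               partner_prev_weight, focal_prev_weight)
  if (!all(vapply(args, function(v) is.numeric(v) && all(is.finite(v)), TRUE))) {
    stop("growth_increment: all inputs must be finite numerics",
         call. = FALSE)
  }
  mu_gr + a_gr + e_p + e_t + b * (partner_prev_weight - focal_prev_weight)
}

# ---------------------------------------------------------------------------
# Cohort container: one generation of paired individuals.

#' Build a cohort from explicit effects and weights
#'
#' Low-level constructor for a generation of individuals. Individuals are
#' given as a data frame of lifetime effects; pairs (if any) as a group-id
#' vector mapping each individual to a 2-member group. Each individual's own
#' interaction coefficient is computed from the effects via
#' \code{\link{compute_b}} unless overridden through \code{b_values}.
#'
#' @param effects Data frame with numeric columns \code{a_gr, e_p_gr, a_d,
#'   e_d, a_i, e_i}, one row per individual.
#' @param start_weights Numeric vector of weights at time 0 (g).
#' @param group_id Optional integer vector assigning each individual to a
#'   group; every group must have exactly 2 members. If \code{NULL} the
#'   cohort is ungrouped (use [assign_groups()] before simulating).
#' @param b_bar Population-average interaction coefficient used when deriving
#'   b values from the effects.
#' @param b_values Optional explicit b values (the coefficient acting on each
#'   individual), bypassing the effects-based computation.
#' @param sire,dam Optional parent ids (\code{NA} for base individuals).
#' @param sex Optional sex codes (\code{"M"}/\code{"F"}).
#' @param id Optional individual ids; defaults to 1..n.
#' @param generation Generation index (0 for the base generation).
#' @param parents Optional data frame describing the parents (columns
#'   \code{id, a_gr, e_p_gr, a_d, e_d, a_i, e_i}), kept for sire-level
#'   statistics.
#' @return An object of class \code{cohort}.
#' @export
make_cohort <- function(effects, start_weights, group_id = NULL, b_bar = 0,
                        b_values = NULL, sire = NA_integer_,
                        dam = NA_integer_, sex = NA_character_,
                        id = NULL, generation = 0L, parents = NULL) {
  need <- c("a_gr", "e_p_gr", "a_d", "e_d", "a_i", "e_i")
  if (!all(need %in% names(effects))) {
    stop("'effects' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(effects)
  if (length(start_weights) != n || !all(is.finite(start_weights))) {
    stop("'start_weights' must be ", n, " finite values", call. = FALSE)
  }
  ind <- data.frame(
    id = if (is.null(id)) seq_len(n) else id,
    sire = rep_len(sire, n), dam = rep_len(dam, n),
    sex = rep_len(sex, n),
    effects[, need, drop = FALSE]
  )
  x <- structure(
    list(generation = as.integer(generation), ind = ind,
         group_id = NULL, partner = NULL, b = NULL,
         W = matrix(as.numeric(start_weights), ncol = 1L),
         parents = parents),
    class = "cohort")
  if (!is.null(group_id)) {
    x <- .set_groups(x, group_id, b_bar = b_bar, b_values = b_values)
  }
  x
}

# Install a pairing into a cohort and compute per-individual b values.
.set_groups <- function(cohort, group_id, b_bar, b_values = NULL) {
  n <- nrow(cohort$ind)
  if (length(group_id) != n) {
    stop("'group_id' must have one entry per individual", call. = FALSE)
  }
  tab <- table(group_id)
  if (any(tab != 2L)) {
    stop("every group must have exactly 2 members", call. = FALSE)
  }
  ord <- order(group_id, seq_len(n))
  partner <- integer(n)
  first <- ord[seq(1L, n, 2L)]
  second <- ord[seq(2L, n, 2L)]
  partner[first] <- second
  partner[second] <- first
  cohort$group_id <- as.integer(factor(group_id))
  cohort$partner <- partner
  if (is.null(b_values)) {
    e <- cohort$ind
    cohort$b <- b_bar + e$a_d + e$e_d + e$a_i[partner] + e$e_i[partner]
  } else {
    if (length(b_values) != n || !all(is.finite(b_values))) {
      stop("'b_values' must be ", n, " finite values", call. = FALSE)
    }
    cohort$b <- as.numeric(b_values)
  }
  cohort
}

#' Build a single 2-member group as a cohort
#'
#' Convenience wrapper around [make_cohort()] for worked examples and the
#' analytic oracle: one pair, optionally with explicit interaction
#' coefficients \code{b_ij} (acting on member i) and \code{b_ji}.
#'
#' @param focal,partner \code{\link{effect_set}}s of the two members.
#' @param w0_focal,w0_partner Initial weights (g).
#' @param b_bar Population-average interaction coefficient.
#' @param b_ij,b_ji Optional explicit coefficients; both or neither.
#' @return A \code{cohort} with one group; member i is row 1.
#' @export
#' @examples
#' g <- make_pair_cohort(effect_set(), effect_set(), 9, 11, b_bar = -0.08)
#' g$b  # both coefficients equal b_bar
make_pair_cohort <- function(focal, partner, w0_focal, w0_partner,
                             b_bar = 0, b_ij = NULL, b_ji = NULL) {
  eff <- rbind(as.data.frame(unclass(focal)),
               as.data.frame(unclass(partner)))
  bv <- NULL
  if (!is.null(b_ij) || !is.null(b_ji)) {
    if (is.null(b_ij) || is.null(b_ji)) {
      stop("provide both 'b_ij' and 'b_ji' or neither", call. = FALSE)
    }
    bv <- c(b_ij, b_ji)
  }
  make_cohort(eff, c(w0_focal, w0_partner), group_id = c(1L, 1L),
              b_bar = b_bar, b_values = bv)
}

#' Number of simulated growth increments in a cohort
#' @param cohort A \code{cohort}.
#' @return Integer count of increments simulated so far (0 for a fresh one).
#' @export
n_steps_simulated <- function(cohort) ncol(cohort$W) - 1L

# Weight column for a time point (0-based), with bounds checking.
.time_col <- function(cohort, time_point) {
  if (is.null(time_point)) time_point <- n_steps_simulated(cohort)
  if (time_point < 0 || time_point > n_steps_simulated(cohort)) {
    stop("time point ", time_point, " not simulated (have 0..",
         n_steps_simulated(cohort), ")", call. = FALSE)
  }
  as.integer(time_point) + 1L
}

#' Weights of a cohort at a time point
#' @param cohort A \code{cohort}.
#' @param time_point Time point 0..T; \code{NULL} for the latest.
#' @return Numeric vector of body weights (g).
#' @export
cohort_weights <- function(cohort, time_point = NULL) {
  cohort$W[, .time_col(cohort, time_point)]
}

#' Advance a cohort by one time point
#'
#' Applies the growth equation synchronously to all individuals: both members
#' of every pair use the weights of the previous time point, each with its
#' own interaction coefficient, plus a fresh temporary environmental draw
#' ~ Normal(0, \code{var_et_gr}) per individual. Uses the current RNG state.
#'
#' @param cohort A grouped \code{cohort}.
#' @param params A \code{\link{sim_params}} object (supplies \code{mu_gr} and
#'   \code{var_et_gr}; b values are fixed at grouping time).
#' @return The cohort with one more weight column.
#' @export
advance_time_point <- function(cohort, params) {
  if (is.null(cohort$partner)) {
    stop("cohort has no groups; call assign_groups() first", call. = FALSE)
  }
  w <- cohort$W[, ncol(cohort$W)]
  n <- length(w)
  e_t <- if (params$var_et_gr > 0) {
    stats::rnorm(n, 0, sqrt(params$var_et_gr))
  } else {
    numeric(n)
  }
  inc <- growth_increment(params$mu_gr, cohort$ind$a_gr, cohort$ind$e_p_gr,
                          e_t, cohort$b, w[cohort$partner], w)
  cohort$W <- cbind(cohort$W, w + inc, deparse.level = 0)
  cohort
}

#' Simulate the full weight trajectories of a cohort
#'
#' Runs [advance_time_point()] for \code{n_time_points} increments so that
#' every individual carries weights at time points 0..T. Warns (once) if any
#' weight goes negative, which can happen under extreme competition; no floor
#' is imposed.
#'
#' @inheritParams advance_time_point
#' @param n_time_points Number of increments; defaults to the value in
#'   \code{params}.
#' @return The cohort with simulated trajectories.
#' @export
simulate_trajectories <- function(cohort, params,
                                  n_time_points = params$n_time_points) {
  for (t in seq_len(n_time_points)) {
    cohort <- advance_time_point(cohort, params)
  }
  if (any(cohort$W < 0)) {
    warning("negative body weights produced (extreme competition); ",
            "no floor is imposed", call. = FALSE)
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: generation %d, %d individuals, %s, %d/%s time points\n",
              x$generation, nrow(x$ind),
              if (is.null(x$group_id)) "ungrouped"
              else sprintf("%d pairs", max(x$group_id)),
              n_steps_simulated(x),
              if (is.null(x$partner)) "-" else "simulated"))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  w <- cohort_weights(object)
  out <- list(
    generation = object$generation,
    n = nrow(object$ind),
    n_groups = if (is.null(object$group_id)) 0L else max(object$group_id),
    time_points = n_steps_simulated(object),
    mean_weight = mean(w),
    sd_weight = stats::sd(w),
    mean_b = if (is.null(object$b)) NA_real_ else mean(object$b)
  )
  class(out) <- "summary.cohort"
  out
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf(
    "generation %d: %d individuals in %d pairs, %d time points\n",
    x$generation, x$n, x$n_groups, x$time_points))
  cat(sprintf("  weight at last point: %.2f +/- %.2f g; mean b = %s\n",
              x$mean_weight, x$sd_weight,
              if (is.na(x$mean_b)) "-" else format(x$mean_b, digits = 4)))
  invisible(x)
}
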