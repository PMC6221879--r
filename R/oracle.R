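#' Closed-form law of the within-pair weight difference
#'
#' For a pair with fixed interaction coefficients, the weight difference
#' d_t = P_(t,i) - P_(t,j) follows the linear recursion
#' \deqn{d_t = c\, d_{t-1} + \delta_{perm} + \delta_{temp,t}, \quad
#'       c = 1 - b_{ij} - b_{ji},}
#' where \eqn{\delta_{perm}} is the (constant) difference in permanent growth
#' effects and \eqn{\delta_{temp,t}} the per-step difference in temporary
#' effects. Conditioning on the pair's coefficients, unrolling the recursion
#' gives closed forms for the expectation and variance of d_T, which serve as
#' the independent oracle for the simulator.
#'
#' @param b_ij,b_ji Interaction coefficients of the two members.
#' @param n_steps Number of growth increments T (>= 0).
#' @param d0 Initial weight difference (g), member i minus member j.
#' @param perm_var Variance of the permanent-effect difference (g^2); for
#'   unrelated mates this is \code{2 * (var_a_gr + var_ep_gr)}.
#' @param temp_var Variance of the temporary-effect difference per step
#'   (g^2); \code{2 * var_et_gr}.
#' @param d0_var Variance of the initial difference (g^2);
#'   \code{2 * start_weight_sd^2} when initial weights are independent.
#' @return An object of class \code{pair_difference_law}.
#' @export
#' @examples
#' law <- pair_difference_law(-0.08, -0.08, n_steps = 10, d0 = 2)
#' expected_pair_difference(law)  # 2 * 1.16^10
pair_difference_law <- function(b_ij, b_ji, n_steps, d0 = 0,
                                perm_var = 0, temp_var = 0, d0_var = 0) {
  vals <- c(b_ij, b_ji, n_steps, d0, perm_var, temp_var, d0_var)
  if (length(vals) != 7L || !all(is.finite(vals))) {
    stop("all law inputs must be finite scalars", call. = FALSE)
  }
  if (n_steps < 0 || n_steps != round(n_steps)) {
    stop("'n_steps' must be a non-negative integer", call. = FALSE)
  }
  if (perm_var < 0 || temp_var < 0 || d0_var < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(
    list(b_ij = b_ij, b_ji = b_ji, c = 1 - b_ij - b_ji,
         n_steps = as.integer(n_steps), d0 = d0,
         perm_var = perm_var, temp_var = temp_var, d0_var = d0_var),
    class = "pair_difference_law")
}

#' Pair-difference law from simulation parameters
#'
#' @inheritParams pair_difference_law
#' @param params A \code{\link{sim_params}} object.
#' @param relatedness Additive-genetic relatedness r of the two group mates;
#'   the genetic part of the permanent-difference variance is scaled by
#'   \code{2 * (1 - r)} (0 for unrelated mates, 1/2 for full sibs, 1/4 for
#'   half sibs).
#' @return A \code{pair_difference_law}.
#' @export
pair_difference_law_from_params <- function(b_ij, b_ji, params, d0 = 0,
                                            n_steps = params$n_time_points,
                                            relatedness = 0) {
  pair_difference_law(
    b_ij, b_ji, n_steps = n_steps, d0 = d0,
    perm_var = 2 * (1 - relatedness) * params$var_a_gr +
      2 * params$var_ep_gr,
    temp_var = 2 * params$var_et_gr,
    d0_var = 2 * params$start_weight_sd^2)
}

# Geometric sums sum_{k=0}^{T-1} c^k and c^{2k}, stable at c = 1.
.geom_sum <- function(c, T) {
  if (T == 0L) return(0)
  if (abs(c - 1) < 1e-12) T else (c^T - 1) / (c - 1)
}

#' Expected within-pair difference at the last time point
#'
#' E(d_T | b_ij, b_ji) = c^T d0: genetic and environmental effects have zero
#' mean, so only the initial difference propagates. Zero whenever d0 = 0.
#'
#' @param law A \code{\link{pair_difference_law}}.
#' @return Expected difference (g).
#' @export
expected_pair_difference <- function(law) {
  law$c^law$n_steps * law$d0
}

#' Variance of the within-pair difference at the last time point
#'
#' Unrolling the recursion,
#' \deqn{V(d_T) = \left(\sum_{k=0}^{T-1} c^k\right)^2 \sigma^2_{perm}
#'   + \sum_{k=0}^{T-1} c^{2k}\, \sigma^2_{temp} + c^{2T}\, V(d_0).}
#' The variance is strictly increasing in \eqn{-(b_{ij}+b_{ji})}: more
#' competition means more within-pair variance.
#'
#' @param law A \code{\link{pair_difference_law}}.
#' @return Variance of the difference (g^2).
#' @export
variance_pair_difference <- function(law) {
  s1 <- .geom_sum(law$c, law$n_steps)
  s2 <- .geom_sum(law$c^2, law$n_steps)
  s1^2 * law$perm_var + s2 * law$temp_var +
    law$c^(2 * law$n_steps) * law$d0_var
}

#' @export
print.pair_difference_law <- function(x, ...) {
  cat(sprintf(
    "pair-difference law: b_ij=%g b_ji=%g (c=%g), T=%d, d0=%g\n",
    x$b_ij, x$b_ji, x$c, x$n_steps, x$d0))
  cat(sprintf("  E(d_T) = %.6g g, V(d_T) = %.6g g^2\n",
              expected_pair_difference(x), variance_pair_difference(x)))
  cat(sprintf("  (perm %.3g, temp %.3g, d0 %.3g g^2)\n",
              x$perm_var, x$temp_var, x$d0_var))
  invisible(x)
}
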