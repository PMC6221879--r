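#' Plot a scenario suite
#'
#' Two base-graphics panels: within-group and phenotypic variance against the
#' population-average coefficient b_bar, and the group-mate correlation
#' against b_bar.
#'
#' @param x A \code{scenario_suite}.
#' @param ... Passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.scenario_suite <- function(x, ...) {
  s <- x$summary
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(s$b_bar, cbind(s$within, s$phenotypic), type = "b",
                    pch = c(16, 17), lty = 1,
                    xlab = expression(bar(b)), ylab = "variance (g^2)",
                    main = "variability of body weight", ...)
  graphics::legend("topright", c("within-group", "phenotypic"),
                   pch = c(16, 17), col = 1:2, bty = "n")
  graphics::plot(s$b_bar, s$rho, type = "b", pch = 16,
                 xlab = expression(bar(b)), ylab = expression(rho),
                 main = "group-mate correlation")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot growth trajectories of selected groups
#'
#' Draws both members' weight trajectories for the groups listed, e.g. the
#' output of [extract_extreme_groups()].
#'
#' @param cohort A simulated \code{cohort}.
#' @param groups Data frame with \code{row_i}/\code{row_j} columns, or a
#'   vector of group ids.
#' @param ... Passed to \code{matplot}.
#' @return \code{cohort}, invisibly.
#' @export
plot_group_trajectories <- function(cohort, groups, ...) {
  if (!is.data.frame(groups)) {
    g <- cohort_groups(cohort)
    groups <- g[g$group %in% groups, , drop = FALSE]
  }
  rows <- c(rbind(groups$row_i, groups$row_j))
  tp <- 0:n_steps_simulated(cohort)
  graphics::matplot(tp, t(cohort$W[rows, , drop = FALSE]), type = "l",
                    lty = rep(1:2, length.out = length(rows)),
                    col = rep(seq_len(nrow(groups)), each = 2),
                    xlab = "time point", ylab = "body weight (g)", ...)
  invisible(cohort)
}

#' Plot a selection experiment
#'
#' Six panels of the per-generation mean trajectories: within-group
#' variance, realised mean b, mean A_D, mean A_I, mean A_GR, and mean body
#' weight.
#'
#' @param x A \code{selection_experiment}.
#' @param ... Unused.
#' @return \code{x}, invisibly.
#' @export
plot.selection_experiment <- function(x, ...) {
  mt <- x$mean_trajectory
  panels <- c(within_var = "within-group variance (g^2)",
              mean_b = "mean b",
              mean_a_d = "mean A_D", mean_a_i = "mean A_I",
              mean_a_gr = "mean A_GR (g)",
              mean_weight = "mean body weight (g)")
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(panels)) {
    graphics::plot(mt$generation, mt[[nm]], type = "b", pch = 16,
                   xlab = "generation", ylab = panels[[nm]],
                   main = x$scheme)
  }
  invisible(x)
}
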