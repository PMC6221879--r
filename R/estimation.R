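#' Build time-series pair records from a cohort
#'
#' Emits two records per group per growth increment: for each focal role,
#' the response y = P(t+1, focal) - P(t, focal) and the covariate
#' delta = P(t, mate) - P(t, focal), both at the same time origin t. The
#' covariates of the two focal roles at the same (group, t) are exact
#' negatives.
#'
#' @param cohort A simulated, grouped \code{cohort}.
#' @return Data frame with columns \code{group, t, focal, increment, delta};
#'   \code{2 * n_groups * n_time_points} rows.
#' @export
build_pair_records <- function(cohort) {
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  T <- n_steps_simulated(cohort)
  if (T < 1L) stop("cohort has no simulated increments", call. = FALSE)
  n <- nrow(cohort$ind)
  W <- cohort$W
  data.frame(
    group = rep(cohort$group_id, T),
    t = rep(0:(T - 1L), each = n),
    focal = rep(cohort$ind$id, T),
    increment = as.vector(W[, 2:(T + 1L)] - W[, 1:T]),
    delta = as.vector(W[cohort$partner, 1:T] - W[, 1:T])
  )
}

#' Estimate a single fixed interaction coefficient by OLS
#'
#' Fits \code{increment ~ delta} by ordinary least squares: the intercept
#' estimates the mean growth rate mu, the slope the population-average
#' interaction coefficient b. Standard errors are the conventional OLS ones
#' and are naive: repeated records per individual are not independent, and
#' when permanent individual effects on growth are present they enter both
#' the response and (cumulatively, with opposite sign) the covariate, so the
#' slope is then a biased estimate of the average b. The estimator is exact
#' on data generated from the fixed-b regression model itself.
#'
#' @param records Data frame from [build_pair_records()] (needs columns
#'   \code{increment} and \code{delta}).
#' @return An object of class \code{fixed_b_fit}: coefficients \code{mu} and
#'   \code{b}, naive standard errors, record count and the underlying
#'   \code{lm} fit.
#' @export
#' @examples
#' p <- sim_params(var_a_gr = 0, var_ep_gr = 0, var_et_gr = 0,
#'                 var_ad = 0, var_ai = 0, var_ed = 0, var_ei = 0,
#'                 b_bar = -0.05, n_sires = 5, n_dams_per_sire = 2,
#'                 n_offspring_per_dam = 2)
#' set.seed(1)
#' co <- simulate_trajectories(sample_base_population(p), p)
#' coef(estimate_fixed_b(build_pair_records(co)))  # mu = 10, b = -0.05
estimate_fixed_b <- function(records) {
  if (!all(c("increment", "delta") %in% names(records))) {
    stop("'records' needs columns 'increment' and 'delta'", call. = FALSE)
  }
  if (nrow(records) < 3L) {
    stop("need at least 3 records", call. = FALSE)
  }
  if (stats::sd(records$delta) == 0) {
    stop("covariate is constant: fixed-b regression is rank deficient",
         call. = FALSE)
  }
  fit <- stats::lm(increment ~ delta, data = records)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(mu_hat = unname(est[1L]), b_hat = unname(est[2L]),
         se_mu = unname(se[1L]), se_b = unname(se[2L]),
         n_records = nrow(records),
         n_groups = length(unique(records$group)),
         naive_se = TRUE, lm = fit),
    class = "fixed_b_fit")
}

#' @export
coef.fixed_b_fit <- function(object, ...) {
  c(mu = object$mu_hat, b = object$b_hat)
}

#' @export
print.fixed_b_fit <- function(x, ...) {
  cat("fixed-b regression (OLS):\n")
  cat(sprintf("  mu = %.5g (se %.3g), b = %.5g (se %.3g)\n",
              x$mu_hat, x$se_mu, x$b_hat, x$se_b))
  cat(sprintf("  %d records, %d groups; standard errors are naive\n",
              x$n_records, x$n_groups))
  invisible(x)
}

#' @export
summary.fixed_b_fit <- function(object, ...) {
  out <- data.frame(
    term = c("mu", "b"),
    estimate = c(object$mu_hat, object$b_hat),
    std_error = c(object$se_mu, object$se_b))
  out$z <- out$estimate / out$std_error
  attr(out, "naive_se") <- TRUE
  out
}

#' Write a fixed-b fit as a small delimited table
#'
#' @param x A \code{fixed_b_fit}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fixed_b_table <- function(x, path) {
  utils::write.table(summary(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
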