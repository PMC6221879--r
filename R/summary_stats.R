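# Variance of a numeric vector under either denominator convention.
.var2 <- function(x, method) {
  if (method == "population") mean((x - mean(x))^2) else stats::var(x)
}

#' Mean within-group variance of body weight
#'
#' Mean over groups of the variance of the two members' weights at a time
#' point. With the default \code{"population"} denominator (n = 2) a pair
#' contributes (P_i - P_j)^2 / 4, and for independent group mates the
#' statistic equals half the phenotypic variance in expectation — the
#' convention under which the headline variability results are stated.
#' \code{"sample"} uses the n-1 denominator, (P_i - P_j)^2 / 2.
#'
#' @param cohort A simulated, grouped \code{cohort}.
#' @param time_point Time point 0..T; \code{NULL} (default) for the last.
#' @param method Denominator convention.
#' @return Mean within-group variance (g^2).
#' @export
within_group_variance <- function(cohort, time_point = NULL,
                                  method = c("population", "sample")) {
  method <- match.arg(method)
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  w <- cohort_weights(cohort, time_point)
  d2 <- (w - w[cohort$partner])^2 # each pair counted twice, same value
  mean(d2) / if (method == "population") 4 else 2
}

#' Phenotypic variance of body weight
#'
#' Variance of all individuals' weights at a time point.
#'
#' @inheritParams within_group_variance
#' @return Phenotypic variance (g^2).
#' @export
phenotypic_variance <- function(cohort, time_point = NULL,
                                method = c("population", "sample")) {
  method <- match.arg(method)
  w <- cohort_weights(cohort, time_point)
  if (length(w) < 2L) stop("need at least 2 individuals", call. = FALSE)
  .var2(w, method)
}

#' Between-group variance of body weight
#'
#' Variance of the group means at a time point. Under the
#' \code{"population"} convention the decomposition
#' phenotypic = between + within holds exactly.
#'
#' @inheritParams within_group_variance
#' @return Between-group variance (g^2).
#' @export
between_group_variance <- function(cohort, time_point = NULL,
                                   method = c("population", "sample")) {
  method <- match.arg(method)
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  w <- cohort_weights(cohort, time_point)
  gm <- (w + w[cohort$partner]) / 2
  first <- which(seq_along(cohort$partner) < cohort$partner)
  .var2(gm[first], method)
}

#' Correlation between group mates from variance components
#'
#' rho = (sigma2_between - sigma2_within) / (sigma2_between + sigma2_within).
#' Negative under competition (group mates diverge), positive under
#' cooperation, zero for independent mates.
#'
#' @param between_var Between-group variance (g^2).
#' @param within_var Mean within-group variance (g^2).
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' groupmate_correlation(2, 1)  # 1/3
groupmate_correlation <- function(between_var, within_var) {
  if (!all(is.finite(c(between_var, within_var))) ||
      between_var < 0 || within_var < 0) {
    stop("variances must be finite and non-negative", call. = FALSE)
  }
  tot <- between_var + within_var
  if (tot == 0) {
    stop("group-mate correlation undefined: both variance components are 0",
         call. = FALSE)
  }
  (between_var - within_var) / tot
}

#' Variability summary of a cohort at a time point
#'
#' @inheritParams within_group_variance
#' @return Named list: \code{within}, \code{between}, \code{phenotypic},
#'   \code{rho} (group-mate correlation), \code{cv} (coefficient of
#'   variation of weight, percent).
#' @export
cohort_stats <- function(cohort, time_point = NULL) {
  w <- within_group_variance(cohort, time_point)
  b <- between_group_variance(cohort, time_point)
  p <- phenotypic_variance(cohort, time_point)
  mw <- mean(cohort_weights(cohort, time_point))
  list(within = w, between = b, phenotypic = p,
       rho = groupmate_correlation(b, w),
       cv = 100 * sqrt(p) / mw)
}

#' Sire-level correlations between b breeding values and offspring variability
#'
#' Per sire, computes VarP_off, the sample variance of his offspring's
#' weights at a time point, and VarP_gm, the sample variance of the weights
#' of the group mates of his offspring; returns the Pearson correlations of
#' both against the sire's direct (A_D) and indirect (A_I) breeding value for
#' b. A negative r(A_D, VarP_off) means that genetic resistance to
#' competition reduces the variability of a sire's progeny, the signature of
#' inherited variability generated by social interactions. Grouping should
#' exclude sibs so that own-group and mate effects separate.
#'
#' @param cohort A simulated \code{cohort} with sire pedigree and parent
#'   effects (as produced by [sample_base_population()]).
#' @param time_point Time point; \code{NULL} for the last.
#' @return Named numeric vector \code{r_ad_off, r_ai_gm, r_ai_off, r_ad_gm},
#'   with the per-sire table as attribute \code{"sires"}.
#' @export
sire_variability_correlations <- function(cohort, time_point = NULL) {
  if (all(is.na(cohort$ind$sire))) {
    stop("cohort has no sire pedigree", call. = FALSE)
  }
  if (is.null(cohort$partner)) stop("cohort has no groups", call. = FALSE)
  w <- cohort_weights(cohort, time_point)
  sire <- cohort$ind$sire
  counts <- table(sire)
  if (any(counts < 2L)) {
    stop("every sire needs at least 2 offspring for a variance",
         call. = FALSE)
  }
  if (length(counts) < 3L) {
    stop("need at least 3 sires to correlate", call. = FALSE)
  }
  var_off <- tapply(w, sire, stats::var)
  var_gm <- tapply(w[cohort$partner], sire, stats::var)
  par <- cohort$parents
  if (is.null(par)) stop("cohort carries no parent effects", call. = FALSE)
  idx <- match(as.integer(names(var_off)), par$id)
  if (anyNA(idx)) stop("sire ids not found among parents", call. = FALSE)
  a_d <- par$a_d[idx]
  a_i <- par$a_i[idx]
  if (stats::sd(var_off) == 0 || stats::sd(var_gm) == 0 ||
      stats::sd(a_d) == 0 || stats::sd(a_i) == 0) {
    stop("correlation undefined: a sire-level quantity has zero variance",
         call. = FALSE)
  }
  out <- c(r_ad_off = stats::cor(a_d, var_off),
           r_ai_gm = stats::cor(a_i, var_gm),
           r_ai_off = stats::cor(a_i, var_off),
           r_ad_gm = stats::cor(a_d, var_gm))
  attr(out, "sires") <- data.frame(
    sire = as.integer(names(var_off)), a_d = a_d, a_i = a_i,
    var_off = as.numeric(var_off), var_gm = as.numeric(var_gm))
  out
}

#' Extract groups with extreme interaction coefficients
#'
#' Filters groups whose absolute initial weight difference is within
#' \code{tol_sd} standard deviations of \code{initial_diff_sd} standard
#' deviations (SD of initial weight measured in the cohort), then ranks by
#' the within-pair coefficient sum b_ij + b_ji and returns the extreme
#' group(s): the most competitive pairs (\code{"lowest_sum_b"}), the most
#' cooperative (\code{"highest_sum_b"}), or pairs whose two members carry
#' opposite-signed coefficients (\code{"mixed_signs"}, ranked by
#' |b_ij - b_ji|). Used to regenerate growth-curve contrasts: low-sum pairs
#' diverge, high-sum pairs stay uniform, and in mixed pairs the smaller
#' member can overtake the larger one.
#'
#' @param cohort A simulated, grouped \code{cohort}.
#' @param criterion Ranking criterion.
#' @param initial_diff_sd Target |initial difference| in units of the initial
#'   weight SD (default 2); \code{NULL} disables the filter.
#' @param tol_sd Half-width of the filter band, in SD units.
#' @param n Number of groups to return.
#' @return Data frame as from [cohort_groups()] plus \code{sum_b}, restricted
#'   and ordered per criterion; empty (with a warning) if no group passes the
#'   filter.
#' @export
extract_extreme_groups <- function(cohort,
                                   criterion = c("lowest_sum_b",
                                                 "highest_sum_b",
                                                 "mixed_signs"),
                                   initial_diff_sd = 2, tol_sd = 0.25,
                                   n = 1L) {
  criterion <- match.arg(criterion)
  g <- cohort_groups(cohort)
  g$sum_b <- g$b_ij + g$b_ji
  if (!is.null(initial_diff_sd)) {
    sd0 <- stats::sd(cohort$W[, 1L])
    keep <- abs(abs(g$d0) - initial_diff_sd * sd0) <= tol_sd * sd0
    g <- g[keep, , drop = FALSE]
  }
  if (criterion == "mixed_signs") {
    g <- g[sign(g$b_ij) * sign(g$b_ji) < 0, , drop = FALSE]
    g <- g[order(-abs(g$b_ij - g$b_ji)), , drop = FALSE]
  } else {
    g <- g[order(g$sum_b, g$id_i,
                 decreasing = (criterion == "highest_sum_b")), ,
           drop = FALSE]
  }
  if (nrow(g) == 0L) {
    warning("no group satisfies the filter; returning empty result",
            call. = FALSE)
    return(g)
  }
  utils::head(g, n)
}
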