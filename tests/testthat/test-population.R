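test_that("zero variances give identically zero effects", {
  p <- det_params(n_sires = 4, n_dams_per_sire = 2, n_offspring_per_dam = 2)
  set.seed(1)
  co <- sample_base_population(p, grouped = FALSE)
  expect_true(all(as.matrix(co$ind[, c("a_gr", "e_p_gr", "a_d", "e_d",
                                       "a_i", "e_i")]) == 0))
})

test_that("base-population effects have the configured variances and are independent", {
  p <- mid_params(scenario = 3) # 2000 offspring
  set.seed(42)
  co <- sample_base_population(p, grouped = FALSE)
  n <- nrow(co$ind)
  expect_identical(n, 2000L)
  # additive variance of growth rate ~ 1 g^2 (3 SE of a variance estimate)
  expect_equal(var(co$ind$a_gr), 1, tolerance = 3 * sqrt(2 / n))
  expect_equal(var(co$ind$a_d), 0.225e-3, tolerance = 3 * sqrt(2 / n))
  # all pairwise correlations among the six effects vanish
  C <- cor(co$ind[, c("a_gr", "e_p_gr", "a_d", "e_d", "a_i", "e_i")])
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(n))
})

test_that("offspring breeding values follow Mendelian inheritance", {
  p0 <- sim_params(var_a_gr = 0)
  s <- list(id = 1, a_gr = 0.02, a_d = 0, a_i = 0)
  d <- list(id = 2, a_gr = 0.04, a_d = 0, a_i = 0)
  expect_identical(make_offspring(s, d, p0)$a_gr, 0.03)

  # within-family (Mendelian-sampling) variance is half the base variance
  p <- sim_params()
  set.seed(7)
  off <- make_offspring(list(id = 1, a_gr = 0.5, a_d = 0, a_i = 0),
                        list(id = 2, a_gr = -0.3, a_d = 0, a_i = 0),
                        p, n = 20000)
  expect_lt(abs(mean(off$a_gr) - 0.1), 3 * sqrt(0.5 / 20000))
  expect_equal(var(off$a_gr), 0.5, tolerance = 3 * sqrt(2 / 20000))

  # across unrelated families the offspring variance returns to the base
  # variance: 1/4 + 1/4 + 1/2 of sigma2_A
  set.seed(8)
  co <- sample_base_population(mid_params(), grouped = FALSE)
  expect_equal(var(co$ind$a_gr), 1, tolerance = 3 * sqrt(2 / 2000) + 0.03)
})

test_that("pedigree links are recorded and acyclic", {
  p <- mid_params(n_sires = 5, n_dams_per_sire = 2)
  set.seed(1)
  co <- sample_base_population(p)
  expect_true(all(co$ind$sire %in% co$parents$id[co$parents$role == "sire"]))
  expect_true(all(co$ind$dam %in% co$parents$id[co$parents$role == "dam"]))
  expect_true(all(!co$ind$id %in% co$parents$id))
  tf <- tempfile(fileext = ".tsv")
  write_pedigree(co, tf)
  ped <- read.table(tf, header = TRUE)
  expect_identical(nrow(ped), nrow(co$ind) + nrow(co$parents))
  base <- ped[ped$sire == 0L, ]
  expect_true(all(ped$sire %in% c(0L, base$id)))
})

test_that("random matching is uniform over perfect matchings", {
  p <- det_params()
  eff <- data.frame(a_gr = 0, e_p_gr = 0, a_d = 0, e_d = 0,
                    a_i = 0, e_i = 0)[rep(1, 6), ]
  co <- make_cohort(eff, rep(10, 6))
  set.seed(123)
  codes <- character(10000)
  for (k in seq_along(codes)) {
    g <- assign_groups(co, p, policy = "random")
    first <- which(seq_along(g$partner) < g$partner)
    m <- cbind(first, g$partner[first])
    m <- m[order(m[, 1]), , drop = FALSE]
    codes[k] <- paste(m[, 1], m[, 2], sep = "-", collapse = "|")
  }
  tab <- table(codes)
  expect_identical(length(tab), 15L) # all matchings of 6 items occur
  expect_gt(chisq.test(tab, p = rep(1 / 15, 15))$p.value, 0.001)
})

test_that("non-sib policy forbids full and half sibs as group mates", {
  p <- sim_params(n_sires = 4, n_dams_per_sire = 2, n_offspring_per_dam = 5,
                  grouping = "non_sib")
  set.seed(5)
  for (k in 1:20) {
    co <- sample_base_population(p)
    first <- which(seq_along(co$partner) < co$partner)
    j <- co$partner[first]
    expect_false(any(co$ind$sire[first] == co$ind$sire[j]))
    expect_false(any(co$ind$dam[first] == co$ind$dam[j]))
  }
  # a single full-sib family can never be matched
  p1 <- sim_params(n_sires = 1, n_dams_per_sire = 1,
                   n_offspring_per_dam = 6)
  set.seed(6)
  co1 <- sample_base_population(p1, grouped = FALSE)
  expect_error(assign_groups(co1, p1, policy = "non_sib", max_retries = 20),
               "non-sib matching")
  # odd counts cannot be paired
  eff <- draw_effects_df(3, p)
  co3 <- make_cohort(eff, rep(10, 3))
  expect_error(assign_groups(co3, p, policy = "random"), "odd")
})

test_that("pair coefficients have the combined b variance", {
  p <- mid_params(scenario = 3) # var sum = 4 x 0.225e-3 = 9e-4
  set.seed(11)
  co <- sample_base_population(p)
  expect_equal(var(co$b), 9e-4, tolerance = 3 * sqrt(2 / 2000))
  # b_ij = b_bar + A_D,i + E_D,i + A_I,j + E_I,j exactly
  i <- 17L
  j <- co$partner[i]
  expect_identical(co$b[i],
                   p$b_bar + co$ind$a_d[i] + co$ind$e_d[i] +
                     co$ind$a_i[j] + co$ind$e_i[j])
})

test_that("cohort tables round-trip through the delimited format", {
  p <- mid_params(n_sires = 4, n_dams_per_sire = 2, scenario = 2)
  set.seed(3)
  co <- quiet_sim(sample_base_population(p), p)
  tf <- tempfile(fileext = ".tsv")
  write_cohort_table(co, tf)
  back <- read_cohort_table(tf)
  expect_equal(back$W, co$W[order(co$ind$id), ], ignore_attr = TRUE)
  ord <- order(co$ind$id)
  expect_equal(back$b, co$b[ord])
  expect_identical(back$group_id[back$partner], back$group_id)
  # group memberships identical up to relabelling
  key <- function(x) {
    first <- which(seq_along(x$partner) < x$partner)
    sort(paste(pmin(x$ind$id[first], x$ind$id[x$partner[first]]),
               pmax(x$ind$id[first], x$ind$id[x$partner[first]])))
  }
  expect_identical(key(back), key(co))
})
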