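test_that("interaction coefficient combines direct and indirect effects", {
  expect_equal(
    compute_b(-0.05, effect_set(a_d = 0.03), effect_set(a_i = 0.03)),
    0.01, tolerance = 1e-12)
  expect_identical(compute_b(0, effect_set(), effect_set()), 0)
  expect_equal(
    compute_b(0.05, effect_set(a_d = -0.03), effect_set(a_i = -0.03)),
    -0.01, tolerance = 1e-12)
  # environmental components contribute like the genetic ones
  expect_equal(
    compute_b(0.1, effect_set(a_d = 0.01, e_d = 0.02),
              effect_set(a_i = 0.03, e_i = -0.04)),
    0.12, tolerance = 1e-12)
  expect_error(compute_b(NaN, effect_set(), effect_set()), "finite")
  expect_error(effect_set(a_d = Inf), "non-finite")
})

test_that("growth increment is the pure one-step equation", {
  expect_equal(growth_increment(0, 0, 0, 0, 0.01, 12, 10), 0.02,
               tolerance = 1e-12)
  expect_identical(growth_increment(10, 0, 0, 0, -0.5, 7, 7), 10)
  expect_equal(growth_increment(0, 0, 0, 0, -0.11, 12, 10), -0.22,
               tolerance = 1e-12)
  # vectorised and pure: repeated evaluation gives identical results
  v1 <- growth_increment(10, c(0.1, -0.1), 0, 0, c(0.01, -0.01), 12, 10)
  expect_identical(v1, growth_increment(10, c(0.1, -0.1), 0, 0,
                                        c(0.01, -0.01), 12, 10))
  expect_error(growth_increment(10, NA, 0, 0, 0, 12, 10), "finite")
})

test_that("the eight signed worked outcomes reproduce bit-for-bit", {
  # one pair, mate 2 g heavier than the focal, no growth effects
  cases <- list(
    list(b_bar = -0.05, bv = 0.03, dP_i = 0.02),
    list(b_bar = -0.05, bv = -0.03, dP_i = -0.22),
    list(b_bar = 0.05, bv = 0.03, dP_i = 0.22),
    list(b_bar = 0.05, bv = -0.03, dP_i = -0.02))
  for (cs in cases) {
    b_ij <- compute_b(cs$b_bar, effect_set(a_d = cs$bv),
                      effect_set(a_i = cs$bv))
    b_ji <- compute_b(cs$b_bar, effect_set(a_d = cs$bv),
                      effect_set(a_i = cs$bv))
    dP_i <- growth_increment(0, 0, 0, 0, b_ij, 12, 10)
    dP_j <- growth_increment(0, 0, 0, 0, b_ji, 10, 12)
    expect_identical(dP_i, 2 * (cs$b_bar + cs$bv + 0 + cs$bv + 0))
    expect_identical(dP_j, -dP_i)
    expect_equal(dP_i, cs$dP_i, tolerance = 1e-12)
    expect_equal(dP_j, -cs$dP_i, tolerance = 1e-12)
  }
})

test_that("b is non-symmetric unless direct and indirect effects coincide", {
  i <- effect_set(a_d = 0.02, a_i = -0.01)
  j <- effect_set(a_d = -0.03, a_i = 0.04)
  expect_false(compute_b(0, i, j) == compute_b(0, j, i))
  k <- effect_set(a_d = 0.02, a_i = 0.02)
  expect_identical(compute_b(0, k, k), compute_b(0, k, k))
})

test_that("synchronous update conserves the pair sum under symmetric b", {
  p <- det_params()
  g <- make_pair_cohort(effect_set(), effect_set(), 11, 9,
                        b_ij = -0.08, b_ji = -0.08)
  g <- simulate_trajectories(g, p, 10)
  sums <- colSums(g$W)
  expect_equal(sums, 20 + 2 * 10 * (0:10), tolerance = 1e-10)
  # difference after one step doubles per the recursion multiplier
  expect_equal(g$W[1, 2] - g$W[2, 2], 2 * 1.16, tolerance = 1e-12)
  # equal b, zero noise, equal weights: both members gain exactly mu
  h <- make_pair_cohort(effect_set(), effect_set(), 10, 10,
                        b_ij = 0.3, b_ji = 0.3)
  h <- advance_time_point(h, p)
  expect_equal(unname(h$W[, 2]), c(20, 20), tolerance = 1e-12)
})

test_that("deterministic trajectories match the hand-iterated recursion", {
  p <- det_params()
  grid <- expand.grid(b_ij = c(-0.08, -0.02, 0, 0.03, 0.08),
                      b_ji = c(-0.08, -0.01, 0, 0.05),
                      d0 = c(0, 2, -3),
                      T = c(1, 5, 10))
  expect_gte(nrow(grid), 100)
  for (k in seq_len(nrow(grid))) {
    g <- with(grid[k, ], make_pair_cohort(
      effect_set(), effect_set(), d0 / 2, -d0 / 2,
      b_ij = b_ij, b_ji = b_ji))
    g <- quiet_sim(g, p, grid$T[k])
    got <- g$W[1, grid$T[k] + 1L] - g$W[2, grid$T[k] + 1L]
    expect_equal(got, with(grid[k, ], brute_force_diff(b_ij, b_ji, d0, T)),
                 tolerance = 1e-10)
  }
  # frozen endpoint values of the divergence/convergence contrast
  g1 <- make_pair_cohort(effect_set(), effect_set(), 1, -1,
                         b_ij = -0.08, b_ji = -0.08)
  expect_equal(diff(-quiet_sim(g1, p, 10)$W[, 11]), 2 * 1.16^10,
               tolerance = 1e-12, ignore_attr = TRUE)
  g2 <- make_pair_cohort(effect_set(), effect_set(), 1, -1,
                         b_ij = 0.08, b_ji = 0.08)
  expect_equal(diff(-quiet_sim(g2, p, 10)$W[, 11]), 2 * 0.84^10,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cohort state is validated before stepping", {
  p <- det_params()
  eff <- data.frame(a_gr = 0, e_p_gr = 0, a_d = 0, e_d = 0, a_i = 0,
                    e_i = 0)[rep(1, 4), ]
  ungrouped <- make_cohort(eff, rep(10, 4))
  expect_error(advance_time_point(ungrouped, p), "no groups")
  expect_error(make_cohort(eff, rep(10, 4), group_id = c(1, 1, 1, 2)),
               "exactly 2 members")
  expect_error(make_cohort(eff, c(10, NA, 10, 10)), "finite")
})

test_that("extreme competition can drive weights negative, with a warning", {
  p <- det_params(mu_gr = 0)
  g <- make_pair_cohort(effect_set(), effect_set(), 3, 1,
                        b_ij = -0.8, b_ji = -0.8)
  expect_warning(simulate_trajectories(g, p, 5), "negative body weights")
})
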