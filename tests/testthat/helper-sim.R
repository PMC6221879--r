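# Shared helpers: small parameter sets, noise-free configurations, and the
# brute-force pair-difference recursion used as an independent oracle.

# All random variances off; single deterministic trajectory.
det_params <- function(...) {
  args <- utils::modifyList(
    list(var_a_gr = 0, var_ep_gr = 0, var_et_gr = 0, var_ad = 0,
         var_ai = 0, var_ed = 0, var_ei = 0, start_weight_sd = 0),
    list(...))
  do.call(sim_params, args)
}

# Compact family design for fast stochastic tests (2000 individuals by
# default; any field can be overridden).
mid_params <- function(...) {
  args <- utils::modifyList(
    list(n_sires = 100, n_dams_per_sire = 10, n_offspring_per_dam = 2),
    list(...))
  do.call(sim_params, args)
}

quiet_sim <- function(cohort, params, ...) {
  suppressWarnings(simulate_trajectories(cohort, params, ...))
}

# Independent oracle: iterate the two-member recursion step by step.
brute_force_diff <- function(b_ij, b_ji, d0, n_steps) {
  w_i <- d0 / 2
  w_j <- -d0 / 2
  for (t in seq_len(n_steps)) {
    inc_i <- b_ij * (w_j - w_i)
    inc_j <- b_ji * (w_i - w_j)
    w_i <- w_i + inc_i
    w_j <- w_j + inc_j
  }
  w_i - w_j
}

# Independent normal effect draws for hand-built cohorts.
draw_effects_df <- function(n, params) {
  z <- function(v) if (v > 0) rnorm(n, 0, sqrt(v)) else numeric(n)
  data.frame(a_gr = z(params$var_a_gr), e_p_gr = z(params$var_ep_gr),
             a_d = z(params$var_ad), e_d = z(params$var_ed),
             a_i = z(params$var_ai), e_i = z(params$var_ei))
}
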