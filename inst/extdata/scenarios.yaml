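# Canonical simulation scenarios: five population-average interaction
# coefficients, all other parameters shared.
default:
  mu_gr: 10
  var_a_gr: 1
  var_ep_gr: 0.4
  var_et_gr: 0.6
  var_ad: 0.000225
  var_ai: 0.000225
  var_ed: 0.000225
  var_ei: 0.000225
  start_weight_mean: 10
  n_sires: 100
  n_dams_per_sire: 40
  n_offspring_per_dam: 2
  n_time_points: 10
  n_replicates: 100
  grouping: non_sib
scenarios:
  scenario_1: {b_bar: -0.08}
  scenario_2: {b_bar: -0.05}
  scenario_3: {b_bar: 0.0}
  scenario_4: {b_bar: 0.05}
  scenario_5: {b_bar: 0.08}
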