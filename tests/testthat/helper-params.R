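# Shared fixtures: the base-case parameterization and a generator of
# random valid parameterizations for property-style tests.

base_params <- function(...) parameter_set(...)

random_margins <- function() {
  margin_model(p_pos_st = runif(1, 0.05, 0.6),
               p_pos_ifmi = runif(1, 0.01, 0.4),
               p_pos_second = runif(1, 0.02, 0.3))
}

random_costs <- function() {
  cost_parameters(drg_cost = runif(1, 1000, 6000),
                  lost_productivity = runif(1, 100, 900),
                  agent_cost = runif(1, 100, 900),
                  draping_cost = runif(1, 5, 50),
                  staff_addon_cost = runif(1, 20, 200),
                  st_duration = runif(1, 40, 90),
                  prolongation = runif(1, 5, 20),
                  fsa_duration = runif(1, 10, 50),
                  staff_time_saving_factor = runif(1),
                  cost_per_minute = runif(1, 30, 100),
                  fsa_fixed_saving = runif(1, 0, 200))
}
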