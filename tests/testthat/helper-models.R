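# Shared fixtures: the reference model (Table-1 defaults) and its calibrated
# growth-independent intensity, computed once per test run.
ref_model <- plasticity_model()
ref_mI <- calibrate_mI(ref_model)
ref_model_cal <- update_model(ref_model, mI = ref_mI)

# Deterministic random nonnegative states for property checks.
random_states <- function(n_states, n, seed = 42, scale = 2) {
  set.seed(seed)
  matrix(stats::runif(n_states * n, 0, scale), n_states, n)
}

# Burden reduction of a scheme run started from the coexistence equilibrium.
scheme_reduction <- function(model, scheme, n_blocks = 1L, duration = 10,
                             dt = 0.5) {
  sched <- build_schedule(scheme, n_blocks = n_blocks, duration = duration)
  traj <- simulate(model, x0 = coexistence_equilibrium(model),
                   schedule = sched, horizon = duration, dt = dt)
  burden_reduction(traj, at_time = duration)
}
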