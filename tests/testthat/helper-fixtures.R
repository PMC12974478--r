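# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

# settled reference trace, detection-grade voltage sampling (1 ms); long
# enough for the slowest sensor filter (tau_D = 60 s) to converge fully
ref_trace <- function() {
  if (is.null(.fx$ref_trace))
    .fx$ref_trace <- simulate(reference_model(), baseline_schedule(400),
                              make_regulation_config("none"),
                              dt = 0.05, record_interval = 1)
  .fx$ref_trace
}

# scaled-down full-variant protocol run of the reference model
ci_full_run <- function() {
  if (is.null(.fx$ci_full)) {
    reg <- make_regulation_config("full",
                                  targets = reference_calibration()$targets)
    .fx$ci_full <- simulate(reference_model(), schedule_profile("ci"), reg,
                            dt = 0.05, record_interval = 5)
  }
  .fx$ci_full
}

# small seeded ensemble + scaled-down full-variant experiment (expensive,
# several minutes; built once, reused by ensemble and acceptance tests)
test_ensemble <- function() {
  if (is.null(.fx$ens))
    .fx$ens <- generate_ensemble(ensemble_spec(n_models = 4, seed = 5))
  .fx$ens
}

test_ensemble_run <- function() {
  if (is.null(.fx$ens_run))
    .fx$ens_run <- run_protocol_experiment(test_ensemble(), "full",
                                           schedule = "ci")
  .fx$ens_run
}

# piecewise-triangular voltage trace with spikes at known times
synth_spike_V <- function(spike_times, total_s, dt = 0.001, peak = 10,
                          base = -60, half_width = 0.003) {
  tt <- seq(0, total_s, by = dt)
  V <- rep(base, length(tt))
  for (ts in spike_times) {
    sel <- abs(tt - ts) <= half_width
    V[sel] <- pmax(V[sel], peak - (peak - base) * abs(tt[sel] - ts) / half_width)
  }
  list(times = tt, V = V)
}
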