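# Shared fixture builders. Everything is generated in code; no files.

noiseless_config <- function(target_asv = NA_real_, setting_sv = 100,
                             bias_flow = 20, duration = 200, seed = 1L,
                             ...) {
  sim_config(
    settings = oscillator_settings(setting_sv = setting_sv,
                                   bias_flow = bias_flow),
    noise = list(flow_sd = 0, pco2_sd = 0),
    duration = duration, seed = seed, target_asv = target_asv, ...)
}

# Criterion usable with shorter traces than the 300-s default run.
quick_criterion <- function() {
  stabilization_criterion(window = 30, max_rel_slope = 0.01,
                          min_elapsed = 60)
}

# Independent fixed point of the per-cycle map: ДC is affine in C, so
# two evaluations of step_cycle() determine slope and intercept and the
# fixed point b / (1 - a). Shares no algebra with steady_state().
fixed_point_from_steps <- function(config, c0 = 0.001, c1 = 0.2) {
  y0 <- step_cycle(c0, config)$fraction
  y1 <- step_cycle(c1, config)$fraction
  a <- (y1 - y0) / (c1 - c0)
  b <- y0 - a * c0
  b / (1 - a)
}
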