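test_that("stroke-volume attenuation is linear, monotone and guarded", {
  att <- list(slope_base = 0.75, slope_bf_penalty = 0.002, intercept = 0)
  expect_equal(attenuate_sv(100, 10, att), 73)
  expect_equal(attenuate_sv(0, 35, att), 0)
  expect_gt(attenuate_sv(160, 20, att), attenuate_sv(80, 20, att))
  # non-increasing in bias flow
  bfs <- seq(10, 60, by = 10)
  vals <- vapply(bfs, function(b) attenuate_sv(120, b, att), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(
    attenuate_sv(100, 60, list(slope_base = 0.1, slope_bf_penalty = 0.01,
                               intercept = 0)),
    "negative")
})

test_that("flow trace integrates to the stroke volume per half-cycle", {
  tr <- make_flow_trace(100, 8, rate = 200, duration = 2, noise_sd = 0)
  expect_equal(max(tr$samples), 100 * pi * 8, tolerance = 1e-2)
  # closed form: integral of a half sine lobe is q0 / (pi f)
  q0 <- 100 * pi * 8
  expect_equal(q0 / (pi * 8), 100)
  zero <- make_flow_trace(0, 8, 200, 1)
  expect_true(all(zero$samples == 0))
  a <- make_flow_trace(100, 8, 200, 1, noise_sd = 10, seed = 99)
  b <- make_flow_trace(100, 8, 200, 1, noise_sd = 10, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_error(make_flow_trace(100, 8, 200, duration = 0.05), "cycle")
})

test_that("step_cycle starts washin, dilutes with BF, and is guarded", {
  cfg <- noiseless_config(target_asv = 100, bias_flow = 20)
  st <- step_cycle(0, cfg)
  expect_gt(st$fraction, 0)
  expect_equal(st$inspired_fraction, 0)

  # inspired fraction vanishes as bias flow grows
  fr <- 0.05
  big <- noiseless_config(target_asv = 100, bias_flow = 1e6)
  small <- noiseless_config(target_asv = 100, bias_flow = 10)
  expect_lt(step_cycle(fr, big)$inspired_fraction, 1e-4)
  expect_gt(step_cycle(fr, small)$inspired_fraction,
            step_cycle(fr, noiseless_config(target_asv = 100,
                                            bias_flow = 40))$inspired_fraction)

  # zero alveolar exchange with active insufflation has no steady state
  dead <- sim_config(
    target_asv = 50,
    lung = lung_model_spec(dead_space = 110),
    transport = list(conv_coeff = 1, disp_coeff = 0, disp_power = 1.8))
  expect_error(step_cycle(0, dead), "no steady state")
  expect_error(step_cycle(1.2, cfg), "lung_co2_fraction")
})

test_that("analytic steady state equals the independent fixed point", {
  # the per-cycle map is affine; reconstruct its fixed point from two
  # step_cycle evaluations (independent of the steady_state() algebra)
  grid <- expand.grid(asv = c(60, 90, 130), bf = c(10, 30, 60),
                      eta = c(0.6, 1))
  for (i in seq_len(nrow(grid))) {
    cfg <- noiseless_config(target_asv = grid$asv[i],
                            bias_flow = grid$bf[i],
                            mixing = mixing_params(grid$eta[i]))
    expect_equal(steady_state(cfg)$fraction, fixed_point_from_steps(cfg),
                 tolerance = 1e-10)
  }
})

test_that("iterating the per-cycle map converges to the analytic value", {
  # small container so the washin time constant is short enough to
  # iterate from zero within a test budget
  cfg <- noiseless_config(target_asv = 100, bias_flow = 20,
                          lung = lung_model_spec(container_volume = 1))
  ss <- steady_state(cfg)
  expect_lt(abs(ss$contraction), 1)
  cur <- 0
  for (k in 1:4000) cur <- step_cycle(cur, cfg)$fraction
  expect_equal(cur, ss$fraction, tolerance = 1e-6)
})

test_that("per-cycle map is a contraction across the operating range", {
  set.seed(11)
  for (i in 1:30) {
    cfg <- noiseless_config(
      target_asv = runif(1, 40, 200),
      bias_flow = runif(1, 5, 60),
      mixing = mixing_params(runif(1, 0.3, 1)))
    expect_lt(abs(steady_state(cfg)$contraction), 1)
  }
})

test_that("simulated runs honour linearity and the noiseless contract", {
  cfg <- noiseless_config(target_asv = 100, bias_flow = 20, duration = 100)
  run <- simulate_run(cfg)
  expect_true(run$converged)
  # noiseless, started at steady state: capno tail equals truth exactly
  expect_equal(tail(run$pco2_trace$samples, 1), run$truth$pco2_ss,
               tolerance = 1e-9)
  expect_equal(run$truth$pco2_ss,
               run$truth$lung_co2_fraction_ss * 760)

  # doubling insufflation doubles the steady-state PCO2
  cfg2 <- cfg
  cfg2$lung <- lung_model_spec(vco2_insufflation = 400)
  run2 <- simulate_run(cfg2)
  expect_equal(run2$truth$pco2_ss, 2 * run$truth$pco2_ss,
               tolerance = 1e-12)
})

test_that("steady state is independent of the initial fraction", {
  # long-duration washin from two initials lands on the same value
  base <- noiseless_config(target_asv = 120, bias_flow = 40,
                           lung = lung_model_spec(container_volume = 2),
                           duration = 600)
  ends <- vapply(c(0, 0.05), function(f0) {
    cfg <- base
    cfg$init_fraction <- f0
    run <- simulate_run(cfg)
    tail(run$pco2_trace$samples, 1)
  }, numeric(1))
  expect_equal(ends[1], ends[2], tolerance = 1e-3)
})

test_that("a too-short washin is flagged as not converged", {
  cfg <- noiseless_config(target_asv = 80, bias_flow = 10, duration = 20,
                          init_fraction = 0)
  expect_warning(run <- simulate_run(cfg), "steady state")
  expect_false(run$converged)
})

test_that("grid simulation has the study cardinalities and is reproducible", {
  base <- noiseless_config(duration = 2)
  g1 <- simulate_grid(base, seq(80, 180, by = 10), c(10, 20, 30, 40),
                      replicates = 5, seed = 5, study = 1)
  expect_length(g1, 11 * 4 * 5)
  g2 <- simulate_grid(base, c(80, 100, 120), seq(10, 60, by = 10),
                      replicates = 5, seed = 5, study = 2)
  expect_length(g2, 3 * 6 * 5)

  small_a <- simulate_grid(base, c(80, 120), c(10, 40), replicates = 2,
                           seed = 7, study = 2)
  small_b <- simulate_grid(base, c(80, 120), c(10, 40), replicates = 2,
                           seed = 7, study = 2)
  expect_identical(
    lapply(small_a, function(r) r$truth),
    lapply(small_b, function(r) r$truth))
  expect_identical(attr(small_a, "seed"), attr(small_b, "seed"))
  # study 2 bypasses the attenuation map: truth aSV equals the target
  expect_equal(vapply(small_a, function(r) r$truth$actual_sv, numeric(1)),
               attr(small_a, "sv"))
  # study 1 routes through it
  s1 <- simulate_grid(base, 100, 10, replicates = 1, seed = 1, study = 1)
  expect_equal(s1[[1]]$truth$actual_sv, 73)
})

test_that("calibration simulation matches the dilution closed form", {
  gas <- gas_conditions(760)
  expect_equal(simulate_calibration(200, 5, gas), 760 * 200 / 5200)
  expect_equal(round(simulate_calibration(200, 5, gas), 2), 29.23)
  expect_equal(simulate_calibration(0, 5, gas), 0)
  a <- simulate_calibration(200, 5, gas, noise_sd = 0.5, seed = 3)
  b <- simulate_calibration(200, 5, gas, noise_sd = 0.5, seed = 3)
  expect_identical(a, b)
})

test_that("CO2 is conserved over an accounting of simulated cycles", {
  cfg <- noiseless_config(target_asv = 110, bias_flow = 30)
  ss <- steady_state(cfg)
  q_cap <- cfg$lung$capno_sample_flow / (60 * 8)
  v_alv <- cfg$transport$conv_coeff *
    max(110 - cfg$lung$dead_space, 0) +
    cfg$transport$disp_coeff * 110^cfg$transport$disp_power
  cur <- ss$fraction
  n <- 500L
  removed <- 0
  for (k in seq_len(n)) {
    st <- step_cycle(cur, cfg)
    removed <- removed + v_alv * (cur - st$inspired_fraction) +
      q_cap * cur
    cur <- st$fraction
  }
  injected <- n * cfg$lung$vco2_insufflation / (60 * 8)
  storage <- (cur - ss$fraction) * cfg$lung$container_volume * 1000
  expect_equal(removed + storage, injected,
               tolerance = 1e-3 * injected)
})
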