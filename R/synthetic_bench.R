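# Synthetic bench: oscillator + circuit mixing + well-mixed test lung,
# iterated at per-cycle resolution. Emits sampled flow and capnometer
# traces plus the analytic ground truth so every downstream stage has a
# known answer.

#' Simulation configuration
#'
#' Assembles everything one bench run needs. Defaults reproduce the
#' study's common condition: 8 Hz, inspiratory fraction 0.5, 20-L lung
#' with 110 mL dead space, ~200 mL/min CO2 insufflation, 200 mL/min
#' capnometer withdrawal, flow sampled at 200 Hz.
#'
#' @param settings An [oscillator_settings()] object.
#' @param lung A [lung_model_spec()] object.
#' @param mixing A [mixing_params()] object.
#' @param gas A [gas_conditions()] object.
#' @param attenuation Named list `slope_base`, `slope_bf_penalty`
#'   (per L/min of bias flow) and `intercept` (mL) for the linear
#'   sSV -> aSV map. The defaults are declared stand-ins: the bench
#'   observation is only that the map is linear in sSV with a slope that
#'   falls as bias flow rises.
#' @param transport Named list `conv_coeff` (c1), `disp_coeff` (c2) and
#'   `disp_power` (p) of the per-cycle alveolar exchange volume
#'   `c1 * max(aSV - VD, 0) + c2 * aSV^p` (mL). A declared
#'   non-physiological stand-in: direct convection above dead space plus
#'   a dispersive term with the supra-linear stroke-volume dependence
#'   characteristic of high-frequency transport (the default `p = 1.8`
#'   sits just below the classical squared dependence; see the methods
#'   vignette for why and for how `c2` was calibrated).
#' @param flow_sample_rate Flow sensor sampling rate, Hz.
#' @param capno_sample_rate Capnometer trace sampling rate, Hz.
#' @param capno_time_constant First-order response time of the sidestream
#'   capnometer, s.
#' @param noise Named list `flow_sd` (mL/s) and `pco2_sd` (mmHg) of the
#'   additive Gaussian measurement noise.
#' @param duration Simulated duration, s.
#' @param seed Integer master seed for the run's noise.
#' @param target_asv Optional target actual stroke volume, mL. When set
#'   (study-2 style) the attenuation map is bypassed and this aSV is
#'   delivered directly; when `NA` (study-1 style) aSV is derived from
#'   `settings$setting_sv` through the attenuation map.
#' @param init_fraction Initial lung CO2 fraction. `NA` (default) starts
#'   at the analytic steady state, emulating the bench protocol of
#'   recording only after stabilization; a number in `[0, 1)` starts a
#'   washin from that fraction.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(settings = oscillator_settings(),
                       lung = lung_model_spec(),
                       mixing = mixing_params(),
                       gas = gas_conditions(),
                       attenuation = list(slope_base = 0.75,
                                          slope_bf_penalty = 0.002,
                                          intercept = 0),
                       transport = list(conv_coeff = 1,
                                        disp_coeff = 0.01,
                                        disp_power = 1.8),
                       flow_sample_rate = 200,
                       capno_sample_rate = 25,
                       capno_time_constant = 1,
                       noise = list(flow_sd = 20, pco2_sd = 0.5),
                       duration = 300,
                       seed = 1L,
                       target_asv = NA_real_,
                       init_fraction = NA_real_) {
  stopifnot(inherits(settings, "oscillator_settings"),
            inherits(lung, "lung_model_spec"),
            inherits(mixing, "mixing_params"),
            inherits(gas, "gas_conditions"))
  need <- function(lst, keys, what) {
    if (!is.list(lst) || !all(keys %in% names(lst))) {
      stop(sprintf("`%s` must be a named list with fields: %s",
                   what, paste(keys, collapse = ", ")), call. = FALSE)
    }
    lst[keys]
  }
  attenuation <- need(attenuation,
                      c("slope_base", "slope_bf_penalty", "intercept"),
                      "attenuation")
  transport <- need(transport, c("conv_coeff", "disp_coeff", "disp_power"),
                    "transport")
  noise <- need(noise, c("flow_sd", "pco2_sd"), "noise")
  stop_if_not_scalar_number(flow_sample_rate, "flow_sample_rate", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(capno_sample_rate, "capno_sample_rate", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(capno_time_constant, "capno_time_constant", 0)
  stop_if_not_scalar_number(duration, "duration", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(noise$flow_sd, "noise$flow_sd", 0)
  stop_if_not_scalar_number(noise$pco2_sd, "noise$pco2_sd", 0)
  stop_if_not_scalar_number(transport$conv_coeff, "transport$conv_coeff", 0)
  stop_if_not_scalar_number(transport$disp_coeff, "transport$disp_coeff", 0)
  if (!is.na(target_asv)) {
    stop_if_not_scalar_number(target_asv, "target_asv", 0)
  }
  if (!is.na(init_fraction)) {
    stop_if_not_scalar_number(init_fraction, "init_fraction", 0)
    if (init_fraction >= 1) stop("`init_fraction` must be < 1", call. = FALSE)
  }
  structure(
    list(settings = settings, lung = lung, mixing = mixing, gas = gas,
         attenuation = attenuation, transport = transport,
         flow_sample_rate = flow_sample_rate,
         capno_sample_rate = capno_sample_rate,
         capno_time_constant = capno_time_constant,
         noise = noise, duration = duration, seed = as.integer(seed),
         target_asv = target_asv, init_fraction = init_fraction),
    class = "sim_config")
}

#' Setting to actual stroke volume attenuation
#'
#' Linear map from panel stroke volume to delivered stroke volume with a
#' slope that shrinks as bias flow rises:
#' `aSV = max(0, (slope_base - slope_bf_penalty * BF) * sSV + intercept)`.
#' The linear-in-sSV, decreasing-in-BF shape is the bench observation;
#' the coefficients are calibratable stand-ins, not device constants.
#'
#' @param setting_sv Panel stroke volume, mL. Non-negative.
#' @param bias_flow Bias flow, L/min.
#' @param attenuation Named list as in [sim_config()].
#' @return Actual stroke volume, mL.
#' @examples
#' attenuate_sv(100, 10) # 73
#' @export
attenuate_sv <- function(setting_sv, bias_flow,
                         attenuation = list(slope_base = 0.75,
                                            slope_bf_penalty = 0.002,
                                            intercept = 0)) {
  stop_if_not_scalar_number(setting_sv, "setting_sv", 0)
  stop_if_not_scalar_number(bias_flow, "bias_flow", 0)
  slope <- attenuation$slope_base - attenuation$slope_bf_penalty * bias_flow
  if (slope < 0) {
    stop("attenuation parameters yield a negative sSV->aSV slope at BF = ",
         bias_flow, " L/min", call. = FALSE)
  }
  max(0, slope * setting_sv + attenuation$intercept)
}

resolve_actual_sv <- function(config) {
  if (!is.na(config$target_asv)) {
    config$target_asv
  } else {
    attenuate_sv(config$settings$setting_sv, config$settings$bias_flow,
                 config$attenuation)
  }
}

#' Synthetic oscillatory flow trace
#'
#' Sinusoidal airway-opening flow `q(t) = q0 sin(2 pi f t)` with
#' amplitude `q0 = aSV * pi * f` so each half-cycle integrates to exactly
#' `actual_sv` mL (inspiration positive, expiration negative), plus
#' optional additive Gaussian sensor noise.
#'
#' @param actual_sv Delivered stroke volume, mL.
#' @param frequency Oscillation frequency, Hz.
#' @param rate Sampling rate, Hz. An integer multiple of `frequency`
#'   keeps whole cycles inside each one-second analysis window.
#' @param duration Trace duration, s. At least one cycle.
#' @param noise_sd Noise standard deviation, mL/s.
#' @param seed Optional seed; a fixed seed gives an identical trace.
#' @param t0 Trace start time, s.
#' @return An object of class `flow_trace`: `samples` (mL/s), `rate`
#'   (Hz), `t0` (s).
#' @export
make_flow_trace <- function(actual_sv, frequency = 8, rate = 200,
                            duration = 60, noise_sd = 0, seed = NULL,
                            t0 = 0) {
  stop_if_not_scalar_number(actual_sv, "actual_sv", 0)
  stop_if_not_scalar_number(frequency, "frequency", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(rate, "rate", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  if (duration < 1 / frequency) {
    stop("`duration` must cover at least one oscillation cycle (",
         signif(1 / frequency, 3), " s)", call. = FALSE)
  }
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate
  q0 <- actual_sv * pi * frequency
  samples <- q0 * sin(2 * pi * frequency * t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples <- samples + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "flow_trace")
}

alveolar_exchange_volume <- function(actual_sv, dead_space, transport) {
  transport$conv_coeff * max(actual_sv - dead_space, 0) +
    transport$disp_coeff * actual_sv^transport$disp_power
}

# Per-cycle bookkeeping shared by step_cycle() and the closed forms.
cycle_quantities <- function(config) {
  s <- config$settings
  asv <- resolve_actual_sv(config)
  f <- s$frequency
  list(
    asv = asv,
    f = f,
    v_bf = config$mixing$effective_bf_fraction * s$bias_flow * 1000 / (60 * f),
    v_alv = alveolar_exchange_volume(asv, config$lung$dead_space,
                                     config$transport),
    vco2_cycle = config$lung$vco2_insufflation / (60 * f),
    capno_cycle_per_fraction = config$lung$capno_sample_flow / (60 * f),
    v_container = config$lung$container_volume * 1000)
}

#' One oscillation cycle of the lung-circuit CO2 balance
#'
#' Advances the well-mixed container CO2 fraction across one cycle.
#' Exhaled gas mixes with one cycle's effective bias flow in the
#' inspiratory limb, so the re-inspired fraction is
#' `C_insp = C * aSV / (aSV + V_bf)` with
#' `V_bf = eta * BF * 1000 / (60 f)` mL per cycle. The alveolar exchange
#' volume `V_alv` then swaps container gas at `C` for inspired gas at
#' `C_insp`, CO2 is insufflated at `VCO2/(60 f)` mL per cycle, and the
#' capnometer withdraws `Qs/(60 f)` mL of container gas.
#'
#' @param lung_co2_fraction Current container CO2 fraction, in `[0, 1)`.
#' @param config A [sim_config()].
#' @return List with `fraction` (the next cycle's container fraction) and
#'   `inspired_fraction` (the CO2 fraction of the re-inspired gas).
#' @export
step_cycle <- function(lung_co2_fraction, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(lung_co2_fraction) || lung_co2_fraction < 0 ||
      lung_co2_fraction >= 1) {
    stop("`lung_co2_fraction` must be in [0, 1)", call. = FALSE)
  }
  q <- cycle_quantities(config)
  if (q$v_alv == 0 && config$lung$vco2_insufflation > 0) {
    stop("alveolar exchange volume is zero while CO2 is insufflated: ",
         "no steady state exists (aSV = ", signif(q$asv, 4),
         " mL, VD = ", config$lung$dead_space, " mL)", call. = FALSE)
  }
  c_insp <- lung_co2_fraction * q$asv / (q$asv + q$v_bf)
  delta <- (q$vco2_cycle -
              q$v_alv * (lung_co2_fraction - c_insp) -
              q$capno_cycle_per_fraction * lung_co2_fraction) / q$v_container
  list(fraction = lung_co2_fraction + delta, inspired_fraction = c_insp)
}

#' Analytic steady state of the per-cycle CO2 balance
#'
#' Solves the linear fixed point of [step_cycle()]:
#' `C_ss = VCO2 * (aSV + V_bf) / (60 f * V_alv * V_bf + Qs * (aSV + V_bf))`
#' with VCO2 and the capnometer withdrawal Qs in mL/min and the per-cycle
#' volumes in mL.
#'
#' @param config A [sim_config()].
#' @return List: `fraction` (steady container CO2 fraction), `pco2`
#'   (mmHg), `va` (ratio-scale alveolar ventilation VCO2/PCO2, L/min),
#'   `va_asymptote` (the same quantity in the infinite-bias-flow limit),
#'   and `contraction` (per-cycle map slope, < 1 for valid configs).
#' @export
steady_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q <- cycle_quantities(config)
  lung <- config$lung
  pb <- config$gas$barometric_pressure
  denom <- 60 * q$f * q$v_alv * q$v_bf +
    lung$capno_sample_flow * (q$asv + q$v_bf)
  if (denom <= 0) {
    stop("no CO2 removal path (zero alveolar exchange, zero capnometer ",
         "withdrawal): steady state undefined", call. = FALSE)
  }
  frac <- lung$vco2_insufflation * (q$asv + q$v_bf) / denom
  pco2 <- frac * pb
  frac_inf <- lung$vco2_insufflation /
    (60 * q$f * q$v_alv + lung$capno_sample_flow)
  list(
    fraction = frac,
    pco2 = pco2,
    va = if (pco2 > 0) lung$vco2_insufflation / pco2 else Inf,
    va_asymptote = if (frac_inf > 0) {
      lung$vco2_insufflation / (frac_inf * pb)
    } else {
      Inf
    },
    contraction = 1 - (q$v_alv * q$v_bf / (q$asv + q$v_bf) +
                         q$capno_cycle_per_fraction) / q$v_container)
}

#' Simulate one bench run
#'
#' Iterates [step_cycle()] over the configured duration, then renders the
#' two measured signals: the 200-Hz airway flow sinusoid and the
#' capnometer PCO2 trace (container PCO2 through a first-order sensor lag
#' plus Gaussian noise). Ground truth comes from the analytic steady
#' state, not from the iteration.
#'
#' @param config A [sim_config()].
#' @return An object of class `bench_run`: `flow_trace`, `pco2_trace`,
#'   `truth` (list `actual_sv`, `pco2_ss`, `lung_co2_fraction_ss`,
#'   `va_asymptote`), `config_echo`, `converged` (FALSE, with a warning,
#'   if the final cycle is still drifting more than 0.1% relative), and
#'   `notes`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$settings
  asv <- resolve_actual_sv(config)
  ss <- steady_state(config)
  n_cycles <- max(1L, floor(config$duration * s$frequency))

  frac0 <- if (is.na(config$init_fraction)) ss$fraction else
    config$init_fraction
  fractions <- numeric(n_cycles + 1L)
  fractions[1L] <- frac0
  cur <- frac0
  for (k in seq_len(n_cycles)) {
    cur <- step_cycle(cur, config)$fraction
    fractions[k + 1L] <- cur
  }
  converged <- if (ss$fraction > 0) {
    abs(fractions[n_cycles + 1L] - ss$fraction) / ss$fraction < 1e-3
  } else {
    TRUE
  }
  if (!converged) {
    warning("run did not reach steady state within duration = ",
            config$duration, " s (relative drift > 0.1%)", call. = FALSE)
  }

  flow <- make_flow_trace(asv, s$frequency, config$flow_sample_rate,
                          config$duration, config$noise$flow_sd,
                          seed = config$seed)

  # Capnometer: sample the (piecewise-constant per cycle) container PCO2,
  # pass through a discrete first-order lag, add noise after the lag.
  n_cap <- floor(config$duration * config$capno_sample_rate)
  t_cap <- (seq_len(n_cap) - 1) / config$capno_sample_rate
  idx <- pmin(floor(t_cap * s$frequency), n_cycles) + 1L
  pco2_in <- fractions[idx] * config$gas$barometric_pressure
  dt <- 1 / config$capno_sample_rate
  alpha <- if (config$capno_time_constant > 0) {
    dt / (config$capno_time_constant + dt)
  } else {
    1
  }
  pco2_lag <- numeric(n_cap)
  state <- pco2_in[1L]
  for (i in seq_len(n_cap)) {
    state <- state + alpha * (pco2_in[i] - state)
    pco2_lag[i] <- state
  }
  if (config$noise$pco2_sd > 0) {
    set.seed(config$seed + 1L)
    pco2_lag <- pco2_lag + stats::rnorm(n_cap, 0, config$noise$pco2_sd)
  }
  pco2_lag[pco2_lag < 0] <- 0
  pco2 <- structure(list(samples = pco2_lag,
                         rate = config$capno_sample_rate, t0 = 0),
                    class = "pco2_trace")

  structure(
    list(flow_trace = flow,
         pco2_trace = pco2,
         truth = list(actual_sv = asv,
                      pco2_ss = ss$pco2,
                      lung_co2_fraction_ss = ss$fraction,
                      va_asymptote = ss$va_asymptote),
         config_echo = config,
         converged = converged,
         notes = paste0(
           "container volume held fixed in the CO2 balance; the ",
           s$map_pressure, " cmH2O mean airway pressure compresses the ",
           "gas by <= 2.5% and is ignored")),
    class = "bench_run")
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Simulate a full experimental grid
#'
#' One [simulate_run()] per (stroke volume, bias flow, replicate) cell.
#' In study-1 mode `sv_values` are panel settings (sSV) passed through
#' the attenuation map; in study-2 mode they are target actual stroke
#' volumes delivered directly. Per-run seeds derive deterministically
#' from `seed` so the grid is reproducible as a whole.
#'
#' @param base A [sim_config()] used as the template for every cell.
#' @param sv_values Stroke volumes, mL (sSV for study 1, target aSV for
#'   study 2).
#' @param bf_values Bias flows, L/min.
#' @param replicates Replicates per cell (the bench used 5).
#' @param seed Master seed.
#' @param study 1 or 2.
#' @return List of `bench_run` objects (or, for a failed cell, a
#'   `simpleError`), with attributes `sv`, `bf`, `replicate`, `study`
#'   and `seed` vectors aligned to the list.
#' @export
simulate_grid <- function(base, sv_values, bf_values, replicates = 5,
                          seed = base$seed, study = 1) {
  stopifnot(inherits(base, "sim_config"),
            length(sv_values) >= 1, length(bf_values) >= 1,
            replicates >= 1, study %in% c(1, 2))
  cells <- expand.grid(replicate = seq_len(replicates),
                       bf = bf_values, sv = sv_values)
  cells <- cells[order(cells$sv, cells$bf, cells$replicate), , drop = FALSE]
  runs <- vector("list", nrow(cells))
  seeds <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- base
    cfg$seed <- derive_seed(seed, i)
    seeds[i] <- cfg$seed
    st <- cfg$settings
    st$bias_flow <- cells$bf[i]
    if (study == 1) {
      st$setting_sv <- cells$sv[i]
      cfg$target_asv <- NA_real_
    } else {
      cfg$target_asv <- cells$sv[i]
    }
    cfg$settings <- st
    runs[[i]] <- tryCatch(simulate_run(cfg), error = function(e) e)
  }
  attr(runs, "sv") <- cells$sv
  attr(runs, "bf") <- cells$bf
  attr(runs, "replicate") <- cells$replicate
  attr(runs, "study") <- study
  attr(runs, "seed") <- seeds
  runs
}

#' Simulate the CO2-in-oxygen calibration measurement
#'
#' The insufflated CO2 flow is calibrated by diluting it into a known
#' oxygen flow and reading the mixed partial pressure:
#' `PCO2 = PB * VCO2 / (VCO2 + O2 * 1000)`.
#'
#' @param vco2 True CO2 flow, mL/min.
#' @param o2_flow Diluting oxygen flow, L/min. Positive.
#' @param gas A [gas_conditions()] object.
#' @param noise_sd Capnometer noise on the reading, mmHg.
#' @param seed Optional seed.
#' @return Measured PCO2 of the mixture, mmHg.
#' @examples
#' simulate_calibration(200, 5) # 29.23
#' @export
simulate_calibration <- function(vco2, o2_flow, gas = gas_conditions(),
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(gas, "gas_conditions"))
  stop_if_not_scalar_number(vco2, "vco2", 0)
  stop_if_not_scalar_number(o2_flow, "o2_flow", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  p <- gas$barometric_pressure * vco2 / (vco2 + o2_flow * 1000)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- p + stats::rnorm(1, 0, noise_sd)
  }
  max(p, 0)
}

#' @export
print.bench_run <- function(x, ...) {
  cfg <- x$config_echo
  cat(sprintf(
    "Bench run: aSV = %.1f mL, BF = %g L/min, f = %g Hz, duration = %g s\n",
    x$truth$actual_sv, cfg$settings$bias_flow, cfg$settings$frequency,
    cfg$duration))
  cat(sprintf("  steady-state PCO2 = %.2f mmHg (converged: %s)\n",
              x$truth$pco2_ss, x$converged))
  invisible(x)
}
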