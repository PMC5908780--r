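# Washout analysis: CO2-flow calibration, steady-state PCO2 detection,
# and assembly of one condition's derived ventilation quantities.

#' Stabilization criterion for the PCO2 trace
#'
#' The bench protocol records "the stabilized value" without stating a
#' criterion; this package's default declares a window stabilized when
#' the fitted relative slope is below 1% of the window mean per minute,
#' searched from 120 s onward over 60-s windows.
#'
#' @param window Window length, s.
#' @param max_rel_slope Maximum |slope| relative to the window mean,
#'   fraction per minute.
#' @param min_elapsed Earliest window start considered, s.
#' @return An object of class `stabilization_criterion`.
#' @export
stabilization_criterion <- function(window = 60, max_rel_slope = 0.01,
                                    min_elapsed = 120) {
  stop_if_not_scalar_number(window, "window", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(max_rel_slope, "max_rel_slope", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(min_elapsed, "min_elapsed", 0)
  structure(list(window = window, max_rel_slope = max_rel_slope,
                 min_elapsed = min_elapsed),
            class = "stabilization_criterion")
}

#' Invert the CO2-in-oxygen calibration
#'
#' Exact dilution inversion of [simulate_calibration()]: with mixture
#' fraction `F = PCO2/PB`, the CO2 flow satisfies
#' `VCO2 = F * O2 * 1000 / (1 - F)` mL/min. The exact form is used
#' rather than the linear approximation `F * O2 * 1000`, which is ~4%
#' low at 200 mL/min in 5 L/min.
#'
#' @param pco2_cal Measured PCO2 of the CO2/O2 mixture, mmHg, in
#'   `[0, PB)`.
#' @param o2_flow Diluting oxygen flow, L/min. Positive.
#' @param gas A [gas_conditions()] object.
#' @return Calibrated CO2 flow, mL/min.
#' @examples
#' calibrate_vco2(simulate_calibration(200, 5), 5) # 200
#' @export
calibrate_vco2 <- function(pco2_cal, o2_flow, gas = gas_conditions()) {
  stopifnot(inherits(gas, "gas_conditions"))
  stop_if_not_scalar_number(o2_flow, "o2_flow", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(pco2_cal, "pco2_cal", 0)
  if (pco2_cal >= gas$barometric_pressure) {
    stop("`pco2_cal` must be below barometric pressure (",
         gas$barometric_pressure, " mmHg)", call. = FALSE)
  }
  frac <- pco2_cal / gas$barometric_pressure
  frac * o2_flow * 1000 / (1 - frac)
}

#' Detect the stabilized PCO2 value
#'
#' Slides a window (1-s stride) from `min_elapsed` onward and returns the
#' mean of the first window whose fitted linear slope, relative to the
#' window mean, is below the criterion. If no window qualifies, the final
#' window's mean is returned flagged as not stabilized.
#'
#' @param trace A `pco2_trace`.
#' @param criterion A [stabilization_criterion()].
#' @return List: `pco2` (mmHg), `stabilized` (logical), `t_start`
#'   (window start, s).
#' @export
detect_stabilized_pco2 <- function(trace,
                                   criterion = stabilization_criterion()) {
  stopifnot(inherits(trace, "pco2_trace"),
            inherits(criterion, "stabilization_criterion"))
  rate <- trace$rate
  n <- length(trace$samples)
  win_n <- round(criterion$window * rate)
  total_s <- n / rate
  if (total_s < criterion$min_elapsed + criterion$window) {
    stop("PCO2 trace (", signif(total_s, 4), " s) is shorter than ",
         "min_elapsed + window = ",
         criterion$min_elapsed + criterion$window, " s", call. = FALSE)
  }
  starts_s <- seq(criterion$min_elapsed, total_s - criterion$window, by = 1)
  t_rel <- (seq_len(win_n) - 1) / rate
  t_c <- t_rel - mean(t_rel)
  sxx <- sum(t_c^2)
  for (s0 in starts_s) {
    i0 <- round(s0 * rate)
    y <- trace$samples[(i0 + 1L):(i0 + win_n)]
    m <- mean(y)
    slope <- sum(t_c * y) / sxx              # mmHg per s
    rel_per_min <- if (m > 0) abs(slope) * 60 / m else Inf
    if (rel_per_min < criterion$max_rel_slope) {
      return(list(pco2 = m, stabilized = TRUE, t_start = s0))
    }
  }
  s0 <- starts_s[length(starts_s)]
  i0 <- round(s0 * rate)
  y <- trace$samples[(i0 + 1L):(i0 + win_n)]
  list(pco2 = mean(y), stabilized = FALSE, t_start = s0)
}

#' Derive one condition's ventilation quantities from its traces
#'
#' The full measurement chain for one bench condition: expiratory stroke
#' volume from the flow trace, minute ventilation, stabilized PCO2,
#' alveolar ventilation by the ratio estimator (with the PB-explicit
#' variant alongside), ventilation efficiency and aVE/BF.
#'
#' @param flow A `flow_trace`.
#' @param pco2 A `pco2_trace`.
#' @param settings The condition's [oscillator_settings()].
#' @param vco2 Calibrated CO2 insufflation rate, mL/min.
#' @param gas A [gas_conditions()] object.
#' @param criterion A [stabilization_criterion()].
#' @param average_seconds Seconds of flow averaged into aSV (default 60).
#' @return A [ventilation_result()].
#' @export
analyze_condition <- function(flow, pco2, settings, vco2,
                              gas = gas_conditions(),
                              criterion = stabilization_criterion(),
                              average_seconds = 60) {
  stopifnot(inherits(settings, "oscillator_settings"))
  stop_if_not_scalar_number(vco2, "vco2", 0)

  asv <- tryCatch({
    series <- expiratory_sv_per_second(remove_dc_offset(flow),
                                       settings$frequency)
    mean_sv(series, n = average_seconds)
  }, error = function(e) {
    stop("stroke-volume stage: ", conditionMessage(e), call. = FALSE)
  })
  ave <- minute_ventilation(asv, settings$frequency)

  det <- tryCatch(detect_stabilized_pco2(pco2, criterion),
                  error = function(e) {
                    stop("PCO2 stage: ", conditionMessage(e), call. = FALSE)
                  })

  va <- if (vco2 == 0) 0 else va_ratio_estimator(vco2, det$pco2)
  va_phys <- if (vco2 == 0) 0 else va_physiological(vco2, det$pco2, gas)
  ventilation_result(actual_sv = asv, minute_ventilation = ave,
                     pco2_ss = det$pco2, alveolar_ventilation = va,
                     settings = settings, stabilized = det$stabilized,
                     va_physio = va_phys)
}

#' Tidy results table for a grid of bench runs
#'
#' Analyzes every run of [simulate_grid()] and binds one row per run,
#' ordered by (study, stroke volume, bias flow, replicate). Failed cells
#' are carried as rows of `NA` with the error message in `error`.
#'
#' @param runs A list of `bench_run` objects, as from [simulate_grid()]
#'   (its `sv`/`bf`/`replicate`/`study`/`seed` attributes are used when
#'   present).
#' @param vco2 Calibrated CO2 insufflation rate, mL/min. Default: the
#'   first run's configured insufflation rate.
#' @param gas A [gas_conditions()] object.
#' @param criterion A [stabilization_criterion()].
#' @return A `data.frame`, one row per run: `study`, `sv`, `bias_flow`,
#'   `replicate`, `seed`, `actual_sv`, `minute_ventilation`, `pco2_ss`,
#'   `alveolar_ventilation`, `va_physio`, `efficiency`, `ve_bf_ratio`,
#'   `stabilized`, `error`.
#' @export
build_results_table <- function(runs, vco2 = NULL,
                                gas = gas_conditions(),
                                criterion = stabilization_criterion()) {
  if (length(runs) == 0L) stop("`runs` is empty", call. = FALSE)
  n <- length(runs)
  sv <- attr(runs, "sv") %||% rep(NA_real_, n)
  bf <- attr(runs, "bf") %||% rep(NA_real_, n)
  rep_id <- attr(runs, "replicate") %||% seq_len(n)
  study <- attr(runs, "study") %||% NA_integer_
  seeds <- attr(runs, "seed") %||% rep(NA_integer_, n)
  if (is.null(vco2)) {
    first_ok <- Find(function(r) inherits(r, "bench_run"), runs)
    if (is.null(first_ok)) stop("no successful runs", call. = FALSE)
    vco2 <- first_ok$config_echo$lung$vco2_insufflation
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- runs[[i]]
    base <- data.frame(study = study, sv = sv[i], bias_flow = bf[i],
                       replicate = rep_id[i], seed = seeds[i])
    if (inherits(r, "bench_run")) {
      res <- tryCatch(
        analyze_condition(r$flow_trace, r$pco2_trace,
                          r$config_echo$settings, vco2, gas, criterion),
        error = function(e) e)
    } else {
      res <- r
    }
    if (inherits(res, "ventilation_result")) {
      rows[[i]] <- cbind(base, data.frame(
        actual_sv = res$actual_sv,
        minute_ventilation = res$minute_ventilation,
        pco2_ss = res$pco2_ss,
        alveolar_ventilation = res$alveolar_ventilation,
        va_physio = res$va_physio,
        efficiency = res$efficiency,
        ve_bf_ratio = res$ve_bf_ratio,
        stabilized = res$stabilized,
        error = NA_character_))
    } else {
      rows[[i]] <- cbind(base, data.frame(
        actual_sv = NA_real_, minute_ventilation = NA_real_,
        pco2_ss = NA_real_, alveolar_ventilation = NA_real_,
        va_physio = NA_real_, efficiency = NA_real_,
        ve_bf_ratio = NA_real_, stabilized = NA,
        error = conditionMessage(res)))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$study, out$sv, out$bias_flow, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
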