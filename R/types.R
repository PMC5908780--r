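# Domain containers for the bench: ventilator state, lung model, gas
# conditions and circuit-mixing assumptions. Plain validated lists with
# lightweight S3 classes, in the style of survival/vegan option objects.

#' Conversion factor: cmH2O per mmHg
#'
#' Used when an absolute pressure stated in mmHg must be expressed in
#' cmH2O (e.g. gas-compression compliance of a rigid container).
#' @export
CMH2O_PER_MMHG <- 1.35951

#' Body-temperature (BTPS) conversion constant of the alveolar ventilation
#' equation, mmHg per (mL/min CO2 output per L/min alveolar ventilation).
#' @export
BTPS_FACTOR <- 0.863

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  invisible(x)
}

#' Oscillator settings
#'
#' The ventilator state common to one experimental condition.
#'
#' @param frequency Oscillation rate, Hz. Must be positive.
#' @param setting_sv Stroke volume as set on the panel (sSV), mL.
#' @param map_pressure Mean airway pressure, cmH2O.
#' @param bias_flow Bias flow (BF), L/min. Must be positive.
#' @param fio2 Inspired oxygen fraction, in `[0.21, 1]`.
#' @param insp_fraction Inspiratory time fraction, in (0, 1). The adult
#'   oscillator modelled here fixes this at 0.5.
#'
#' @return An object of class `oscillator_settings`.
#' @examples
#' oscillator_settings(frequency = 8, setting_sv = 120, bias_flow = 20)
#' @export
oscillator_settings <- function(frequency = 8, setting_sv = 100,
                                map_pressure = 25, bias_flow = 20,
                                fio2 = 0.21, insp_fraction = 0.5) {
  stop_if_not_scalar_number(frequency, "frequency", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(setting_sv, "setting_sv", 0)
  stop_if_not_scalar_number(map_pressure, "map_pressure", 0)
  stop_if_not_scalar_number(bias_flow, "bias_flow", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(fio2, "fio2", 0.21, 1.0)
  stop_if_not_scalar_number(insp_fraction, "insp_fraction", 0, 1,
                            strict_lower = TRUE)
  if (insp_fraction >= 1) stop("`insp_fraction` must be < 1", call. = FALSE)
  structure(
    list(frequency = frequency, setting_sv = setting_sv,
         map_pressure = map_pressure, bias_flow = bias_flow,
         fio2 = fio2, insp_fraction = insp_fraction),
    class = "oscillator_settings")
}

#' Test-lung specification
#'
#' Geometry and gas-exchange plumbing of the rigid-container lung model:
#' a well-mixed airtight container with continuous CO2 insufflation and
#' sidestream capnometer sampling.
#'
#' @param container_volume Total gas volume of the container, L.
#' @param dead_space Dead-space volume VD (circuit + simulated airways), mL.
#' @param airway_resistance Airway resistance, cmH2O/L/s. Metadata only;
#'   not used by the mass-balance computations.
#' @param vco2_insufflation CO2 inflow rate, mL/min.
#' @param capno_sample_flow Gas withdrawal rate of the capnometer, mL/min.
#'   Withdrawn gas is assumed not to return to the container.
#' @param well_mixed Logical; the container is stirred (fan), so a single
#'   compartment CO2 fraction is meaningful.
#'
#' @return An object of class `lung_model_spec`.
#' @export
lung_model_spec <- function(container_volume = 20, dead_space = 110,
                            airway_resistance = 2.0,
                            vco2_insufflation = 200,
                            capno_sample_flow = 200,
                            well_mixed = TRUE) {
  stop_if_not_scalar_number(container_volume, "container_volume", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(dead_space, "dead_space", 0)
  stop_if_not_scalar_number(airway_resistance, "airway_resistance", 0)
  stop_if_not_scalar_number(vco2_insufflation, "vco2_insufflation", 0)
  stop_if_not_scalar_number(capno_sample_flow, "capno_sample_flow", 0)
  if (!is.logical(well_mixed) || length(well_mixed) != 1L) {
    stop("`well_mixed` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(container_volume = container_volume, dead_space = dead_space,
         airway_resistance = airway_resistance,
         vco2_insufflation = vco2_insufflation,
         capno_sample_flow = capno_sample_flow, well_mixed = well_mixed),
    class = "lung_model_spec")
}

#' Gas reporting conditions
#'
#' @param barometric_pressure Barometric pressure PB, mmHg.
#' @param btps Logical; if `TRUE` the physiological alveolar-ventilation
#'   estimator uses the BTPS constant 0.863 instead of the dry-gas
#'   `PB/1000` factor. The bench itself runs at ambient dry conditions.
#' @return An object of class `gas_conditions`.
#' @export
gas_conditions <- function(barometric_pressure = 760, btps = FALSE) {
  stop_if_not_scalar_number(barometric_pressure, "barometric_pressure", 0,
                            strict_lower = TRUE)
  if (!is.logical(btps) || length(btps) != 1L) {
    stop("`btps` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(barometric_pressure = barometric_pressure,
         temperature_note = "ATPD", btps = btps,
         btps_factor = BTPS_FACTOR),
    class = "gas_conditions")
}

#' Circuit gas-mixing assumption
#'
#' @param effective_bf_fraction Fraction eta of the bias flow that mixes
#'   completely with exhaled gas in the inspiratory limb ("effective"
#'   bias flow), in (0, 1].
#' @return An object of class `mixing_params`.
#' @export
mixing_params <- function(effective_bf_fraction = 1.0) {
  stop_if_not_scalar_number(effective_bf_fraction, "effective_bf_fraction",
                            0, 1, strict_lower = TRUE)
  structure(list(effective_bf_fraction = effective_bf_fraction),
            class = "mixing_params")
}

#' One condition's derived ventilation quantities
#'
#' Bundle of everything derived from one bench condition: the measured
#' actual stroke volume, actual minute ventilation, stabilized CO2 partial
#' pressure, alveolar ventilation and the two efficiency ratios.
#'
#' @param actual_sv Measured actual stroke volume (aSV), mL.
#' @param minute_ventilation Actual minute ventilation aVE, L/min.
#' @param pco2_ss Stabilized CO2 partial pressure, mmHg.
#' @param alveolar_ventilation VA, L/min (ratio-estimator scale).
#' @param settings The generating [oscillator_settings()].
#' @param stabilized Logical; whether the PCO2 trace met the
#'   stabilization criterion.
#' @param va_physio Optional PB-explicit alveolar ventilation, L/min.
#'
#' @return An object of class `ventilation_result`. Efficiency (VA/aVE)
#'   and aVE/BF are computed from the supplied fields.
#' @export
ventilation_result <- function(actual_sv, minute_ventilation, pco2_ss,
                               alveolar_ventilation, settings,
                               stabilized = TRUE, va_physio = NA_real_) {
  stopifnot(inherits(settings, "oscillator_settings"))
  stop_if_not_scalar_number(actual_sv, "actual_sv", 0)
  stop_if_not_scalar_number(minute_ventilation, "minute_ventilation", 0)
  stop_if_not_scalar_number(pco2_ss, "pco2_ss", 0)
  stop_if_not_scalar_number(alveolar_ventilation, "alveolar_ventilation", 0)
  eff <- if (minute_ventilation > 0) {
    efficiency_index(alveolar_ventilation, minute_ventilation)
  } else {
    NA_real_
  }
  structure(
    list(actual_sv = actual_sv,
         minute_ventilation = minute_ventilation,
         pco2_ss = pco2_ss,
         alveolar_ventilation = alveolar_ventilation,
         va_physio = va_physio,
         efficiency = eff,
         ve_bf_ratio = ve_bf_ratio(minute_ventilation, settings$bias_flow),
         stabilized = isTRUE(stabilized),
         settings = settings),
    class = "ventilation_result")
}

#' @export
print.oscillator_settings <- function(x, ...) {
  cat(sprintf(
    "Oscillator settings: f = %g Hz, sSV = %g mL, MAP = %g cmH2O, BF = %g L/min, FiO2 = %.2f, Ti = %.0f%%\n",
    x$frequency, x$setting_sv, x$map_pressure, x$bias_flow, x$fio2,
    100 * x$insp_fraction))
  invisible(x)
}

#' @export
print.ventilation_result <- function(x, ...) {
  cat("Ventilation result (one condition)\n")
  cat(sprintf("  aSV     = %8.2f mL      aVE    = %6.2f L/min\n",
              x$actual_sv, x$minute_ventilation))
  cat(sprintf("  PCO2ss  = %8.2f mmHg    VA     = %6.2f L/min%s\n",
              x$pco2_ss, x$alveolar_ventilation,
              if (x$stabilized) "" else "  [not stabilized]"))
  cat(sprintf("  VA/aVE  = %8.3f         aVE/BF = %6.2f\n",
              x$efficiency, x$ve_bf_ratio))
  invisible(x)
}
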