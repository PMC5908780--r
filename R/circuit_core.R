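# Closed-form circuit/physiology relations: minute ventilation, the
# alveolar-ventilation estimators, bias-flow dilution and rebreathing,
# required-bias-flow algebra and gas-compression compliance. All pure.

#' Actual minute ventilation from stroke volume and frequency
#'
#' aVE = aSV/1000 x f x 60, i.e. the volume delivered per minute at the
#' airway opening.
#'
#' @param actual_sv Actual stroke volume, mL. Non-negative.
#' @param frequency Oscillation frequency, Hz. Positive.
#' @return Minute ventilation, L/min.
#' @examples
#' minute_ventilation(80, 8)   # 38.4
#' minute_ventilation(120, 8)  # 57.6
#' @export
minute_ventilation <- function(actual_sv, frequency) {
  stop_if_not_scalar_number(actual_sv, "actual_sv", 0)
  stop_if_not_scalar_number(frequency, "frequency", 0, strict_lower = TRUE)
  actual_sv / 1000 * frequency * 60
}

#' Alveolar ventilation, ratio form
#'
#' The bench estimator VA = VCO2 / PCO2: CO2 insufflation rate in mL/min
#' divided by the stabilized CO2 partial pressure in mmHg, reported on the
#' study's L/min scale. Valid for the dry room-temperature bench where the
#' lung-model CO2 fraction, not a body-conditions alveolar gas, is
#' monitored. See [va_physiological()] for the PB-explicit form.
#'
#' @param vco2 CO2 output (insufflation) rate, mL/min. Non-negative.
#' @param pco2 Stabilized CO2 partial pressure, mmHg. Positive.
#' @return Alveolar ventilation on the ratio scale, L/min.
#' @examples
#' va_ratio_estimator(200, 10)  # 20
#' @export
va_ratio_estimator <- function(vco2, pco2) {
  stop_if_not_scalar_number(vco2, "vco2", 0)
  if (!is.numeric(pco2) || length(pco2) != 1L || !is.finite(pco2) ||
      pco2 <= 0) {
    stop("`pco2` must be > 0 mmHg: the ratio estimator VCO2/PCO2 is ",
         "undefined at or below zero", call. = FALSE)
  }
  vco2 / pco2
}

#' Alveolar ventilation, dimensionally explicit form
#'
#' Dry-gas mass balance: VA (L/min) = (VCO2/1000) x PB / PCO2, i.e. the
#' fresh-gas flow that would carry away VCO2 at a steady fraction
#' PCO2/PB. With `gas$btps = TRUE` the body-conditions alveolar
#' ventilation equation is used instead: VA = 0.863 x VCO2 / PCO2.
#'
#' @inheritParams va_ratio_estimator
#' @param gas A [gas_conditions()] object.
#' @return Alveolar ventilation, L/min.
#' @examples
#' va_physiological(200, 15.2, gas_conditions(760))       # 10
#' va_physiological(200, 40, gas_conditions(btps = TRUE)) # 4.315
#' @export
va_physiological <- function(vco2, pco2, gas = gas_conditions()) {
  stopifnot(inherits(gas, "gas_conditions"))
  stop_if_not_scalar_number(vco2, "vco2", 0)
  if (!is.numeric(pco2) || length(pco2) != 1L || !is.finite(pco2) ||
      pco2 <= 0) {
    stop("`pco2` must be > 0 mmHg", call. = FALSE)
  }
  if (isTRUE(gas$btps)) {
    gas$btps_factor * vco2 / pco2
  } else {
    (vco2 / 1000) * gas$barometric_pressure / pco2
  }
}

#' Mean rebreathed CO2 partial pressure under full mixing
#'
#' In steady state all insufflated CO2 leaves through the expiratory
#' circuit, so the mean exhausted CO2 fraction is VCO2/BF. If the whole
#' bias flow mixes completely with exhaled gas ("all bias flow
#' effective"), the mean rebreathed partial pressure equals that fraction
#' times barometric pressure. A smaller effective fraction can only raise
#' the true rebreathed value, so this is a lower bound.
#'
#' @param vco2 CO2 output rate, mL/min. Non-negative.
#' @param bias_flow Bias flow, L/min. Positive.
#' @param gas A [gas_conditions()] object.
#' @return Mean rebreathed PCO2, mmHg.
#' @examples
#' rebreathing_pco2(200, 10) # 15.2
#' rebreathing_pco2(200, 40) # 3.8
#' @export
rebreathing_pco2 <- function(vco2, bias_flow, gas = gas_conditions()) {
  stopifnot(inherits(gas, "gas_conditions"))
  stop_if_not_scalar_number(vco2, "vco2", 0)
  stop_if_not_scalar_number(bias_flow, "bias_flow", 0, strict_lower = TRUE)
  (vco2 / (bias_flow * 1000)) * gas$barometric_pressure
}

#' Minute-ventilation to bias-flow ratio
#'
#' The per-minute form of the per-cycle aSV:(BF/cycle) ratio that governs
#' how strongly exhaled CO2 is diluted in the inspiratory limb before the
#' next inspiration.
#'
#' @param minute_ventilation aVE, L/min. Non-negative.
#' @param bias_flow Bias flow, L/min. Positive.
#' @return The dimensionless ratio aVE/BF.
#' @examples
#' ve_bf_ratio(38.4, 10) # 3.84
#' @export
ve_bf_ratio <- function(minute_ventilation, bias_flow) {
  stop_if_not_scalar_number(minute_ventilation, "minute_ventilation", 0)
  stop_if_not_scalar_number(bias_flow, "bias_flow", 0, strict_lower = TRUE)
  minute_ventilation / bias_flow
}

#' Bias flow required to hold a target aVE/BF ratio
#'
#' @param target_ratio Desired aVE/BF. Positive.
#' @param minute_ventilation aVE, L/min. Non-negative.
#' @return Required bias flow, L/min.
#' @examples
#' required_bias_flow(3.84, minute_ventilation(100, 8)) # 12.5
#' required_bias_flow(3.84, minute_ventilation(120, 8)) # 15
#' @export
required_bias_flow <- function(target_ratio, minute_ventilation) {
  stop_if_not_scalar_number(target_ratio, "target_ratio", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(minute_ventilation, "minute_ventilation", 0)
  minute_ventilation / target_ratio
}

#' Gas-compression compliance of a rigid container
#'
#' Ideal-gas differential compliance dV/dP of a fixed gas volume V at
#' absolute pressure P: V/P for isothermal compression and V/(gamma P)
#' for adiabatic compression. A 20-L container near 1 atm is compliant
#' only through gas compression, about 19.4 mL/cmH2O isothermally.
#'
#' @param volume Container gas volume, L. Positive.
#' @param pressure_abs Absolute pressure, cmH2O. Positive
#'   (1 atm = 760 mmHg = 1033.2 cmH2O).
#' @param mode `"isothermal"` (default) or `"adiabatic"`. The default is
#'   isothermal: slow bench manoeuvres equilibrate temperature with the
#'   container walls.
#' @param gamma Adiabatic index (heat-capacity ratio), >= 1; 1.4 for air.
#' @return Compliance, mL/cmH2O.
#' @examples
#' gas_compression_compliance(20, 760 * CMH2O_PER_MMHG) # 19.36
#' @export
gas_compression_compliance <- function(volume, pressure_abs,
                                       mode = c("isothermal", "adiabatic"),
                                       gamma = 1.4) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(volume, "volume", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(pressure_abs, "pressure_abs", 0,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(gamma, "gamma", 1)
  if (mode == "isothermal") {
    1000 * volume / pressure_abs
  } else {
    1000 * volume / (gamma * pressure_abs)
  }
}

#' Ventilation-efficiency index
#'
#' The fraction of the delivered minute volume that is effective for CO2
#' elimination: VA / aVE.
#'
#' @param alveolar_ventilation VA, L/min. Non-negative.
#' @param minute_ventilation aVE, L/min. Positive.
#' @return Dimensionless efficiency (reported as a fraction, not percent).
#' @examples
#' efficiency_index(19.2, 38.4) # 0.5
#' @export
efficiency_index <- function(alveolar_ventilation, minute_ventilation) {
  stop_if_not_scalar_number(alveolar_ventilation, "alveolar_ventilation", 0)
  stop_if_not_scalar_number(minute_ventilation, "minute_ventilation", 0,
                            strict_lower = TRUE)
  alveolar_ventilation / minute_ventilation
}
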