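# File formats: two-column delimited time series with a '#'-prefixed
# header block, tidy TSV tables with a schema header, and a strict JSON
# configuration file.

#' Write a flow or PCO2 trace to a delimited time-series file
#'
#' Two tab-separated columns (time in s, value) preceded by a `#` header
#' block carrying type, sampling rate, units and start time.
#'
#' @param trace A `flow_trace` or `pco2_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "flow_trace")) {
    type <- "flow"; units <- "mL/s"
  } else if (inherits(trace, "pco2_trace")) {
    type <- "pco2"; units <- "mmHg"
  } else {
    stop("`trace` must be a flow_trace or pco2_trace", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hfovbench trace v1",
               paste0("# type: ", type),
               paste0("# rate_hz: ", format(trace$rate, digits = 15)),
               paste0("# t0_s: ", format(trace$t0, digits = 15)),
               paste0("# units: ", units),
               "time\tvalue"), con)
  t <- trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
  utils::write.table(
    data.frame(time = t, value = trace$samples),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path File path.
#' @return A `flow_trace` or `pco2_trace` according to the header.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 6L)
  if (length(lines) < 6L || lines[1L] != "# hfovbench trace v1") {
    stop("not an hfovbench trace file: ", path, call. = FALSE)
  }
  header_val <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(ln) != 1L) {
      stop("trace header missing field `", key, "`: ", path, call. = FALSE)
    }
    sub(paste0("^# ", key, ": "), "", ln)
  }
  type <- header_val("type")
  rate <- as.numeric(header_val("rate_hz"))
  t0 <- as.numeric(header_val("t0_s"))
  dat <- utils::read.table(path, header = TRUE, sep = "\t", skip = 5L)
  cls <- switch(type, flow = "flow_trace", pco2 = "pco2_trace",
                stop("unknown trace type `", type, "`", call. = FALSE))
  structure(list(samples = dat$value, rate = rate, t0 = t0), class = cls)
}

#' Write a tidy results table with a schema header
#'
#' @param table A data.frame (e.g. from [build_results_table()]).
#' @param path Output file path.
#' @param schema Short schema tag recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path, schema = "results v1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hfovbench table v1",
               paste0("# schema: ", schema),
               paste0("# columns: ", paste(names(table), collapse = ","))),
             con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path File path.
#' @return A data.frame; the schema tag is attached as attribute
#'   `"schema"`.
#' @export
read_results_table <- function(path) {
  lines <- readLines(path, n = 3L)
  if (length(lines) < 3L || lines[1L] != "# hfovbench table v1") {
    stop("not an hfovbench table file: ", path, call. = FALSE)
  }
  dat <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3L,
                           na.strings = "NA", stringsAsFactors = FALSE)
  attr(dat, "schema") <- sub("^# schema: ", "", lines[2L])
  dat
}

config_schema_v1 <- list(
  version = "character",
  settings = c("frequency", "setting_sv", "map_pressure", "bias_flow",
               "fio2", "insp_fraction"),
  lung = c("container_volume", "dead_space", "airway_resistance",
           "vco2_insufflation", "capno_sample_flow", "well_mixed"),
  mixing = "effective_bf_fraction",
  gas = c("barometric_pressure", "btps"),
  attenuation = c("slope_base", "slope_bf_penalty", "intercept"),
  transport = c("conv_coeff", "disp_coeff", "disp_power"),
  sampling = c("flow_sample_rate", "capno_sample_rate",
               "capno_time_constant"),
  noise = c("flow_sd", "pco2_sd"),
  run = c("duration", "seed", "init_fraction"),
  grid = c("study", "sv_values", "bf_values", "replicates"))

#' Read a simulation/grid configuration file
#'
#' Strict JSON with a versioned schema: unknown top-level or nested keys
#' are errors, so typos fail fast instead of silently reverting to
#' defaults. Any known key may be omitted, in which case the package
#' default applies. The `grid` block (study, sv_values, bf_values,
#' replicates) describes the experimental design.
#'
#' @param path Path to a JSON configuration file.
#' @return List with `config` (a [sim_config()]) and `grid`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  unknown <- setdiff(names(raw), names(config_schema_v1))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$version) && !identical(raw$version, "1")) {
    stop("unsupported config version `", raw$version, "`", call. = FALSE)
  }
  for (blk in setdiff(names(config_schema_v1), "version")) {
    if (!is.null(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), config_schema_v1[[blk]])
      if (length(bad) > 0L) {
        stop("unknown key(s) in `", blk, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  fill <- function(given, defaults) {
    out <- as.list(defaults)
    for (k in names(given)) out[[k]] <- given[[k]]
    out
  }
  settings <- do.call(oscillator_settings,
                      fill(raw$settings, formals(oscillator_settings)))
  lung <- do.call(lung_model_spec,
                  fill(raw$lung, formals(lung_model_spec)))
  mixing <- do.call(mixing_params,
                    fill(raw$mixing, formals(mixing_params)))
  gas <- do.call(gas_conditions,
                 fill(raw$gas, formals(gas_conditions)))
  defaults <- sim_config()
  cfg <- sim_config(
    settings = settings, lung = lung, mixing = mixing, gas = gas,
    attenuation = fill(raw$attenuation, defaults$attenuation),
    transport = fill(raw$transport, defaults$transport),
    flow_sample_rate = raw$sampling$flow_sample_rate %||%
      defaults$flow_sample_rate,
    capno_sample_rate = raw$sampling$capno_sample_rate %||%
      defaults$capno_sample_rate,
    capno_time_constant = raw$sampling$capno_time_constant %||%
      defaults$capno_time_constant,
    noise = fill(raw$noise, defaults$noise),
    duration = raw$run$duration %||% defaults$duration,
    seed = raw$run$seed %||% defaults$seed,
    init_fraction = {
      ifr <- raw$run$init_fraction
      if (is.null(ifr) || length(ifr) != 1L ||
          is.na(suppressWarnings(as.numeric(ifr)))) {
        NA_real_
      } else {
        as.numeric(ifr)
      }
    })
  grid <- list(study = raw$grid$study %||% 2,
               sv_values = raw$grid$sv_values %||% c(80, 100, 120),
               bf_values = raw$grid$bf_values %||% seq(10, 60, by = 10),
               replicates = raw$grid$replicates %||% 5)
  list(config = cfg, grid = grid)
}

#' Write a configuration file capturing a [sim_config()] and grid
#'
#' @param config A [sim_config()].
#' @param grid List with `study`, `sv_values`, `bf_values`, `replicates`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, grid, path) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$settings
  obj <- list(
    version = "1",
    settings = s[c("frequency", "setting_sv", "map_pressure", "bias_flow",
                   "fio2", "insp_fraction")],
    lung = config$lung[c("container_volume", "dead_space",
                         "airway_resistance", "vco2_insufflation",
                         "capno_sample_flow", "well_mixed")],
    mixing = config$mixing["effective_bf_fraction"],
    gas = config$gas[c("barometric_pressure", "btps")],
    attenuation = config$attenuation,
    transport = config$transport,
    sampling = list(flow_sample_rate = config$flow_sample_rate,
                    capno_sample_rate = config$capno_sample_rate,
                    capno_time_constant = config$capno_time_constant),
    noise = config$noise,
    run = list(duration = config$duration, seed = config$seed,
               init_fraction = config$init_fraction),
    grid = grid)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
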