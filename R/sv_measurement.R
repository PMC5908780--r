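# Stroke-volume measurement: per-second expiratory volume by trapezoidal
# integration of the sampled flow signal, averaged over one minute.

#' Remove the DC offset of a flow trace
#'
#' Subtracts the whole-trace mean so the oscillatory signal is zero-mean
#' and the expiratory lobes can be identified by sign alone.
#'
#' @param trace A `flow_trace` (see [make_flow_trace()]).
#' @return A `flow_trace` with zero-mean samples.
#' @export
remove_dc_offset <- function(trace) {
  stopifnot(inherits(trace, "flow_trace"))
  if (length(trace$samples) == 0L) {
    stop("flow trace is empty", call. = FALSE)
  }
  trace$samples <- trace$samples - mean(trace$samples)
  trace
}

#' Per-second expiratory stroke volume
#'
#' For each full second of the trace, integrates the expiratory
#' (negative) flow samples by the trapezoidal rule and divides the
#' magnitude by the number of oscillation cycles in the window, yielding
#' one stroke volume per second, in mL per cycle. At the bench rates
#' (8 Hz oscillation sampled at 200 Hz) each window holds exactly eight
#' whole cycles of 25 samples. A partial trailing second is discarded.
#'
#' @param trace A `flow_trace`, at least 1 s long.
#' @param frequency Oscillation frequency, Hz. Used only to convert the
#'   per-window expiratory volume to a per-cycle stroke volume.
#' @return An object of class `sv_series`: `per_second_sv` (mL) and
#'   `n_seconds`.
#' @export
expiratory_sv_per_second <- function(trace, frequency = 8) {
  stopifnot(inherits(trace, "flow_trace"))
  stop_if_not_scalar_number(frequency, "frequency", 0, strict_lower = TRUE)
  rate <- trace$rate
  n_win <- floor(length(trace$samples) / rate)
  if (n_win < 1L) {
    stop("flow trace must cover at least one full second (",
         length(trace$samples), " samples at ", rate, " Hz)",
         call. = FALSE)
  }
  per_sec <- numeric(n_win)
  for (w in seq_len(n_win)) {
    v <- trace$samples[((w - 1L) * rate + 1L):(w * rate)]
    v <- pmin(v, 0)
    trapz <- (sum(v) - (v[1L] + v[length(v)]) / 2) / rate
    per_sec[w] <- abs(trapz) / frequency
  }
  structure(list(per_second_sv = per_sec, n_seconds = n_win),
            class = "sv_series")
}

#' Mean stroke volume over the first n seconds
#'
#' The bench protocol: the mean of 60 one-second measurements is reported
#' as the actual stroke volume.
#'
#' @param series An `sv_series` from [expiratory_sv_per_second()].
#' @param n Number of leading per-second values to average (default 60).
#' @return Mean stroke volume, mL.
#' @export
mean_sv <- function(series, n = 60) {
  stopifnot(inherits(series, "sv_series"))
  stop_if_not_scalar_number(n, "n", 1)
  if (series$n_seconds < n) {
    stop("sv series holds only ", series$n_seconds,
         " per-second values; ", n, " requested", call. = FALSE)
  }
  mean(series$per_second_sv[seq_len(n)])
}

#' @export
print.sv_series <- function(x, ...) {
  cat(sprintf("SV series: %d per-second values, mean %.2f mL (sd %.3f)\n",
              x$n_seconds, mean(x$per_second_sv),
              stats::sd(x$per_second_sv)))
  invisible(x)
}
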