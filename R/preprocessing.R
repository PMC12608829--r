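#' Raw constant-capacitance (CONCAP) voltage trace
#'
#' One recorded bias-voltage time series at a fixed bulk substrate
#' concentration. In constant-capacitance mode the bias voltage tracking a
#' fixed capacitance follows the surface pH; after the settling transient the
#' trace approaches a pseudo-steady-state plateau.
#'
#' @param time Sample times, s, strictly increasing.
#' @param voltage Voltages, V (same length as `time`).
#' @param s_b Bulk substrate concentration for this trace, mol/L (>= 0).
#' @param sensor_id Sensor identifier.
#' @param medium Free-text medium label.
#'
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(time, voltage, s_b, sensor_id = "sensor-1",
                          medium = "") {
  stopifnot(is.numeric(time), is.numeric(voltage),
            length(time) == length(voltage), length(time) >= 2L,
            is.numeric(s_b), length(s_b) == 1L, s_b >= 0)
  if (any(diff(time) <= 0)) stop("trace times must be strictly increasing")
  if (any(!is.finite(voltage))) stop("trace voltages must be finite")
  structure(list(time = time, voltage = voltage, s_b = s_b,
                 sensor_id = sensor_id, medium = medium),
            class = "voltage_trace")
}

#' Sensor pH calibration
#'
#' Linear voltage-to-pH map anchored at the start of the measurement:
#' `pH = pH0 + (V0 - Vx) / S_pH`. `S_pH` is stored in V per pH unit with the
#' sign convention that a voltage decrease corresponds to a pH increase
#' (alkalinization lowers the tracked bias voltage); the synthetic trace
#' generator uses the same convention.
#'
#' @param pH0 pH at the start of the measurement (no substrate), in (0, 14).
#' @param V0 Voltage at the start of the measurement, V.
#' @param S_pH Sensitivity, V per pH unit (non-zero). Typical pH-sensitive
#'   Ta2O5 gates give 0.030-0.035 V/pH.
#'
#' @return An object of class `sensor_calibration`.
#' @export
sensor_calibration <- function(pH0, V0, S_pH) {
  stopifnot(is.numeric(pH0), length(pH0) == 1L, pH0 > 0, pH0 < 14,
            is.numeric(V0), length(V0) == 1L, is.finite(V0),
            is.numeric(S_pH), length(S_pH) == 1L, is.finite(S_pH))
  if (S_pH == 0) stop("S_pH must be non-zero")
  structure(list(pH0 = pH0, V0 = V0, S_pH = S_pH),
            class = "sensor_calibration")
}

#' Reduce a CONCAP trace to its pseudo-steady-state voltage
#'
#' The plateau voltage is taken as the arithmetic mean of the last `window`
#' samples, by when the settling transient is assumed to have decayed and the
#' reaction to have reached its pseudo-steady state.
#'
#' @param trace A [voltage_trace()].
#' @param window Number of trailing samples to average (default 100).
#' @param slope_warn Optional V/s threshold: warn if the fitted linear slope
#'   over the averaging window exceeds it in magnitude (residual drift).
#'
#' @return Plateau voltage Vx, V.
#' @export
concap_reduce <- function(trace, window = 100L, slope_warn = NULL) {
  stopifnot(inherits(trace, "voltage_trace"), window >= 1L)
  n <- length(trace$voltage)
  if (n < window) {
    stop(sprintf("trace has %d samples, fewer than the %d-sample window",
                 n, window))
  }
  idx <- (n - window + 1L):n
  if (!is.null(slope_warn)) {
    slope <- stats::coef(stats::lm(trace$voltage[idx] ~ trace$time[idx]))[2L]
    if (abs(slope) > slope_warn) {
      warning(sprintf("window slope %.3g V/s exceeds %.3g V/s: trace may not have settled",
                      slope, slope_warn))
    }
  }
  mean(trace$voltage[idx])
}

#' Convert a plateau voltage to pH (and back)
#'
#' `voltage_to_pH` applies the linear map `pH = pH0 + (V0 - Vx) / S_pH`;
#' `pH_to_voltage` inverts it exactly.
#'
#' @param Vx Plateau voltage(s), V.
#' @param cal A [sensor_calibration()].
#'
#' @return pH value(s) (or voltages, for the inverse).
#' @export
voltage_to_pH <- function(Vx, cal) {
  stopifnot(inherits(cal, "sensor_calibration"), is.numeric(Vx))
  cal$pH0 + (cal$V0 - Vx) / cal$S_pH
}

#' @rdname voltage_to_pH
#' @param pH pH value(s) to map back to voltage.
#' @export
pH_to_voltage <- function(pH, cal) {
  stopifnot(inherits(cal, "sensor_calibration"), is.numeric(pH))
  cal$V0 - (pH - cal$pH0) * cal$S_pH
}

#' Build a calibration dataset from raw voltage traces
#'
#' Reduces each trace with [concap_reduce()], converts plateau voltages to pH
#' with [voltage_to_pH()], and assembles a [calibration_dataset()] sorted by
#' concentration. When no explicit calibration is given, the plateau of the
#' zero-concentration trace defines `V0`, the chemistry's bulk pH defines
#' `pH0`, and `S_pH` must be supplied.
#'
#' @param traces List of [voltage_trace()] objects sharing one sensor id, with
#'   distinct concentrations.
#' @param chemistry A [biosensor_chemistry()] for the resulting dataset.
#' @param cal A [sensor_calibration()], or `NULL` to derive `pH0`/`V0` from
#'   the zero-concentration trace.
#' @param S_pH Sensitivity used when `cal` is `NULL`, V/pH.
#' @param window Trailing-sample window for [concap_reduce()].
#' @param medium Medium label for the dataset.
#'
#' @return A [calibration_dataset()].
#' @export
build_dataset <- function(traces, chemistry, cal = NULL, S_pH = 0.033,
                          window = 100L, medium = "") {
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "voltage_trace")))
  ids <- unique(vapply(traces, `[[`, character(1), "sensor_id"))
  if (length(ids) > 1L) {
    stop("traces come from different sensors: ", paste(ids, collapse = ", "))
  }
  s_b <- vapply(traces, `[[`, numeric(1), "s_b")
  if (anyDuplicated(s_b)) {
    stop("duplicated trace concentrations: ",
         paste(format(unique(s_b[duplicated(s_b)])), collapse = ", "))
  }
  Vx <- vapply(traces, concap_reduce, numeric(1), window = window)
  if (is.null(cal)) {
    i0 <- which(s_b == 0)
    if (!length(i0)) {
      stop("no zero-concentration trace to anchor pH0/V0; supply 'cal'")
    }
    cal <- sensor_calibration(pH0 = chemistry$buffer$pH_B, V0 = Vx[i0],
                              S_pH = S_pH)
  }
  calibration_dataset(s_b, voltage_to_pH(Vx, cal), chemistry,
                      medium = medium)
}

#' Read / write voltage traces (CSV files plus JSON manifest)
#'
#' Each trace is a CSV with columns `time_s`, `voltage_V`; the manifest
#' (`manifest.json`) maps file names to bulk concentrations in mM and records
#' the sensor id and medium.
#'
#' @param dir Directory holding the trace CSVs and `manifest.json`.
#' @return A list of [voltage_trace()] objects.
#' @export
read_traces <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(seq_along(man$files$file), function(i) {
    d <- utils::read.csv(file.path(dir, man$files$file[i]))
    voltage_trace(d$time_s, d$voltage_V,
                  s_b = man$files$s_b_mM[i] * 1e-3,
                  sensor_id = man$sensor_id %||% "sensor-1",
                  medium = man$medium %||% "")
  })
}

#' @rdname read_traces
#' @param traces List of [voltage_trace()] objects to write.
#' @export
write_traces <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(seq_along(traces), function(i) {
    f <- sprintf("trace_%02d.csv", i)
    utils::write.csv(data.frame(time_s = traces[[i]]$time,
                                voltage_V = traces[[i]]$voltage),
                     file.path(dir, f), row.names = FALSE)
    f
  }, character(1))
  jsonlite::write_json(
    list(sensor_id = traces[[1]]$sensor_id, medium = traces[[1]]$medium,
         files = data.frame(
           file = files,
           s_b_mM = vapply(traces, `[[`, numeric(1), "s_b") * 1e3)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
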