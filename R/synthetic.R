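#' Synthetic-data generator specification
#'
#' Bundles everything needed to emulate a calibration experiment: the
#' chemistry, the true kinetic parameters, the concentration series, the pH
#' noise level, a seed, and (for raw-trace synthesis) CONCAP trace options.
#' The defaults mirror the study design this package targets: urea
#' concentrations spanning 0.1-50 mM plus a zero point, additive Gaussian pH
#' noise, and an exponential settling transient on the voltage traces.
#'
#' @param chemistry A [biosensor_chemistry()].
#' @param truth A [kinetic_parameters()] - the generating values, recorded in
#'   the output for recovery scoring.
#' @param s_b_grid Bulk concentrations, mol/L. Default
#'   {0, 0.1, 0.3, 1, 3, 10, 30, 50} mM.
#' @param noise_sd_pH Gaussian pH noise standard deviation (>= 0).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param trace_options List for [generate_voltage_traces()]:
#'   `sampling_rate` (Hz), `duration` (s), `settling_tau` (s),
#'   `voltage_noise_sd` (V), `cal` (a [sensor_calibration()]). Defaults:
#'   5 Hz, 300 s, tau = 20 s (duration > 10 tau), 0.5 mV noise, and a
#'   calibration anchored at the chemistry's bulk pH with V0 = 0.5 V and
#'   33 mV/pH sensitivity (mid-range for pH-sensitive Ta2O5 gates).
#'
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(chemistry, truth,
                           s_b_grid = c(0, 0.1, 0.3, 1, 3, 10, 30, 50) * 1e-3,
                           noise_sd_pH = 0.02, seed = 1L,
                           trace_options = list()) {
  stopifnot(inherits(chemistry, "biosensor_chemistry"),
            inherits(truth, "kinetic_parameters"),
            is.numeric(s_b_grid), all(is.finite(s_b_grid)),
            all(s_b_grid >= 0),
            is.numeric(noise_sd_pH), noise_sd_pH >= 0)
  defaults <- list(
    sampling_rate = 5, duration = 300, settling_tau = 20,
    voltage_noise_sd = 5e-4,
    cal = sensor_calibration(pH0 = chemistry$buffer$pH_B, V0 = 0.5,
                             S_pH = 0.033))
  trace_options <- utils::modifyList(defaults, trace_options)
  structure(list(chemistry = chemistry, truth = truth, s_b_grid = s_b_grid,
                 noise_sd_pH = noise_sd_pH, seed = as.integer(seed),
                 trace_options = trace_options),
            class = "generator_spec")
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic calibration dataset
#'
#' Solves the surface balance at the true parameters over the concentration
#' grid and adds seeded Gaussian pH noise:
#' `pH_i = pH_model(S_B_i; truth) + eps_i`, `eps_i ~ N(0, noise_sd_pH)`.
#' The generating truth is attached as attribute `truth`.
#'
#' @param spec A [generator_spec()].
#' @return A [calibration_dataset()] with attribute `truth`.
#' @export
#' @examples
#' spec <- generator_spec(chem_preset("pbs_urea"),
#'                        kinetic_parameters(10.88e-3, 2.2e-4),
#'                        noise_sd_pH = 0)
#' generate_dataset(spec)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  curve <- response_curve(spec$s_b_grid, spec$chemistry, spec$truth)
  eps <- .with_seed(spec$seed,
                    stats::rnorm(length(spec$s_b_grid), 0, spec$noise_sd_pH))
  d <- calibration_dataset(spec$s_b_grid, curve$pH_surface + eps,
                           spec$chemistry, medium = "synthetic")
  attr(d, "truth") <- spec$truth
  d
}

#' Generate synthetic CONCAP voltage traces
#'
#' For each grid concentration the target plateau voltage encodes the model
#' surface pH through the inverse linear calibration; the trace starts at the
#' zero-substrate voltage `V0` and settles exponentially,
#' `V(t) = V_target + (V0 - V_target) exp(-t / tau) + eta(t)`, with seeded
#' Gaussian voltage noise `eta`. The default duration exceeds 10 tau, so the
#' trailing 100-sample mean is within `|V0 - V_target| exp(-10)` of the
#' plateau.
#'
#' @param spec A [generator_spec()].
#' @return List of [voltage_trace()] objects (one per grid concentration),
#'   with the generating truth attached as attribute `truth`.
#' @export
generate_voltage_traces <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  to <- spec$trace_options
  n_samp <- floor(to$duration * to$sampling_rate) + 1L
  if (n_samp < 100L) {
    stop(sprintf(
      "trace would have %d samples, fewer than the 100-sample averaging window",
      n_samp))
  }
  curve <- response_curve(spec$s_b_grid, spec$chemistry, spec$truth)
  tgrid <- seq(0, to$duration, by = 1 / to$sampling_rate)
  traces <- .with_seed(spec$seed, {
    lapply(seq_along(spec$s_b_grid), function(i) {
      V_target <- pH_to_voltage(curve$pH_surface[i], to$cal)
      V <- V_target + (to$cal$V0 - V_target) * exp(-tgrid / to$settling_tau) +
        stats::rnorm(length(tgrid), 0, to$voltage_noise_sd)
      voltage_trace(tgrid, V, s_b = spec$s_b_grid[i],
                    sensor_id = "synthetic-1", medium = "synthetic")
    })
  })
  attr(traces, "truth") <- spec$truth
  traces
}
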