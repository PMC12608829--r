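#' Run the full calibration-analysis pipeline
#'
#' Ties the stages together: optional preprocessing of raw voltage traces into
#' a calibration dataset, parameter fitting, conversion of the normalized rate
#' to an absolute V_max, and a linearization cross-check. Every number in the
#' report is produced by the corresponding exported operation; nothing is
#' computed in reporting code. Given the same inputs and seed the report is
#' byte-identical across invocations.
#'
#' @param data A [calibration_dataset()], or a path to a calibration CSV
#'   (columns `s_b_mM`, `pH`). Ignored when `traces` is given.
#' @param chemistry A [biosensor_chemistry()], a preset name, or a path to a
#'   chemistry YAML file.
#' @param traces Optional list of [voltage_trace()] objects or a directory
#'   containing trace CSVs plus `manifest.json`; when given, preprocessing
#'   builds the dataset.
#' @param cal Optional [sensor_calibration()] for preprocessing.
#' @param method Optimizer, `"NM"` or `"DE"`.
#' @param seed Integer seed, recorded in the report.
#' @param out_path Optional path; when given the report is written there as
#'   JSON.
#'
#' @return A list of class `pipeline_report`: fitted `K_M_mM`, `kbar_V_M`,
#'   `V_max_M_per_s` (when the transport model carries `k_S`), `phi`, `chi2`,
#'   `p_value`, `method`, `seed`, a `model_vs_data` table and the
#'   `linearizations` cross-check.
#' @export
#' @examples
#' \donttest{
#' spec <- generator_spec(chem_preset("pbs_urea"),
#'                        kinetic_parameters(10.88e-3, 2.2e-4),
#'                        noise_sd_pH = 0)
#' run_pipeline(generate_dataset(spec), chem_preset("pbs_urea"))
#' }
run_pipeline <- function(data = NULL, chemistry, traces = NULL, cal = NULL,
                         method = c("NM", "DE"), seed = 1L,
                         out_path = NULL) {
  method <- match.arg(method)
  if (is.character(chemistry)) {
    chemistry <- if (file.exists(chemistry)) read_chemistry(chemistry)
                 else chem_preset(chemistry)
  }
  stopifnot(inherits(chemistry, "biosensor_chemistry"))
  if (!is.null(traces)) {
    if (is.character(traces)) traces <- read_traces(traces)
    data <- build_dataset(traces, chemistry, cal = cal)
  } else if (is.character(data)) {
    data <- read_calibration_csv(data, chemistry)
  }
  if (!inherits(data, "calibration_dataset")) {
    stop("no calibration dataset: supply 'data' or 'traces'")
  }

  fit <- fit_parameters(data, method = method, seed = seed)
  pH_model <- .model_pH(fit$params, data)

  V_max <- if (!is.null(chemistry$transport$k_S)) {
    vmax_from_normalized(fit$params$kbar_V, chemistry$transport)
  } else NA_real_
  lin <- if (!is.na(V_max)) {
    rates <- rates_from_fit(fit$params, chemistry$transport,
                            data$s_b[data$s_b > 0])
    lapply(list(lineweaver_burk, eadie_hofstee, hanes_woolf),
           function(f) f(rates$S, rates$v))
  } else NULL

  report <- structure(list(
    K_M_mM = fit$params$K_M * 1e3,
    kbar_V_M = fit$params$kbar_V,
    V_max_M_per_s = V_max,
    phi = fit$phi, chi2 = fit$chi2, p_value = fit$p_value,
    method = fit$method, seed = seed,
    model_vs_data = data.frame(s_b_mM = data$s_b * 1e3,
                               pH_obs = data$pH, pH_model = pH_model),
    linearizations = lin
  ), class = "pipeline_report")
  if (!is.null(out_path)) write_report(report, out_path)
  report
}

#' Serialize a pipeline report as JSON
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- unclass(report)
  out$schema <- "ureakin-report-1"
  if (!is.null(out$linearizations)) {
    out$linearizations <- lapply(out$linearizations, function(l) {
      list(method = l$method, V_max_M_per_s = l$V_max, K_M_mM = l$K_M * 1e3)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  K_M    = %.4g mM\n", x$K_M_mM))
  cat(sprintf("  kbar_V = %.4g M\n", x$kbar_V_M))
  if (!is.na(x$V_max_M_per_s)) {
    cat(sprintf("  V_max  = %.4g M/(L s)\n", x$V_max_M_per_s))
  }
  cat(sprintf("  phi = %.4g, chi2 = %.4g, p = %.4g (%s, seed %d)\n",
              x$phi, x$chi2, x$p_value, x$method, x$seed))
  cat(sprintf("  %d calibration points\n", nrow(x$model_vs_data)))
  invisible(x)
}
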