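#' Configuration, serialization and preset patients
#'
#' Run configurations are JSON (or YAML) files validated against a small
#' versioned schema; simulation results are written as a breath-indexed
#' CSV plus a companion JSON carrying maneuver-level metrics and full
#' provenance (config hash, seeds, package version). The five calibrated
#' reference patients are shipped as a plain-text fixture of fitted
#' parameters (produced once by the calibration pipeline; regeneration
#' script in `scripts/`), so simulations and tests do not re-run the
#' optimizer.
#'
#' @name io-config
NULL

.schema_version <- "1.0"
.config_keys <- c("schema_version", "patient", "protocol", "peep_end",
                  "peep_max", "seed", "out_csv", "out_json", "hpv")

# order-dependent 31-bit rolling checksum of a string
tiny_checksum <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  h
}

param_checksum <- function(params) {
  tiny_checksum(paste(names(params), sprintf("%.10g", unlist(params)),
                      collapse = "|"))
}

#' Load and validate a run configuration
#'
#' @param path Path to a JSON (`.json`) or YAML (`.yml`/`.yaml`) file
#'   with keys: `patient` (preset label "A".."E" or path to a fitted
#'   parameter file), `protocol` (one of "baseline", "MRS", "SI", "PRM"),
#'   optional `peep_end` (default 10), `peep_max` (default 45), `seed`
#'   (default 1), `hpv` (default TRUE), `out_csv`, `out_json`.
#' @return A validated `run_config` list with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$schema_version) && cfg$schema_version != .schema_version)
    stop("unsupported schema version: ", cfg$schema_version)
  defaults <- list(schema_version = .schema_version, peep_end = 10,
                   peep_max = 45, seed = 1L, hpv = TRUE,
                   out_csv = NULL, out_json = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$patient)) stop("config must name a patient")
  if (is.null(cfg$protocol)) stop("config must name a protocol")
  if (!cfg$protocol %in% c("baseline", "MRS", "SI", "PRM"))
    stop("unknown protocol: ", cfg$protocol)
  if (cfg$peep_end < 0) stop("peep_end must be non-negative")
  if (cfg$peep_max %% 5 != 0 || cfg$peep_max < 10 || cfg$peep_max > 45)
    stop("peep_max must be a multiple of 5 in [10, 45]")
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg A `run_config` (or plain list with valid keys).
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a simulation result to CSV + JSON
#'
#' The CSV holds the breath-indexed series with unit-bearing headers; the
#' JSON holds maneuver-level metrics (baseline and maximum PaO2/FiO2,
#' delta PO2, P_peak, final recruitment) and provenance (labels, seeds,
#' package version, checksum of the series).
#'
#' @param sim An `ards_sim` from [run_protocol()].
#' @param csv_path Destination CSV path.
#' @param json_path Optional destination JSON path (default: CSV path
#'   with extension swapped).
#' @param seed Seed to record in provenance.
#' @return Invisibly, the metric list written to JSON.
#' @export
write_result <- function(sim, csv_path, json_path = NULL, seed = NA) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  series <- sim$series
  names(series) <- sub("^time_s$", "time_s", names(series))
  utils::write.csv(series, csv_path, row.names = FALSE)
  metrics <- list(
    patient = sim$patient, protocol = sim$protocol,
    baseline_pf_mmHg = sim$baseline_pf,
    max_pf_mmHg = max(series$pf_ratio),
    delta_po2_mmHg = sim$delta_po2,
    p_peak_cmH2O = sim$p_peak,
    final_pct_open = sim$final_pct_open,
    provenance = list(
      package = "ardsim",
      version = as.character(utils::packageVersion("ardsim")),
      seed = seed,
      series_checksum = param_checksum(
        list(n = nrow(series), pf = round(sum(series$pf_ratio), 6)))
    ))
  jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(metrics)
}

#' Load the calibrated preset patients
#'
#' Builds the five reference virtual patients from the committed fitted
#' parameter fixture. Each fixture record carries a checksum of its
#' parameters, verified at load.
#'
#' @param label Optional subset of labels "A".."E".
#' @param path Fixture path; defaults to the fixture shipped with the
#'   package.
#' @return Named list of `ards_patient` objects.
#' @export
preset_patients <- function(label = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fitted_patients.json", package = "ardsim")
  if (!nzchar(path) || !file.exists(path))
    stop("fitted patient fixture not found")
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- if (is.null(label)) names(fx$patients) else label
  out <- lapply(labels, function(lb) {
    entry <- fx$patients[[lb]]
    if (is.null(entry)) stop("no preset patient with label ", lb)
    params <- unlist(entry$params)
    if (param_checksum(as.list(params)) != entry$checksum)
      stop("fixture checksum mismatch for patient ", lb,
           " (fixture corrupted or tampered)")
    rec <- load_patient_records(lb)
    params_to_patient(params, rec, seed = entry$seed, n = entry$n)
  })
  names(out) <- labels
  out
}

#' Save fitted patients as the preset fixture
#'
#' Serialises a list of fits (from [fit_static()]/[fit_dynamic()]) into
#' the plain-text fixture format consumed by [preset_patients()].
#'
#' @param fits Named list of `ards_fit` objects (labels "A".."E").
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
save_preset_fixture <- function(fits, path) {
  patients <- lapply(fits, function(f) {
    params <- as.list(f$params)
    list(params = params, seed = f$seed, n = f$n,
         stage = f$stage, budget = f$budget,
         checksum = param_checksum(params))
  })
  jsonlite::write_json(
    list(schema_version = .schema_version, patients = patients),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
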