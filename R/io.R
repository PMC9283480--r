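# Delimited-text readers/writers, YAML presets, and the simulate/fit/report
# entry points that bind the modules into reproducible runs. Data files are
# CSV with metadata in '#key=value' comment lines; results are JSON records
# embedding package version, seed and an input digest.

.meta_lines <- function(meta) {
  vapply(names(meta), function(k) sprintf("#%s=%s", k, format(meta[[k]])),
         character(1))
}

.read_meta <- function(path) {
  lines <- readLines(path)
  mlines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in mlines) {
    kv <- sub("^#", "", m)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  meta
}

# Polynomial rolling hash (mod 2^31 - 1) of a character vector, as a hex
# string; a lightweight content digest for provenance records.
.digest32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a dose-response series as delimited text
#'
#' CSV with columns `dose_Gy, irradiated, control, time_h`; the readout type
#' and the `a0`/`a_inf` calibration travel in `#key=value` header lines.
#'
#' @param series A [dose_response_series()].
#' @param path File path.
#' @return `write_dose_response` returns `path` invisibly;
#'   `read_dose_response` returns the reconstructed series.
#' @export
write_dose_response <- function(series, path) {
  stopifnot(inherits(series, "dose_response_series"))
  meta <- list(schema = "dose_response", readout = attr(series, "readout"),
               a0 = attr(series, "a0"), a_inf = attr(series, "a_inf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_lines(meta), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("dose_Gy", "irradiated", "control", "time_h")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dose_response_series(df$dose_Gy, df$irradiated,
                       if (all(is.na(df$control))) NULL else df$control,
                       df$time_h,
                       readout = meta$readout %||% "trans_fraction",
                       a0 = as.numeric(meta$a0),
                       a_inf = as.numeric(meta$a_inf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a relaxation time course
#'
#' CSV with columns `time_h, trans_fraction`.
#'
#' @param timecourse Data.frame with those columns.
#' @param path File path.
#' @export
write_timecourse <- function(timecourse, path) {
  utils::write.csv(timecourse[c("time_h", "trans_fraction")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_h", "trans_fraction") %in% names(df))) {
    stop(sprintf("missing column(s) in %s: need time_h, trans_fraction", path),
         call. = FALSE)
  }
  df
}

#' Write / read a coumarin assay
#'
#' CSV with columns `dose_Gy, fluorescence_au`; standard curve, conversion
#' yield and Gd concentration travel as header metadata.
#'
#' @param assay A [coumarin_assay()].
#' @param path File path.
#' @export
write_coumarin_assay <- function(assay, path) {
  stopifnot(inherits(assay, "coumarin_assay"))
  meta <- list(schema = "coumarin_assay",
               std_slope = assay$standard_curve[["slope"]],
               std_intercept = assay$standard_curve[["intercept"]],
               conversion_yield = assay$conversion_yield,
               gd_concentration_uM = assay$gd_concentration_uM)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_lines(meta), con)
  utils::write.csv(data.frame(dose_Gy = assay$doses_Gy,
                              fluorescence_au = assay$fluorescence_au),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coumarin_assay
#' @export
read_coumarin_assay <- function(path) {
  meta <- .read_meta(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("dose_Gy", "fluorescence_au") %in% names(df))) {
    stop(sprintf("missing column(s) in %s: need dose_Gy, fluorescence_au",
                 path), call. = FALSE)
  }
  coumarin_assay(df$dose_Gy, df$fluorescence_au,
                 c(slope = as.numeric(meta$std_slope),
                   intercept = as.numeric(meta$std_intercept %||% 0)),
                 as.numeric(meta$conversion_yield %||% 0.031),
                 as.numeric(meta$gd_concentration_uM %||% 0))
}

#' Built-in presets as a list (and the YAML they ship as)
#'
#' Sources, scavenger panel and Gd anchor curves are also shipped as a
#' human-editable YAML file under `inst/extdata/presets.yaml`; this loader
#' reads that file (or any file with the same schema).
#'
#' @param path YAML file; defaults to the shipped presets.
#' @return Nested list of presets.
#' @export
load_presets <- function(path = system.file("extdata", "presets.yaml",
                                            package = "radioswitch")) {
  yaml::read_yaml(path)
}

#' Default run configuration
#'
#' All tunables of a simulate-then-fit run in one serialisable list: seed,
#' source preset, solution conditions, switch parameters, assay schedules
#' and noise magnitudes. A run re-executed from its emitted configuration
#' reproduces its outputs exactly.
#'
#' @param seed Integer root seed.
#' @param source Source preset name.
#' @param gas,gd_concentration_uM Solution conditions.
#' @param doses_Gy Dose schedule for the dose-response assay.
#' @param lag_h,replicates Plate design of the dose-response assay.
#' @param relax_duration_h,relax_points Relaxation course schedule.
#' @param coumarin_doses_Gy Dosimetry dose schedule.
#' @param fraction_sigma,absorbance_sigma,fluorescence_sigma_rel Noise.
#' @param params A [switch_parameters()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, source = "GR", gas = "none",
                       gd_concentration_uM = 0,
                       doses_Gy = c(0, 2, 3, 5, 10),
                       lag_h = 0, replicates = 3,
                       relax_duration_h = 8, relax_points = 8,
                       coumarin_doses_Gy = c(0, 2, 5, 10, 15, 20, 25, 30, 40),
                       fraction_sigma = 0.01, absorbance_sigma = 0.005,
                       fluorescence_sigma_rel = 0.03,
                       params = switch_parameters()) {
  structure(
    list(seed = as.integer(seed), source = source, gas = gas,
         gd_concentration_uM = gd_concentration_uM, doses_Gy = doses_Gy,
         lag_h = lag_h, replicates = replicates,
         relax_duration_h = relax_duration_h, relax_points = relax_points,
         coumarin_doses_Gy = coumarin_doses_Gy,
         fraction_sigma = fraction_sigma,
         absorbance_sigma = absorbance_sigma,
         fluorescence_sigma_rel = fluorescence_sigma_rel,
         params = unclass(params)),
    class = "run_config"
  )
}

.provenance <- function(config, extra = list()) {
  cfg_yaml <- yaml::as.yaml(unclass(config))
  c(list(package = "radioswitch",
         version = as.character(utils::packageVersion("radioswitch")),
         seed = config$seed,
         config_digest = .digest32(cfg_yaml)),
    extra)
}

#' Simulate the full assay corpus from a configuration
#'
#' Materialises one dose-response series, one relaxation course, one
#' coumarin dosimetry assay and one Gd enhancement table under `out_dir`,
#' plus a `provenance.json` recording the package version, seed, and config
#' digest. Child seeds for the four assays derive deterministically from the
#' root seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(switch_parameters, config$params)
  source <- ir_source(config$source)
  conditions <- solution_conditions(config$gas, config$gd_concentration_uM)
  seeds <- child_seeds(config$seed, 4)
  mk_noise <- function(s) assay_noise(config$absorbance_sigma,
                                      config$fraction_sigma,
                                      config$fluorescence_sigma_rel, s)

  files <- c(dose_response = file.path(out_dir, "dose_response.csv"),
             relaxation = file.path(out_dir, "relaxation.csv"),
             coumarin = file.path(out_dir, "coumarin.csv"),
             gd_table = file.path(out_dir, "gd_table.csv"),
             provenance = file.path(out_dir, "provenance.json"))

  write_dose_response(
    gen_dose_response(params, source, conditions, config$doses_Gy,
                      noise = mk_noise(seeds[1]), lag_h = config$lag_h,
                      replicates = config$replicates),
    files["dose_response"])
  write_timecourse(
    gen_relaxation_course(params, config$relax_duration_h,
                          config$relax_points, mk_noise(seeds[2])),
    files["relaxation"])
  write_coumarin_assay(
    gen_coumarin_assay(source, conditions, config$coumarin_doses_Gy,
                       noise = mk_noise(seeds[3])),
    files["coumarin"])
  utils::write.csv(
    gen_gd_enhancement_table(source, noise = mk_noise(seeds[4])),
    files["gd_table"], row.names = FALSE)

  jsonlite::write_json(
    .provenance(config, list(files = as.list(basename(files)))),
    files["provenance"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}

#' Fit an estimator to an assay file
#'
#' Dispatches on estimator name, reads the matching file schema, runs the
#' estimator, and returns (optionally writes) a JSON-ready result record
#' with provenance.
#'
#' @param path Input data file.
#' @param estimator One of `"activation"`, `"g_value"`, `"g_ho"`,
#'   `"half_life"`, `"efficiency"`, `"enhancement"`.
#' @param out Optional JSON output path.
#' @param ... Extra arguments passed to the underlying estimator (e.g.
#'   `initial_cis_uM` and `dose_Gy` for `"g_value"`).
#' @return The result record, invisibly if `out` is given.
#' @export
run_fit <- function(path, estimator = c("activation", "g_value", "g_ho",
                                        "half_life", "efficiency",
                                        "enhancement"),
                    out = NULL, ...) {
  estimator <- match.arg(estimator)
  est <- switch(estimator,
    activation = {
      f <- fit_activation_constant(read_dose_response(path), ...)
      list(k_per_Gy = f$k_per_Gy, k_stderr = f$k_stderr,
           r_squared = f$r_squared, n_points = f$n_points)
    },
    g_value = {
      f <- fit_g_value(read_dose_response(path), ...)
      list(g_per_100ev = f$g$value_per_100ev,
           g_umol_per_J = f$g$value_umol_per_J,
           corrected_for_thermal = f$corrected_for_thermal,
           dose_Gy = f$dose_Gy)
    },
    g_ho = {
      g <- fit_g_ho(read_coumarin_assay(path), ...)
      list(g_ho_umol_per_J = g$value_umol_per_J,
           g_ho_per_100ev = g$value_per_100ev,
           r_squared = attr(g, "r_squared"))
    },
    half_life = {
      f <- fit_thermal_half_life(read_timecourse(path), ...)
      list(half_life_h = f$half_life_h, stderr_h = f$stderr_h,
           r_squared = f$r_squared)
    },
    efficiency = {
      df <- utils::read.csv(path, comment.char = "#")
      f <- fit_efficiency_model(df, ...)
      list(a = f$a, b = f$b, r_squared = f$r_squared)
    },
    enhancement = {
      df <- utils::read.csv(path, comment.char = "#")
      p <- enhancement_profile(df, ...)
      list(max_enhancement = p$max_enhancement,
           argmax_concentration_uM = p$argmax_concentration_uM)
    }
  )
  record <- list(estimator = estimator, input = basename(path),
                 input_digest = .digest32(readLines(path)),
                 package = "radioswitch",
                 version = as.character(utils::packageVersion("radioswitch")),
                 estimates = est)
  if (!is.null(out)) {
    jsonlite::write_json(record, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(record))
  }
  record
}

#' Summarise fit records as a table
#'
#' Flattens a list of [run_fit()] records (or JSON paths to them) into one
#' human-readable data.frame, one row per estimate.
#'
#' @param results List of result records and/or JSON file paths.
#' @return Data.frame with columns `estimator`, `quantity`, `value`.
#' @export
run_report <- function(results) {
  if (!length(results)) {
    return(data.frame(estimator = character(), quantity = character(),
                      value = numeric()))
  }
  rows <- lapply(results, function(r) {
    if (is.character(r)) r <- jsonlite::read_json(r, simplifyVector = TRUE)
    est <- r$estimates
    num <- vapply(est, function(v) is.numeric(v) || is.logical(v), TRUE)
    data.frame(estimator = r$estimator, quantity = names(est)[num],
               value = as.numeric(unlist(est[num])), row.names = NULL)
  })
  do.call(rbind, rows)
}
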