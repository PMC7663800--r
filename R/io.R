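#' Read tensile curves from a delimited text file
#'
#' Expects a header naming at least `strain` and `stress_MPa` columns, with
#' an optional `specimen_id` column grouping replicates within one file.
#' The delimiter is auto-detected between comma and tab (overridable). Rows
#' with non-finite values are dropped with a message. Strain may be recorded
#' as a fraction (default) or in percent.
#'
#' @param path file path.
#' @param strain_unit `"fraction"` (default) or `"percent"`.
#' @param delimiter `NULL` for auto-detection, or an explicit `","`/`"\t"`.
#' @param composition_label,hydration_state metadata attached to the curves.
#' @return A named list of [uniaxial_curve()] objects, one per specimen, in
#'   file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("strain,stress_MPa", "0,0", "0.5,0.8", "1.0,1.6"), f)
#' read_curve_file(f)[[1]]$stretch
#' @export
read_curve_file <- function(path, strain_unit = c("fraction", "percent"),
                            delimiter = NULL, composition_label = "",
                            hydration_state = "non_hydrated") {
  strain_unit <- match.arg(strain_unit)
  if (!file.exists(path)) {
    stop_pugraft(sprintf("file not found: %s", path), "pugraft_io_error")
  }
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = delimiter,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("strain", "stress_MPa") %in% names(df))) {
    stop_pugraft(
      sprintf("missing required column(s): %s",
              paste(setdiff(c("strain", "stress_MPa"), names(df)),
                    collapse = ", ")),
      "pugraft_format_error"
    )
  }
  ids <- if ("specimen_id" %in% names(df)) {
    as.character(df$specimen_id)
  } else {
    rep(sub("\\.[^.]*$", "", basename(path)), nrow(df))
  }
  file_row <- seq_len(nrow(df)) + 1L  # +1 for the header line
  ok <- is.finite(df$strain) & is.finite(df$stress_MPa)
  if (any(!ok)) {
    message(sprintf("read_curve_file: dropped %d row(s) with non-finite values",
                    sum(!ok)))
    df <- df[ok, , drop = FALSE]
    ids <- ids[ok]
    file_row <- file_row[ok]
  }
  scale <- if (strain_unit == "percent") 1 / 100 else 1

  out <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    if (sum(sel) < 3L) {
      stop_pugraft(
        sprintf("specimen '%s' has fewer than 3 valid rows", id),
        "pugraft_data_error"
      )
    }
    bad <- which(diff(df$strain[sel]) <= 0)
    if (length(bad)) {
      stop_pugraft(
        sprintf("specimen '%s': strain not strictly increasing at file row %d",
                id, file_row[sel][bad[1L] + 1L]),
        "pugraft_data_error"
      )
    }
    out[[id]] <- uniaxial_curve(
      strain_eng = df$strain[sel] * scale,
      stress_eng = df$stress_MPa[sel],
      specimen_id = id,
      composition_label = composition_label,
      hydration_state = hydration_state
    )
  }
  out
}

#' Write a curve to delimited text
#'
#' Inverse of [read_curve_file()]: writes `strain`, `stress_MPa` and
#' `specimen_id` columns as CSV.
#'
#' @param curve a [uniaxial_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve_file <- function(curve, path) {
  if (!inherits(curve, "uniaxial_curve")) {
    stop_pugraft("`curve` must be a uniaxial_curve", "pugraft_value_error")
  }
  df <- data.frame(strain = curve$strain_eng, stress_MPa = curve$stress_eng,
                   specimen_id = curve$specimen_id)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_results_table <- function(fits) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      label = if (nzchar(f$label)) f$label else "material",
      C10 = f$params$c10, C01 = f$params$c01, C11 = f$params$c11,
      v = f$crosslink_density, RMSE = f$rmse, CCC = f$ccc,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write and read fitted-coefficient tables
#'
#' The fit table has one row per material with columns
#' `label, C10, C01, C11, v, RMSE, CCC` (coefficients in MPa, crosslink
#' density v in kmol/m^3). Values round-trip through CSV at full double
#' precision (15 significant digits).
#'
#' @param fits an `mr_fit` or list of them.
#' @param path output CSV path.
#' @return `write_fit_results()` returns `path` invisibly;
#'   `read_fit_results()` returns the table as a data.frame.
#' @export
write_fit_results <- function(fits, path) {
  tab <- fit_results_table(fits)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_results
#' @export
read_fit_results <- function(path) {
  if (!file.exists(path)) {
    stop_pugraft(sprintf("file not found: %s", path), "pugraft_io_error")
  }
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write compliance series in long format
#'
#' One row per time sample per sweep cell with columns
#' `material, r0, h, omega, time, pressure, radius, compliance` (compliance
#' `NA` at gap samples and at the final sample of each series). An empty
#' input writes the header only.
#'
#' @param sweeps a `sweep_result`, a list of them, or a single
#'   `compliance_series`.
#' @param path output CSV path.
#' @param material label used when the input carries none.
#' @return `path`, invisibly.
#' @export
write_compliance <- function(sweeps, path, material = "material") {
  rows <- compliance_long(sweeps, material)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(rows) == 0L) {
    writeLines("material,r0,h,omega,time,pressure,radius,compliance", con)
  } else {
    write.csv(rows, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

compliance_long <- function(x, material = "material") {
  empty <- data.frame(
    material = character(0), r0 = numeric(0), h = numeric(0),
    omega = numeric(0), time = numeric(0), pressure = numeric(0),
    radius = numeric(0), compliance = numeric(0)
  )
  series_rows <- function(cs, label) {
    data.frame(
      material = label, r0 = cs$geometry$r0, h = cs$geometry$h,
      omega = cs$waveform$freq, time = cs$time, pressure = cs$pressure,
      radius = cs$radius, compliance = c(cs$compliance, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  if (inherits(x, "compliance_series")) {
    return(series_rows(x, material))
  }
  if (inherits(x, "sweep_result")) x <- list(x)
  if (!is.list(x)) {
    stop_pugraft("unsupported input to write_compliance", "pugraft_value_error")
  }
  parts <- list()
  for (sw in x) {
    if (inherits(sw, "compliance_series")) {
      parts[[length(parts) + 1L]] <- series_rows(sw, material)
    } else if (inherits(sw, "sweep_result")) {
      lab <- if (nzchar(sw$label)) sw$label else material
      for (cs in sw$series) {
        if (!is.null(cs)) parts[[length(parts) + 1L]] <- series_rows(cs, lab)
      }
    } else if (!is.null(sw)) {
      stop_pugraft("unsupported input to write_compliance", "pugraft_value_error")
    }
  }
  if (length(parts) == 0L) empty else do.call(rbind, parts)
}

#' Load and validate a run configuration
#'
#' The configuration is a single YAML (or JSON) document describing a full
#' pipeline run: the materials (each either a list of curve files or a
#' synthetic specification), temperature, pressure waveform, sweep grids,
#' sampling and seed. Missing fields take the documented defaults.
#'
#' Defaults: `temperature_K` 310.15; waveform `p_max` 180, `p_min` 40, `ps`
#' 10 mmHg; `omega_grid` 1, 1.5, 2 Hz; `r0_grid` 1.5, 2, 3 mm; `h_grid`
#' 0.3, 0.4, 0.5 mm; `samples_per_cycle` 256; `n_cycles` 3; `n_grid` 200;
#' `strain_unit` `"fraction"`; `seed` 1.
#'
#' @param path path to a YAML or JSON config file.
#' @return Object of class `run_config` (a validated list).
#' @examples
#' cfg <- load_run_config(system.file("extdata", "example_config.yaml",
#'                                    package = "pugraft"))
#' cfg$samples_per_cycle
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_pugraft(sprintf("config file not found: %s", path), "pugraft_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(
    temperature_K = 310.15,
    waveform = list(p_max = 180, p_min = 40, ps = 10),
    omega_grid = c(1, 1.5, 2),
    r0_grid = c(1.5, 2, 3),
    h_grid = c(0.3, 0.4, 0.5),
    samples_per_cycle = 256L,
    n_cycles = 3L,
    n_grid = 200L,
    strain_unit = "fraction",
    seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$waveform)) {
    if (is.null(cfg$waveform[[nm]])) cfg$waveform[[nm]] <- defaults$waveform[[nm]]
  }
  if (is.null(cfg$materials) || length(cfg$materials) == 0L) {
    stop_pugraft("config must list at least one material", "pugraft_config_error")
  }
  for (m in cfg$materials) {
    if (is.null(m$label)) {
      stop_pugraft("every material needs a `label`", "pugraft_config_error")
    }
    if (is.null(m$files) && is.null(m$synthetic)) {
      stop_pugraft(
        sprintf("material '%s' needs either `files` or a `synthetic` block",
                m$label),
        "pugraft_config_error"
      )
    }
  }
  if (length(cfg$omega_grid) == 0L || length(cfg$r0_grid) == 0L ||
      length(cfg$h_grid) == 0L) {
    stop_pugraft("sweep grids must be non-empty", "pugraft_config_error")
  }
  if (cfg$samples_per_cycle < 16) {
    stop_pugraft("`samples_per_cycle` must be >= 16", "pugraft_config_error")
  }
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "run_config")
}
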