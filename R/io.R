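# CSV dialect everywhere: comma-separated, header required, UTF-8, "." decimals.
# Mixing times cross the I/O boundary in ms and ppm stays ppm; internally all
# times are seconds and all temperatures Kelvin.

.read_csv_strict <- function(path, required, file_kind) {
  if (!file.exists(path)) stop(file_kind, " file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop(sprintf("%s '%s' lacks column(s): %s", file_kind, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Read / write a decay table (ZZ + T1 intensities vs mixing time)
#'
#' Columns: `residue_id`, `experiment` (ZZ|T1), `channel` (AA|BB|A|B),
#' `mixing_time_ms`, `intensity`, optional `intensity_err`. On read, a
#' `mixing_time` column in seconds is added for the fitting layer.
#'
#' @param path CSV file path.
#' @return Tibble (reader); invisibly `path` (writer).
#' @export
read_decay_table <- function(path) {
  d <- .read_csv_strict(path, c("residue_id", "experiment", "channel",
                                "mixing_time_ms", "intensity"), "decay table")
  bad <- setdiff(unique(d$channel), c("AA", "BB", "A", "B"))
  if (length(bad)) stop("decay table has unknown channel(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  d$mixing_time <- d$mixing_time_ms / 1000
  d
}

#' @rdname read_decay_table
#' @param data Decay tibble (as produced by [gen_exchange_dataset()]).
#' @export
write_decay_table <- function(data, path) {
  cols <- c("residue_id", "experiment", "channel", "mixing_time_ms", "intensity")
  if ("intensity_err" %in% names(data)) cols <- c(cols, "intensity_err")
  readr::write_csv(dplyr::select(data, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Read a quantitative-J coupling table
#'
#' Columns: `residue_id`, `s_cross`, `s_diag`, optional `fold`,
#' `zeta_ms` (default 13.05) and `detected`. A `zeta` column in seconds
#' is added on read.
#'
#' @param path CSV file path.
#' @return Tibble ready for [analyze_coupling()].
#' @export
read_coupling_table <- function(path) {
  d <- .read_csv_strict(path, c("residue_id", "s_cross", "s_diag"), "coupling table")
  if (!"zeta" %in% names(d)) {
    d$zeta <- if ("zeta_ms" %in% names(d)) d$zeta_ms / 1000 else 0.01305
  }
  d
}

#' Read a peak-volume table
#'
#' Columns: `condition`, `probe`, `fold` (1B|2B), `volume`, optional
#' `volume_err`.
#'
#' @param path CSV file path.
#' @return Tibble ready for [estimate_populations()].
#' @export
read_peak_table <- function(path) {
  .read_csv_strict(path, c("condition", "fold", "volume"), "peak table")
}

#' Read 1D trace(s)
#'
#' Columns: `ppm`, `intensity`, optional `condition` for stacked traces.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_trace <- function(path) {
  .read_csv_strict(path, c("ppm", "intensity"), "trace")
}

#' Read a melting table
#'
#' Columns: either `temperature_C` (Celsius, converted to a Kelvin
#' `temperature` column on read) or `temperature` (Kelvin), plus
#' `absorbance`, optional `wavelength_nm`, `cycle_id`, `case`.
#'
#' @param path CSV file path.
#' @return Tibble ready for [association_degree()] / [cycle_average()].
#' @export
read_melt_table <- function(path) {
  d <- .read_csv_strict(path, "absorbance", "melt table")
  if ("temperature_C" %in% names(d)) {
    d$temperature <- d$temperature_C + 273.15
  } else if (!"temperature" %in% names(d)) {
    stop("melt table needs a temperature_C or temperature column", call. = FALSE)
  }
  d
}

#' Run the full analysis pipeline over a scenario directory
#'
#' Drives every stage over the tables of one directory (as written by
#' [generate_scenario()]): exchange fitting per residue, fold populations
#' per condition, sugar-pucker analysis, and melting thermodynamics per
#' case. Each stage runs only when its input file exists; per-stage JSON
#' reports, a combined summary CSV and the echoed configuration are
#' written to `out_dir`. By default a failing stage is isolated (the
#' others still run); with `strict = TRUE` the first failure aborts.
#'
#' @param config List (or path to a JSON file) with elements `input_dir`,
#'   `out_dir`, optional `seed` (default 1), `mc_runs` (default 200;
#'   0 disables Monte-Carlo errors), `zeta_ms`, `j_north`, `j_south`,
#'   `detection_threshold`, `strict`.
#' @return Invisibly, a list with per-stage results and a `summary`
#'   tibble; `errors` holds messages of failed stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("input_dir", "out_dir", "seed", "mc_runs", "zeta_ms", "j_north",
             "j_south", "detection_threshold", "strict", "baseline_windows")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (is.null(config$input_dir) || is.null(config$out_dir)) {
    stop("config must name input_dir and out_dir", call. = FALSE)
  }
  seed <- config$seed %||% 1L
  mc_runs <- config$mc_runs %||% 200L
  strict <- isTRUE(config$strict)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list(config = config)
  errors <- list()
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      if (strict) stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                       call. = FALSE)
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    out
  }
  in_file <- function(nm) file.path(config$input_dir, nm)
  report <- function(obj, nm) {
    jsonlite::write_json(obj, file.path(config$out_dir, nm),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (file.exists(in_file("exchange.csv"))) {
    results$exchange <- run_stage("exchange", {
      d <- read_decay_table(in_file("exchange.csv"))
      fits <- d |>
        dplyr::group_by(.data$residue_id) |>
        dplyr::group_map(function(g, key) {
          f <- fit_exchange(dplyr::mutate(g, residue_id = key$residue_id))
          if (mc_runs >= 2) f <- monte_carlo_errors(f, n_runs = mc_runs, seed = seed)
          cbind(residue_id = key$residue_id, glance(f),
                tibble::tibble(k_f = f$params$k_f, k_b = f$params$k_b,
                               r1_a = f$params$r1_a, r1_b = f$params$r1_b,
                               k_ex_err = if (is.null(f$mc)) NA_real_ else f$mc$errors$k_ex))
        }) |>
        dplyr::bind_rows()
      report(fits, "exchange_report.json")
      fits
    })
  }
  if (file.exists(in_file("peaks.csv"))) {
    results$populations <- run_stage("populations", {
      pops <- estimate_populations(read_peak_table(in_file("peaks.csv")))
      report(pops, "populations_report.json")
      pops
    })
  }
  if (file.exists(in_file("couplings.csv"))) {
    results$pucker <- run_stage("pucker", {
      pk <- analyze_coupling(
        read_coupling_table(in_file("couplings.csv")),
        j_north = config$j_north %||% 1.0,
        j_south = config$j_south %||% 8.8,
        detection_threshold = config$detection_threshold %||% 0.01
      )
      report(pk, "pucker_report.json")
      pk
    })
  }
  if (file.exists(in_file("melt.csv"))) {
    results$melting <- run_stage("melting", {
      m <- read_melt_table(in_file("melt.csv"))
      if (!"case" %in% names(m)) m$case <- "melt"
      out <- m |>
        dplyr::group_by(.data$case) |>
        dplyr::group_map(function(g, key) {
          cyc <- cycle_average(g, seed = seed)
          tibble::tibble(case = key$case, tm_mean = cyc$tm_mean, tm_sd = cyc$tm_sd,
                         dH_mean = mean(cyc$cycles$dH), dS_mean = mean(cyc$cycles$dS),
                         n_cycles = cyc$n_cycles)
        }) |>
        dplyr::bind_rows()
      report(out, "melting_report.json")
      out
    })
  }

  summary_rows <- list()
  if (!is.null(results$exchange)) {
    summary_rows$exchange <- tibble::tibble(
      stage = "exchange", item = results$exchange$residue_id,
      value = results$exchange$k_ex, quantity = "k_ex_s1"
    )
  }
  if (!is.null(results$populations)) {
    summary_rows$populations <- tibble::tibble(
      stage = "populations", item = results$populations$condition,
      value = results$populations$p_1B, quantity = "p_1B"
    )
  }
  if (!is.null(results$pucker)) {
    summary_rows$pucker <- tibble::tibble(
      stage = "pucker", item = results$pucker$residue_id,
      value = results$pucker$south_fraction, quantity = "south_fraction"
    )
  }
  if (!is.null(results$melting)) {
    summary_rows$melting <- tibble::tibble(
      stage = "melting", item = results$melting$case,
      value = results$melting$tm_mean, quantity = "tm_K"
    )
  }
  results$summary <- dplyr::bind_rows(summary_rows)
  readr::write_csv(results$summary, file.path(config$out_dir, "summary.csv"))
  report(list(seed = seed, mc_runs = mc_runs,
              package_version = as.character(utils::packageVersion("rnafoldeq")),
              config = config, failed_stages = names(errors)),
         "run_log.json")
  results$errors <- errors
  invisible(results)
}
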