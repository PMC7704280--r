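#' Load a run configuration from YAML or JSON
#'
#' The configuration document has two blocks:
#'
#' ```yaml
#' variables:
#'   - name: age
#'     role: quasi_identifier
#'     kind: continuous
#'     hierarchy:
#'       - {type: bin, breaks: [0, 10, 20, 30, 40, 50, 60, 70, 80, 125]}
#'       - {type: suppress}
#'   - {name: diagnosis, role: sensitive, kind: nominal}
#' parameters:
#'   threshold: 0.09
#'   L: 5
#'   error_rate: {min: 0, mode: 0.0426, max: 0.0852}
#'   verification_rate: {min: 0, mode: 0.23, max: 0.46}
#'   correlation: 0.3
#'   mad_multiplier: 1.48
#'   seed: 1
#' ```
#'
#' A hierarchy entry `builtin: age` (or `year_month`, `zip`,
#' `suppress`) expands to [default_hierarchy()].
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return list with `meta` (list of [variable_spec()]) and `params`
#'   ([risk_parameters()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$variables)) stop("config has no `variables:` block", call. = FALSE)
  meta <- lapply(cfg$variables, function(v) {
    hier <- NULL
    if (!is.null(v$hierarchy)) {
      hier <- if (is.character(v$hierarchy) ||
                  (is.list(v$hierarchy) && !is.null(v$hierarchy$builtin))) {
        b <- if (is.character(v$hierarchy)) v$hierarchy else v$hierarchy$builtin
        default_hierarchy(b)
      } else if (!is.null(v$hierarchy[[1]]$builtin)) {
        default_hierarchy(v$hierarchy[[1]]$builtin)
      } else {
        lapply(v$hierarchy, function(h) {
          if (!is.null(h$breaks)) h$breaks <- unlist(h$breaks)
          if (!is.null(h$labels)) h$labels <- unlist(h$labels)
          as_hierarchy_level(h)
        })
      }
    }
    variable_spec(v$name, role = v$role %||% "quasi_identifier",
                  kind = v$kind %||% "nominal", hierarchy = hier)
  })
  p <- cfg$parameters %||% list()
  tri <- function(x, default) {
    if (is.null(x)) return(default)
    c(min = x$min %||% x[[1]], mode = x$mode %||% x$mean %||% x[[2]],
      max = x$max %||% x[[3]])
  }
  params <- risk_parameters(
    threshold = p$threshold %||% 0.09,
    L = p$L %||% 5,
    error_rate = tri(p$error_rate, c(min = 0, mode = 0.0426, max = 0.0852)),
    verification_rate = tri(p$verification_rate, c(min = 0, mode = 0.23, max = 0.46)),
    correlation = p$correlation %||% 0.3,
    mad_multiplier = p$mad_multiplier %||% 1.48,
    kmeans_max_k = p$kmeans_max_k %||% 10,
    seed = p$seed)
  list(meta = meta, params = params)
}

#' Assess risk from files (command-line back end)
#'
#' Reads the three datasets and the configuration, runs
#' [assess_risk()] (with or without the attack search), writes the
#' report JSON, and returns the process exit status: 0 when the
#' verdict is acceptable, 2 when the risk is too high. File and
#' configuration errors raise conditions (the CLI maps them to exit
#' status 1).
#'
#' @param real_path,synthetic_path,population_path CSV files.
#' @param config_path YAML/JSON configuration (see
#'   [read_run_config()]).
#' @param out path for the report JSON.
#' @param search run the attack-modality search (default) or evaluate
#'   only the all-quasi-identifiers configuration.
#' @param max_configs enumeration cap for the search.
#' @param audit include the per-record audit columns in the report.
#' @param seed overrides the configured seed when non-`NULL`.
#' @return exit status, invisibly; the `risk_report` as attribute
#'   `"report"`.
#' @export
cmd_assess <- function(real_path, synthetic_path, population_path, config_path,
                       out = "risk_report.json", search = TRUE,
                       max_configs = 10000, audit = FALSE, seed = NULL) {
  for (p in c(real = real_path, synthetic = synthetic_path,
              population = population_path)) {
    if (is.null(p) || !file.exists(p)) {
      stop(sprintf("missing dataset file: %s (check --real/--synthetic/--population)",
                   p %||% "<unset>"), call. = FALSE)
    }
  }
  cfg <- read_run_config(config_path)
  if (!is.null(seed)) cfg$params$seed <- as.integer(seed)
  real <- read_dataset(real_path, cfg$meta, "real_sample")
  synthetic <- read_dataset(synthetic_path, cfg$meta, "synthetic_sample")
  population <- read_dataset(population_path, cfg$meta, "population")
  report <- assess_risk(real, synthetic, population, params = cfg$params,
                        search = search, max_configs = max_configs, audit = audit)
  write_risk_report(report, out)
  status <- if (report$verdict == "acceptable") 0L else 2L
  message(sprintf("overall risk %.6g (A=%.6g, B=%.6g) vs threshold %.4g -> %s",
                  report$overall, report$risk_pop_to_sample,
                  report$risk_sample_to_pop, report$threshold,
                  toupper(report$verdict)))
  invisible(structure(status, report = report))
}

#' Render a one-line human-readable summary of a report
#'
#' @param report_path path to a report JSON written by
#'   [write_risk_report()] (or a `risk_report` object / parsed list).
#' @param baseline_path optional second report (typically the
#'   real-data baseline); when given, the summary adds the risk ratio
#'   between the two.
#' @return the summary string, invisibly (also printed).
#' @export
cmd_report <- function(report_path, baseline_path = NULL) {
  rep <- if (is.character(report_path)) read_risk_report(report_path) else report_path
  if (is.null(rep$overall) || is.null(rep$threshold)) {
    stop("malformed report: missing `overall` or `threshold`", call. = FALSE)
  }
  line <- render_report_summary(rep$overall, rep$threshold)
  if (!is.null(baseline_path)) {
    base <- if (is.character(baseline_path)) read_risk_report(baseline_path) else baseline_path
    if (!is.null(base$overall) && rep$overall > 0) {
      line <- sprintf("%s; %.1fx lower than the real-data baseline (%.4g)",
                      line, base$overall / rep$overall, base$overall)
    }
  }
  cat(line, "\n", sep = "")
  invisible(line)
}

render_report_summary <- function(overall, threshold) {
  if (overall <= threshold) {
    if (overall > 0) {
      sprintf("ACCEPTABLE (%.1fx below threshold)", threshold / overall)
    } else {
      "ACCEPTABLE (zero measured risk)"
    }
  } else {
    sprintf("TOO HIGH (%.4g exceeds threshold %.4g)", overall, threshold)
  }
}

#' Synthesize from files (command-line back end)
#'
#' @param real_path training CSV.
#' @param config_path YAML/JSON configuration.
#' @param n number of synthetic records.
#' @param seed integer seed.
#' @param out output CSV path.
#' @param sequence optional synthesis order (defaults to column
#'   order).
#' @param min_leaf minimum terminal node size.
#' @return the output path, invisibly.
#' @export
cmd_synthesize <- function(real_path, config_path, n, seed = 1,
                           out = "synthetic.csv", sequence = NULL,
                           min_leaf = 5) {
  cfg <- read_run_config(config_path)
  real <- read_dataset(real_path, cfg$meta, "real_sample")
  gen <- synth_fit(real, sequence = sequence, min_leaf = min_leaf)
  syn <- synth_generate(gen, n, seed = seed)
  write_dataset(syn, out)
  invisible(out)
}

#' Emit fixture datasets (command-line back end)
#'
#' With `worked_example = TRUE`, writes the three worked-example CSVs
#' (`population.csv`, `real.csv`, `synthetic.csv`) to `out_dir`;
#' otherwise generates a population from a YAML fixture spec.
#'
#' @param out_dir output directory (created if needed).
#' @param spec_path YAML fixture specification for
#'   [generate_population()].
#' @param worked_example emit the built-in example triple.
#' @return the output directory, invisibly.
#' @export
cmd_fixture <- function(out_dir, spec_path = NULL, worked_example = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(worked_example)) {
    ex <- synthrisk::worked_example()
    write_dataset(ex$population, file.path(out_dir, "population.csv"))
    write_dataset(ex$real, file.path(out_dir, "real.csv"))
    write_dataset(ex$synthetic, file.path(out_dir, "synthetic.csv"))
  } else {
    if (is.null(spec_path)) stop("either `spec_path` or `worked_example` is required",
                                 call. = FALSE)
    spec <- yaml::read_yaml(spec_path)
    pop <- generate_population(spec)
    write_dataset(pop, file.path(out_dir, "population.csv"))
    if (!is.null(spec$sampling_fraction)) {
      real <- sample_real(pop, spec$sampling_fraction, seed = spec$seed)
      write_dataset(real, file.path(out_dir, "real.csv"))
    }
  }
  invisible(out_dir)
}
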