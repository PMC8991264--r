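# CSV I/O with schema validation ------------------------------------------

read_checked_csv <- function(path) {
  ep_assert(is.character(path) && length(path) == 1L && file.exists(path),
            "epferm_usage_error", sprintf("input file not found: %s", path))
  fields <- tryCatch(count.fields(path, sep = ",", quote = "\""),
                     error = function(e) {
                       ep_stop("epferm_data_error",
                               sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e)))
                     })
  bad <- which(fields != fields[1])
  if (length(bad)) {
    ep_stop("epferm_data_error",
            sprintf("malformed CSV %s: line %d has %d fields, expected %d",
                    path, bad[1], fields[bad[1]], fields[1]))
  }
  read.csv(path)
}

#' Read a batch fermentation time series from CSV
#'
#' Schema: `time_h,substrate_g_per_L[,biomass_g_per_L][,product][,volume_L]`
#' — UTF-8, comma separated, `.` decimal, header mandatory.
#'
#' @param path file path.
#' @return data frame with the validated columns.
#' @export
read_batch_csv <- function(path) {
  tab <- read_checked_csv(path)
  need <- c("time_h", "substrate_g_per_L")
  miss <- setdiff(need, names(tab))
  ep_assert(length(miss) == 0L, "epferm_data_error",
            sprintf("batch CSV misses columns: %s (found: %s)",
                    paste(miss, collapse = ", "),
                    paste(names(tab), collapse = ", ")))
  for (cc in intersect(c(need, "biomass_g_per_L", "product", "volume_L"),
                       names(tab))) {
    ep_assert(is.numeric(tab[[cc]]), "epferm_data_error",
              sprintf("column '%s' of %s is not numeric", cc, path))
  }
  tab
}

#' Write a batch trajectory to CSV
#'
#' @param series an `ep_batch` or compatible data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long observation table from CSV
#'
#' Schema:
#' `run,time_h,glycerol,yeast_powder,peptone,znso4,mgso4,kh2po4,ep_ug_per_L`.
#'
#' @param path file path.
#' @return data frame ready for [fit_response_surface()].
#' @export
read_long_table_csv <- function(path) {
  tab <- read_checked_csv(path)
  need <- c("run", "time_h", "glycerol", "yeast_powder", "peptone",
            "znso4", "mgso4", "kh2po4", "ep_ug_per_L")
  miss <- setdiff(need, names(tab))
  ep_assert(length(miss) == 0L, "epferm_data_error",
            sprintf("long-table CSV misses columns: %s (found: %s)",
                    paste(miss, collapse = ", "),
                    paste(names(tab), collapse = ", ")))
  tab[need]
}

# pipeline ----------------------------------------------------------------

#' Build a pipeline run configuration
#'
#' @param command one of `"design"`, `"fit-rsm"`, `"optimize"`,
#'   `"fit-kinetics"`, `"simulate"`, `"generate"`.
#' @param input input file path (command dependent; the packaged design
#'   table is used when `NULL` where a design is needed).
#' @param out_dir output directory, created if missing.
#' @param seed integer seed for every stochastic step.
#' @param verbose print progress messages.
#' @param options named list of command-specific options (e.g. `C0_eff`,
#'   `Yb`, `Yp` for `fit-kinetics`; `kind` and `kd` for `simulate`).
#' @return an object of class `ep_config`.
#' @export
pipeline_config <- function(command, input = NULL, out_dir = ".",
                            seed = 0L, verbose = FALSE, options = list()) {
  cmds <- c("design", "fit-rsm", "optimize", "fit-kinetics", "simulate",
            "generate")
  ep_assert(is.character(command) && length(command) == 1L &&
              command %in% cmds,
            "epferm_usage_error",
            sprintf("'command' must be one of: %s",
                    paste(cmds, collapse = ", ")))
  if (!is.null(input)) {
    ep_assert(file.exists(input), "epferm_usage_error",
              sprintf("input path not resolvable: %s", input))
  }
  structure(
    list(command = command, input = input, out_dir = out_dir,
         seed = as.integer(seed), verbose = isTRUE(verbose),
         options = options),
    class = "ep_config"
  )
}

#' Run one pipeline stage
#'
#' Dispatches on the configured command, writes its primary artifacts and a
#' run log (package version, seed, input checksums) into the output
#' directory, and returns the artifact paths. Identical configuration and
#' inputs give identical primary artifacts; all randomness flows through
#' the configured seed.
#'
#' @param config an [pipeline_config()].
#' @return named character vector of artifact paths, invisibly.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile()
#' run_pipeline(pipeline_config("fit-rsm", out_dir = out))
#' }
run_pipeline <- function(config) {
  ep_assert(inherits(config, "ep_config"), "epferm_usage_error",
            "'config' must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  opt <- config$options
  art <- character(0)

  load_input_design <- function() {
    if (is.null(config$input)) load_design_fixture()
    else read_design_csv(config$input)
  }
  load_input_long <- function() {
    if (is.null(config$input)) {
      assemble_long_table(load_design_fixture())
    } else if (grepl("ep_ug_per_L", readLines(config$input, n = 1L))) {
      read_long_table_csv(config$input)
    } else {
      assemble_long_table(read_design_csv(config$input))
    }
  }
  path_in <- function(name) file.path(config$out_dir, name)

  if (config$command == "design") {
    n_runs <- opt$n_runs %||% 10L
    factors <- opt$factors %||% ep_medium_factors()
    say("constructing U%d(%d^%d) design", n_runs, n_runs, length(factors))
    d <- uniform_design(n_runs, factors, generators = opt$generators)
    art["design"] <- write_design_csv(d, path_in("design.csv"))
  } else if (config$command == "fit-rsm") {
    long <- load_input_long()
    fit <- fit_response_surface(long)
    art[c("report_txt", "report_json")] <-
      write_report(render_report(fit), path_in("rsm_report"))
  } else if (config$command == "optimize") {
    design <- load_input_design()
    fit <- fit_response_surface(assemble_long_table(design))
    optimum <- recommend_optimum(fit, design)
    payload <- list(
      type = "optimum_recommendation",
      settings = optimum$settings,
      predicted_ug_per_L = optimum$predicted,
      optimum_time_h = optimum$optimum_time,
      recipe_g_per_L = as.list(optimum$recipe_g_per_L)
    )
    art["optimum_json"] <- path_in("optimum.json")
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), art["optimum_json"])
    art["optimum_txt"] <- path_in("optimum.txt")
    writeLines(utils::capture.output(print(optimum)), art["optimum_txt"])
  } else if (config$command == "fit-kinetics") {
    ep_assert(!is.null(config$input), "epferm_usage_error",
              "fit-kinetics needs an input batch CSV")
    series <- read_batch_csv(config$input)
    C0_eff <- opt$C0_eff %||% max(series$substrate_g_per_L)
    comp <- compare_models(series, C0_eff, Yb = opt$Yb, Yp = opt$Yp)
    if (all(comp$ranking$failed)) {
      ep_stop("epferm_insufficient_data_error",
              "no kinetic model could be fitted to the input series")
    }
    art[c("report_txt", "report_json")] <-
      write_report(render_report(comp), path_in("kinetics_report"))
  } else if (config$command == "simulate") {
    spec <- default_trajectory_spec(seed = config$seed,
                                    kd = opt$kd)
    kind <- opt$kind %||% spec$kind
    params <- opt$params %||% spec$params
    times <- opt$times %||% spec$times
    if (is.null(opt$schedule)) {
      sim <- simulate_batch(kind, params, times, kd = opt$kd %||% 0)
    } else {
      sim <- simulate_fed_batch(kind, params, opt$schedule, times,
                                kd = opt$kd %||% 0)
    }
    art["trajectory"] <- write_batch_csv(sim, path_in("trajectory.csv"))
  } else if (config$command == "generate") {
    design <- load_input_design()
    truth <- fit_response_surface(assemble_long_table(design))
    noisy_design <- generate_design_responses(
      design, design_noise_spec(truth, sd = opt$design_sd %||% 10,
                                seed = config$seed))
    art["design_responses"] <-
      write_design_csv(noisy_design, path_in("synthetic_design.csv"))
    series <- generate_batch_series(default_trajectory_spec(
      seed = config$seed, kd = opt$kd))
    art["batch_series"] <-
      write_batch_csv(series, path_in("synthetic_batch.csv"))
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  checksums <- if (is.null(config$input)) "none" else {
    paste(basename(config$input), unname(tools::md5sum(config$input)))
  }
  writeLines(c(
    sprintf("command: %s", config$command),
    sprintf("epferm version: %s", as.character(packageVersion("epferm"))),
    sprintf("R version: %s", as.character(getRversion())),
    sprintf("seed: %d", config$seed),
    sprintf("input checksum: %s", checksums),
    sprintf("artifacts: %s", paste(basename(art), collapse = ", "))
  ), log_path)
  art["log"] <- log_path
  say("wrote %d artifact(s) to %s", length(art) - 1L, config$out_dir)
  invisible(art)
}
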