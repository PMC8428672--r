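#' Load a model configuration from YAML
#'
#' Reads a structured text config with blocks \code{parameters} (per-month
#' model parameters, keys as in \code{\link{sbe_parameters}}),
#' \code{initial_state} (keys as in \code{\link{sbe_initial_state}}) and
#' optional \code{weights} / \code{cea}.  Unknown keys are rejected and all
#' parameter invariants are enforced at load.
#'
#' @param path YAML file path.
#' @return list with \code{params}, \code{init}, and (if present)
#'   \code{weights}, \code{cea}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("parameters", "initial_state", "weights",
                               "cea"))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  params <- do.call(sbe_parameters, as.list(cfg$parameters))
  init <- do.call(sbe_initial_state, as.list(cfg$initial_state))
  out <- list(params = params, init = init)
  if (!is.null(cfg$weights))
    out$weights <- do.call(control_weights, as.list(cfg$weights))
  if (!is.null(cfg$cea)) out$cea <- do.call(cea_config, as.list(cfg$cea))
  out
}

#' Save a model configuration to YAML
#'
#' Inverse of \code{\link{load_config}}; round-trips exactly.
#'
#' @param params an \code{\link{sbe_parameters}} object.
#' @param init an initial state vector.
#' @param path output file path.
#' @param weights optional \code{\link{control_weights}}.
#' @param cea optional \code{\link{cea_config}}.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(params, init, path, weights = NULL, cea = NULL) {
  cfg <- list(parameters = unclass(params),
              initial_state = as.list(init[.state_names]))
  if (!is.null(weights)) cfg$weights <- unclass(weights)
  if (!is.null(cea)) cfg$cea <- unclass(cea)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Path to the packaged baseline configuration
#'
#' The fitted parameter estimates and initial conditions for the northeast
#' Nigeria registry, as shipped in \code{inst/extdata}.
#'
#' @return file path.
#' @export
baseline_config_path <- function() {
  system.file("extdata", "baseline_config.yaml", package = "sbecontrol",
              mustWork = TRUE)
}

#' Read / write a monthly cumulative report table
#'
#' Delimited-text schema: header \code{month,envenomings,early_treatment,
#' late_treatment,ear_early,ear_late,recovered_disability,
#' recovered_no_disability,deaths}, one row per month boundary, cumulative
#' counts.
#'
#' @param path CSV file path.
#' @return the validated report table.
#' @export
read_report_table <- function(path) {
  tab <- read.csv(path)
  validate_report_table(tab)
  tab
}

#' @rdname read_report_table
#' @param table a report table.
#' @export
write_report_table <- function(table, path) {
  validate_report_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as delimited text
#'
#' One row per output time, columns named as the state vector.
#'
#' @param traj an \code{sbe_trajectory}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Run the full published-scenario suite
#'
#' Executes the awareness cases (10/50/90\%), the early-treatment cases,
#' optimal-control strategies A/B/C under the published scenario, and the
#' cost-effectiveness chain, writing one comparison table per stage to
#' \code{out_dir} (delimited text), plus a run-metadata file with the
#' package version and settings.  Stage failures are logged and the report
#' continues.
#'
#' @param out_dir output directory (created if missing).
#' @param months scenario horizon in months.
#' @param n_steps sweep grid intervals for the optimal-control stages.
#' @param max_iter sweep iteration cap.
#' @return invisible list of the written file paths and any failures.
#' @export
run_paper_suite <- function(out_dir, months = 12, n_steps = 1460,
                            max_iter = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  failures <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error"))
      failures <<- c(failures, paste0(name, ": ", attr(res, "condition")$message))
    res
  }
  params <- sbe_parameters()
  init <- sbe_initial_state()

  stage("awareness", {
    rows <- lapply(c(0.1, 0.5, 0.9), function(lev) {
      sc <- awareness_scenario(lev, months, params, init)
      av <- averted_outcomes(sc$intervention, sc$baseline)
      data.frame(level = lev, sbe_averted = av$cases,
                 deaths_averted = av$deaths,
                 disability_averted = av$disabilities)
    })
    emit(do.call(rbind, rows), "awareness_averted")
  })

  stage("early_treatment", {
    rows <- lapply(c(0.1, 0.5, 0.9), function(lev) {
      sc <- early_treatment_scenario(lev, months, params, init)
      av <- averted_outcomes(sc$intervention, sc$baseline)
      data.frame(level = lev, deaths_averted = av$deaths)
    })
    emit(do.call(rbind, rows), "early_treatment_averted")
  })

  stage("budget", {
    b <- awareness_budget()
    emit(data.frame(component = c("broadcast", "sms", "total", "per_capita"),
                    amount = c(b$broadcast, b$sms, b$total, b$per_capita)),
         "awareness_budget")
  })

  so <- stage("optimal_control", {
    so <- strategy_outcomes(months = months, n_steps = n_steps,
                            max_iter = max_iter)
    emit(so$outcomes, "strategy_outcomes")
    so
  })

  stage("cea", {
    if (inherits(so, "try-error")) stop("strategy outcomes unavailable")
    cfg <- cea_config()
    ic <- icer_analysis(so$outcomes, cfg)
    emit(ic$final, "icer_deaths")
    daly <- so$outcomes
    daly$effect <- deaths_to_daly(daly$effect, cfg)
    ic_daly <- icer_analysis(daly, cfg)
    emit(ic_daly$final, "icer_daly")
    emit(data.frame(dominated = if (length(ic$dominated))
                      paste(ic$dominated, collapse = ";") else NA,
                    recommended = ic$recommended,
                    classification = ic$classification),
         "cea_verdict")
  })

  meta <- c(paste("package:", as.character(utils::packageVersion("sbecontrol"))),
            paste("months:", months), paste("n_steps:", n_steps),
            paste("written:", length(written)),
            if (length(failures)) paste("FAILED", failures))
  writeLines(meta, file.path(out_dir, "run_metadata.txt"))
  invisible(list(written = written, failures = failures))
}
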