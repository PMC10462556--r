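#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis/simulation
#' pipeline run. A run is reproducible from `(config, seed)`.
#'
#' @param source `"table"` (use the bundled summary parameters),
#'   `"synthetic"` (generate a synthetic cohort, analyse it, and simulate
#'   from the estimated parameters) or `"steplog"` (read a step-log CSV).
#' @param steplog_path step-log CSV path (source `"steplog"`).
#' @param synthetic_n cohort size per category (source `"synthetic"`).
#' @param categories,modes,scenarios cells of the simulation grid.
#' @param n_runs runs per batch.
#' @param seed root seed; every batch uses a numbered substream derived
#'   from it.
#' @param output_dir directory for the artifact set.
#' @param imaging_policy,leakage_policy scenario and fixed-addition
#'   policies, see [apply_scenario()] and [fit_models()].
#' @param include_idle,include_p11 phase-breakdown inclusion flags.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = "table", steplog_path = NULL,
                            synthetic_n = 30,
                            categories = surgery_categories(),
                            modes = c("gaussian", "uniform"),
                            scenarios = 1:3, n_runs = 45000, seed = 1L,
                            output_dir = "llrsim-output",
                            imaging_policy = "replace",
                            leakage_policy = "mean_times_occ",
                            include_idle = FALSE, include_p11 = FALSE) {
  stopifnot(source %in% c("table", "synthetic", "steplog"),
            all(categories %in% surgery_categories()),
            all(modes %in% c("gaussian", "uniform")),
            all(scenarios %in% 1:3), n_runs >= 1)
  if (source == "steplog" && is.null(steplog_path)) {
    stop("source 'steplog' requires steplog_path")
  }
  structure(list(source = source, steplog_path = steplog_path,
                 synthetic_n = synthetic_n, categories = categories,
                 modes = modes, scenarios = sort(unique(scenarios)),
                 n_runs = n_runs, seed = as.integer(seed),
                 output_dir = output_dir, imaging_policy = imaging_policy,
                 leakage_policy = leakage_policy,
                 include_idle = include_idle, include_p11 = include_p11),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML or JSON key-value document; keys as in [pipeline_config()].
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, vals)
}

batch_seed <- function(root_seed, index) {
  # numbered substreams; stays well below 2^31 for small root seeds
  (as.integer(root_seed) %% 1000000L) * 1000L + index
}

#' Run the full pipeline
#'
#' Executes generate/read, verify, analyse, model fitting, the full
#' scenario-by-mode-by-category simulation grid, and report writing. The
#' artifact set comprises `module_stats.csv` (per-category summary table),
#' `phase_breakdown.csv`, `batches.json` (per-cell batch summaries),
#' `improvement.csv`/`improvement.json` (scenario impact), a convergence
#' report and `pipeline_log.txt` (seed, config hash and the substream id of
#' every batch). Any stage error aborts the run with the stage name and
#' removes partial outputs. Identical `(config, seed)` produce identical
#' outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the in-memory results (`params`, `stats`,
#'   `batches`, `improvement`, `convergence`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  res <- tryCatch({
    stage <- "input"
    inputs <- pipeline_inputs(config)
    stage <- "analyse"
    stats <- lapply(inputs$cohorts, module_stats)
    breakdowns <- lapply(inputs$params, phase_breakdown,
                         include_idle = config$include_idle,
                         include_p11 = config$include_p11)
    stage <- "simulate"
    grid <- expand.grid(category = config$categories, mode = config$modes,
                        scenario = config$scenarios,
                        stringsAsFactors = FALSE)
    batches <- vector("list", nrow(grid))
    log_lines <- character(0)
    for (i in seq_len(nrow(grid))) {
      cell <- grid[i, ]
      model <- fit_models(inputs$params[[cell$category]], mode = cell$mode,
                          leakage_policy = config$leakage_policy)
      model <- apply_scenario(model, scenario_spec(cell$scenario),
                              imaging_policy = config$imaging_policy)
      s <- batch_seed(config$seed, i)
      batches[[i]] <- run_batch(model, n_runs = config$n_runs, seed = s)
      log_lines <- c(log_lines,
                     sprintf("batch %d: %s scenario %d %s substream %d",
                             i, cell$category, cell$scenario, cell$mode, s))
    }
    stage <- "convergence"
    conv_model <- fit_models(inputs$params[[config$categories[1]]],
                             mode = config$modes[1],
                             leakage_policy = config$leakage_policy)
    cb1 <- run_batch(conv_model, config$n_runs, batch_seed(config$seed, 901L))
    cb2 <- run_batch(conv_model, config$n_runs, batch_seed(config$seed, 902L))
    conv <- check_convergence(cb1, cb2)
    stage <- "report"
    improvement <- improvement_table(grid, batches)
    files <- write_pipeline_outputs(config, inputs, stats, breakdowns, grid,
                                    batches, improvement, conv, log_lines)
    list(params = inputs$params, stats = stats, batches = batches,
         improvement = improvement, convergence = conv, files = files)
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

pipeline_inputs <- function(config) {
  params <- list()
  cohorts <- list()
  if (config$source == "table") {
    for (cat_id in config$categories) params[[cat_id]] <- default_params(cat_id)
  } else if (config$source == "synthetic") {
    for (i in seq_along(config$categories)) {
      cat_id <- config$categories[i]
      cohort <- generate_cohort(default_params(cat_id), config$synthetic_n,
                                seed = batch_seed(config$seed, 800L + i))
      verify_cohort(cohort, build_category_graph(cat_id))
      cohorts[[cat_id]] <- cohort
      params[[cat_id]] <- estimated_params(cohort)
    }
  } else {
    logs <- read_steplogs(config$steplog_path)
    for (cat_id in config$categories) {
      cohort <- Filter(function(l) l$category == cat_id, logs)
      if (length(cohort) == 0) {
        stop("no surgeries of category ", cat_id, " in ", config$steplog_path)
      }
      verify_cohort(cohort, build_category_graph(cat_id))
      cohorts[[cat_id]] <- cohort
      params[[cat_id]] <- estimated_params(cohort)
    }
  }
  list(params = params, cohorts = cohorts)
}

verify_cohort <- function(cohort, graph) {
  for (log in cohort) {
    rep <- verify_log(log, graph)
    if (length(rep) > 0) {
      stop("log '", log$surgery_id, "' fails verification: ",
           paste(rep, collapse = "; "))
    }
  }
  invisible(TRUE)
}

improvement_table <- function(grid, batches) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    if (cell$scenario == 1) next
    ref_i <- which(grid$category == cell$category & grid$mode == cell$mode &
                     grid$scenario == 1)
    if (length(ref_i) != 1) next
    b <- batches[[i]]
    ref <- batches[[ref_i]]
    rows[[length(rows) + 1]] <- data.frame(
      category = cell$category, mode = cell$mode, scenario = cell$scenario,
      mean_s = b$mean_s, decrease_pct = improvement_percent(b, ref),
      peak_s = b$peak_s,
      peak_decrease_pct = if (is.finite(b$peak_s) && is.finite(ref$peak_s)) {
        improvement_percent(b, ref, stat = "peak")
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(config, inputs, stats, breakdowns, grid,
                                   batches, improvement, conv, log_lines) {
  out <- config$output_dir
  files <- character(0)
  f <- file.path(out, "module_stats.csv")
  stats_tab <- if (length(stats) > 0) {
    do.call(rbind, lapply(names(stats), function(cat_id) {
      cbind(category = cat_id, stats[[cat_id]])
    }))
  } else {
    do.call(rbind, lapply(names(inputs$params), function(cat_id) {
      p <- inputs$params[[cat_id]]
      data.frame(category = cat_id, module = p$module,
                 n_present = NA_integer_, occ_mean = p$occ_mean,
                 occ_sd = p$occ_sd, duration_mean_s = p$duration_mean_s,
                 duration_sd_s = p$duration_sd_s, stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(stats_tab, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out, "phase_breakdown.csv")
  bd <- do.call(rbind, lapply(names(breakdowns), function(cat_id) {
    cbind(category = cat_id, breakdowns[[cat_id]])
  }))
  utils::write.csv(bd, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out, "batches.json")
  summaries <- lapply(seq_len(nrow(grid)), function(i) {
    b <- batches[[i]]
    list(category = b$category, mode = b$mode, scenario = b$scenario_id,
         n = b$n_runs, n_excluded = b$n_excluded, mean_s = b$mean_s,
         sd_s = b$sd_s, peak_s = b$peak_s, seed = b$seed)
  })
  jsonlite::write_json(summaries, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  if (!is.null(improvement)) {
    f <- file.path(out, "improvement.csv")
    utils::write.csv(improvement, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out, "improvement.json")
    jsonlite::write_json(improvement, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, f)
  }

  f <- file.path(out, "convergence.json")
  jsonlite::write_json(conv, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  cfg_file <- file.path(out, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg_file)

  f <- file.path(out, "pipeline_log.txt")
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("config_md5: %s", unname(tools::md5sum(cfg_file))),
               log_lines), f)
  files <- c(files, f)
  files
}
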