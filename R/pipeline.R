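#' Assemble a pipeline run configuration
#'
#' Bundles stage toggles, inputs (simulation configs or file paths), seeds
#' and thresholds for [run_pipeline()].  Each enabled stage takes its input
#' either from the previous stage or from a file, so stages can also be run
#' separately on persisted intermediates.
#'
#' @param stages character vector of stages to run, in pipeline order, from
#'   `c("simulate", "normalize", "call", "network", "screen")`.
#' @param plate a [plate_sim_config()] (when `"simulate"` is enabled).
#' @param wells_path CSV of well counts (when normalizing without simulating).
#' @param control_condition,experiment_id forwarded to
#'   [normalize_to_control()].
#' @param threshold_multiplier forwarded to [call_interactions()].
#' @param predicted_edges tibble (`central`, `cancer`) or TSV path of
#'   yeast-predicted pairs for the network stage.
#' @param kinetics a [kinetic_sim_config()] for the screen stage (or `NULL`).
#' @param traces_path,descriptors_path CSVs for a screen on real files.
#' @param concentrations molar doses to simulate (must include 0, the
#'   vehicle).
#' @param descriptors compound descriptor tibble (alternative to the path).
#' @param counterscreen quencherless inhibition table; `NULL` simulates it
#'   from `kinetics`.
#' @param screening_conc,hit_threshold,counterscreen_threshold screen-funnel
#'   thresholds (see [run_screen()]).
#' @param seed master seed, required whenever a simulation input is used.
#' @param out_dir directory for intermediate tables and the JSON report;
#'   `NULL` keeps everything in memory.
#' @return a `synlethnet_run_config` list.
#' @seealso [demo_run_config()] for a ready-made study-shaped configuration.
#' @export
run_config <- function(stages = c("simulate", "normalize", "call", "network",
                                  "screen"),
                       plate = NULL, wells_path = NULL,
                       control_condition = "GAPDH", experiment_id = "expt1",
                       threshold_multiplier = 3,
                       predicted_edges = NULL,
                       kinetics = NULL, traces_path = NULL,
                       descriptors_path = NULL,
                       concentrations = c(0, 1e-5),
                       descriptors = NULL, counterscreen = NULL,
                       screening_conc = NULL, hit_threshold = 50,
                       counterscreen_threshold = 50,
                       seed = NULL, out_dir = NULL) {
  structure(list(stages = stages, plate = plate, wells_path = wells_path,
                 control_condition = control_condition,
                 experiment_id = experiment_id,
                 threshold_multiplier = threshold_multiplier,
                 predicted_edges = predicted_edges,
                 kinetics = kinetics, traces_path = traces_path,
                 descriptors_path = descriptors_path,
                 concentrations = concentrations,
                 descriptors = descriptors, counterscreen = counterscreen,
                 screening_conc = screening_conc,
                 hit_threshold = hit_threshold,
                 counterscreen_threshold = counterscreen_threshold,
                 seed = seed, out_dir = out_dir),
            class = "synlethnet_run_config")
}

#' Validate a run configuration
#'
#' Checks that every enabled stage has an input and that thresholds are
#' sensible; problems are returned, not raised, so a front end can present
#' them all at once.  An empty return value means [run_pipeline()] would
#' start.
#'
#' @param config a [run_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  known <- c("simulate", "normalize", "call", "network", "screen")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) {
    problems <- c(problems, paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  simulating <- "simulate" %in% config$stages ||
    (!is.null(config$kinetics) && "screen" %in% config$stages)
  if (simulating && is.null(config$seed)) {
    problems <- c(problems, "seed is required when simulation is enabled")
  }
  if ("simulate" %in% config$stages && is.null(config$plate)) {
    problems <- c(problems, "stage 'simulate' needs a plate config")
  }
  if ("normalize" %in% config$stages && !"simulate" %in% config$stages) {
    if (is.null(config$wells_path)) {
      problems <- c(problems, "stage 'normalize' needs wells_path when not simulating")
    } else if (!file.exists(config$wells_path)) {
      problems <- c(problems, paste("wells_path does not exist:", config$wells_path))
    }
  }
  if ("network" %in% config$stages) {
    pe <- config$predicted_edges
    if (is.character(pe) && !file.exists(pe)) {
      problems <- c(problems, paste("predicted_edges path does not exist:", pe))
    }
    if (!"call" %in% config$stages) {
      problems <- c(problems, "stage 'network' needs stage 'call' upstream")
    }
  }
  if ("screen" %in% config$stages) {
    if (is.null(config$kinetics) && is.null(config$traces_path)) {
      problems <- c(problems, "stage 'screen' needs kinetics config or traces_path")
    }
    if (!is.null(config$traces_path) && !file.exists(config$traces_path)) {
      problems <- c(problems, paste("traces_path does not exist:", config$traces_path))
    }
    if (is.null(config$descriptors) && is.null(config$descriptors_path)) {
      problems <- c(problems, "stage 'screen' needs descriptors or descriptors_path")
    }
    if (!is.null(config$descriptors_path) &&
        !file.exists(config$descriptors_path)) {
      problems <- c(problems, paste("descriptors_path does not exist:",
                                    config$descriptors_path))
    }
  }
  if (!is.numeric(config$threshold_multiplier) ||
      config$threshold_multiplier < 0) {
    problems <- c(problems, "threshold_multiplier must be non-negative")
  }
  problems
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in order — simulate plate, normalize to
#' control, call interactions, assemble the conservation network, run the
#' inhibitor-screen funnel — carrying intermediates in memory and optionally
#' persisting every table plus a JSON report under `out_dir`.  Re-running
#' with an identical config and seed reproduces identical outputs.
#'
#' @param config a [run_config()] (see also [demo_run_config()]).
#' @return a `synlethnet_report` list: per-stage row counts, interaction
#'   calls, conservation summary, hub ranking, screen funnel, package
#'   version, seed and config hash.
#' @examples
#' \donttest{
#' report <- run_pipeline(demo_run_config(seed = 1))
#' report$conservation
#' }
#' @export
run_pipeline <- function(config) {
  check_that(inherits(config, "synlethnet_run_config"),
             "config must be built with run_config()")
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid config:\n", paste("-", problems, collapse = "\n")),
          class = "synlethnet_validation_error")
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  persist <- function(obj, writer, file) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
    obj
  }

  report <- list(stages = config$stages,
                 counts = list(),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("synlethnet")),
                 config_hash = rlang::hash(config[setdiff(names(config),
                                                          "out_dir")]))
  wells <- summaries <- calls <- edges <- NULL

  if ("simulate" %in% config$stages) {
    wells <- persist(simulate_plate(config$plate), write_well_csv, "wells.csv")
    report$counts$wells <- nrow(wells)
  }
  if ("normalize" %in% config$stages) {
    if (is.null(wells)) wells <- read_well_csv(config$wells_path)
    summaries <- normalize_to_control(
      wells, control_condition = config$control_condition,
      experiment_id = config$experiment_id
    )
    persist(summaries, write_summary_tsv, "viability_summaries.tsv")
    report$counts$conditions <- nrow(summaries)
  }
  if ("call" %in% config$stages) {
    check_that(!is.null(summaries), "stage 'call' needs normalized summaries")
    calls <- call_interactions(summaries,
                               threshold_multiplier = config$threshold_multiplier)
    persist(calls, write_calls_tsv, "interaction_calls.tsv")
    report$counts$pairs_tested <- nrow(calls)
    report$calls <- calls
  }
  if ("network" %in% config$stages) {
    pe <- config$predicted_edges
    if (is.character(pe)) pe <- read_edges_tsv(pe)
    if (is.null(pe)) pe <- tibble(central = character(0),
                                  cancer = character(0))
    edges <- build_network(pe, calls)
    persist(edges, write_edges_tsv, "network_edges.tsv")
    if (!is.null(out_dir)) write_edges_sif(edges, file.path(out_dir, "sif"))
    report$conservation <- conservation_summary(edges)
    report$hubs <- rank_hubs(edges)
    if (!is.null(out_dir)) {
      jsonlite::write_json(as.list(report$conservation),
                           file.path(out_dir, "conservation_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    report$counts$edges <- nrow(edges)
  }
  if ("screen" %in% config$stages) {
    if (!is.null(config$kinetics)) {
      traces <- simulate_kinetic_screen(config$kinetics,
                                        config$concentrations)
      counterscreen <- config$counterscreen %||%
        simulate_counterscreen(config$kinetics,
                               config$screening_conc %||%
                                 max(config$concentrations))
    } else {
      traces <- read_traces_csv(config$traces_path)
      counterscreen <- config$counterscreen
    }
    persist(traces, write_traces_csv, "kinetic_traces.csv")
    descriptors <- config$descriptors %||%
      read_descriptors_csv(config$descriptors_path)
    funnel <- run_screen(traces, counterscreen, descriptors,
                         screening_conc = config$screening_conc,
                         hit_threshold = config$hit_threshold,
                         counterscreen_threshold = config$counterscreen_threshold)
    funnel <- dplyr::left_join(
      funnel, fit_screen_ic50s(traces, funnel), by = "compound_id"
    )
    persist(funnel, function(x, p) readr::write_tsv(x, p), "screen_funnel.tsv")
    report$funnel <- funnel
    report$counts$compounds <- nrow(funnel)
    report$counts$primary_hits <- sum(funnel$primary_hit)
    report$counts$selected <- sum(funnel$selected)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = "synlethnet_report")
}

# 4PL fits for the compounds retained by the funnel (needs >= 4 doses).
fit_screen_ic50s <- function(traces, funnel) {
  doses <- sort(unique(traces$conc_M[traces$conc_M > 0]))
  selected <- funnel$compound_id[funnel$selected]
  if (length(doses) < 4 || length(selected) == 0) {
    return(tibble(compound_id = character(0), ic50 = numeric(0),
                  hill = numeric(0), fit_converged = logical(0)))
  }
  rates <- screen_rates(traces[traces$compound %in% selected |
                                 traces$conc_M == 0, ])
  purrr::map_dfr(selected, function(cpd) {
    veh <- rates$slope[rates$compound == cpd & rates$conc_M == 0]
    sub <- rates[rates$compound == cpd & rates$conc_M > 0, ]
    act <- 100 - percent_inhibition(sub$slope, veh)
    fit <- fit_ic50(sub$conc_M, act)
    tibble(compound_id = cpd, ic50 = fit$ic50, hill = fit$hill,
           fit_converged = fit$converged)
  })
}

# JSON-serialisable view of a report (tibbles become row-wise data frames).
report_to_json <- function(report) {
  out <- unclass(report)
  for (nm in names(out)) {
    if (is.data.frame(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}

#' @export
print.synlethnet_report <- function(x, ...) {
  cat("synlethnet pipeline report (seed ", x$seed %||% "none",
      ", config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  for (nm in names(x$counts)) cat(sprintf("  %-13s %d\n", nm, x$counts[[nm]]))
  if (!is.null(x$conservation)) {
    s <- x$conservation
    cat(sprintf("  conservation: %d/%d predicted pairs conserved (%d%%)\n",
                s$n_conserved, s$n_predicted, s$pct_conserved))
  }
  invisible(x)
}

#' Demo configuration replicating the study-shaped analysis
#'
#' A 3 central x 10 cancer gene plate screen whose ground truth is a network
#' fixture with 22 yeast-predicted pairs, 16 of them planted as true
#' interactions, plus one unpredicted (human-only) interaction; and a small
#' compound screen with genuine inhibitors, fluorescent artifacts, and
#' rule-of-five violators.  Interaction strength 0.5, 5% well CV, 6 wells
#' per condition.
#'
#' @param seed master seed; sub-seeds for the plate, kinetics and fixture are
#'   derived from it.
#' @param out_dir optional output directory.
#' @return a `synlethnet_run_config`.
#' @export
demo_run_config <- function(seed = 1L, out_dir = NULL) {
  central <- c("WDHD1", "FEN1", "CHTF8")
  cancer <- c("SMC1A", "SMC3", "NIPBL", "STAG1", "STAG2", "STAG3",
              "RNF20", "FBXW7", "MRE11A", "RAD54B")
  truth <- make_network_fixture(3, 10, 22, 16, 1,
                                central_genes = central, cancer_genes = cancer,
                                seed = derive_seed(seed, 11L))
  epsilon <- tibble(central = truth$central[truth$human_observed],
                    cancer = truth$cancer[truth$human_observed],
                    epsilon = 0.5)
  plate <- study_plate_config(epsilon = epsilon, seed = derive_seed(seed, 12L))
  predicted <- truth[truth$yeast_predicted, c("central", "cancer")]

  compounds <- tibble(
    compound_id = c("inh-A", "inh-B", "inh-C", "art-D", "art-E",
                    "inact-F", "bigmw-G"),
    true_ic50 = c(5e-7, 1e-6, 3e-6, 1e-6, 2e-6, 1, 8e-7),
    hill = 1,
    is_fluorescent_artifact = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
  kinetics <- kinetic_sim_config(compounds, noise_sd = 2,
                                 seed = derive_seed(seed, 13L))
  descriptors <- tibble(
    compound_id = compounds$compound_id,
    mw = c(320, 410, 380, 290, 350, 300, 650),
    clogp = c(2.1, 3.4, 1.8, 2.5, 4.0, 1.2, 3.0),
    hbd = c(2L, 1L, 3L, 2L, 1L, 2L, 4L),
    hba = c(4L, 6L, 5L, 3L, 7L, 4L, 8L)
  )

  run_config(plate = plate, predicted_edges = predicted,
             kinetics = kinetics,
             concentrations = c(0, 10^seq(-7.5, -4.5, by = 0.5)),
             screening_conc = 1e-5,
             descriptors = descriptors, seed = as.integer(seed),
             out_dir = out_dir)
}
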