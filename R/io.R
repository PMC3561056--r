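# On-disk dialects: plain-text CSV/TSV tables plus SIF edge lists, so every
# intermediate of the pipeline round-trips through files.

#' Read and write well-count tables
#'
#' CSV with header `plate_id,well_id,condition_id,genes_targeted,nuclei_count`
#' (genes semicolon-joined, empty string for the non-silencing condition).
#'
#' @param wells tibble of well records.
#' @param path file path.
#' @return `read_well_csv()` returns the well tibble; the writer returns its
#'   input invisibly.
#' @export
write_well_csv <- function(wells, path) {
  readr::write_csv(as_tibble(wells), path, na = "")
  invisible(wells)
}

#' @rdname write_well_csv
#' @export
read_well_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    well_id = readr::col_character(),
    condition_id = readr::col_character(),
    genes_targeted = readr::col_character(),
    nuclei_count = readr::col_integer()
  ), na = character())
}

#' Read and write viability summary tables
#'
#' TSV with header
#' `experiment_id,condition_id,genes,mean_viability_pct,sem_pct,n,is_control`.
#'
#' @param summaries tibble from [normalize_to_control()].
#' @param path file path.
#' @return the summary tibble (reader) / input invisibly (writer).
#' @export
write_summary_tsv <- function(summaries, path) {
  out <- tibble(experiment_id = summaries$experiment_id,
                condition_id = summaries$condition_id,
                genes = summaries$genes_targeted,
                mean_viability_pct = summaries$mean_viability,
                sem_pct = summaries$sem,
                n = summaries$n_wells,
                is_control = summaries$is_control)
  readr::write_tsv(out, path, na = "")
  invisible(summaries)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    experiment_id = readr::col_character(),
    condition_id = readr::col_character(),
    genes = readr::col_character(),
    mean_viability_pct = readr::col_double(),
    sem_pct = readr::col_double(),
    n = readr::col_integer(),
    is_control = readr::col_logical()
  ), na = character())
  tibble(experiment_id = raw$experiment_id,
         condition_id = raw$condition_id,
         genes_targeted = raw$genes,
         mean_viability = raw$mean_viability_pct,
         sem = raw$sem_pct,
         n_wells = raw$n,
         is_control = raw$is_control)
}

#' Write interaction calls as TSV
#'
#' Header `experiment_id,central,cancer,v_central,v_cancer,v_obs,v_pred,`
#' `defect,threshold,call`.
#'
#' @param calls tibble from [call_interactions()].
#' @param path file path.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- tibble(experiment_id = calls$experiment_id,
                central = calls$central_gene,
                cancer = calls$cancer_gene,
                v_central = calls$v_central,
                v_cancer = calls$v_cancer,
                v_obs = calls$v_obs,
                v_pred = calls$v_pred,
                defect = calls$defect,
                threshold = calls$threshold,
                call = calls$is_synthetic_lethal)
  readr::write_tsv(out, path)
  invisible(calls)
}

#' Read and write edge tables
#'
#' TSV with header `central,cancer,yeast_predicted,human_observed`.
#'
#' @param edges edge tibble.
#' @param path file path.
#' @return the edge tibble (reader) / input invisibly (writer).
#' @export
write_edges_tsv <- function(edges, path) {
  readr::write_tsv(as_tibble(edges), path)
  invisible(edges)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    central = readr::col_character(),
    cancer = readr::col_character(),
    yeast_predicted = readr::col_logical(),
    human_observed = readr::col_logical()
  ))
}

#' Write SIF edge lists, one file per conservation class
#'
#' Simple interaction format (`central<TAB>sl<TAB>cancer`), split the way the
#' network figure draws its line styles: `conserved.sif` (both flags),
#' `yeast_only.sif`, `human_only.sif`.
#'
#' @param edges edge tibble with both flags.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_edges_sif <- function(edges, dir) {
  edges <- as_tibble(edges)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  classes <- list(
    conserved = edges$yeast_predicted & edges$human_observed,
    yeast_only = edges$yeast_predicted & !edges$human_observed,
    human_only = !edges$yeast_predicted & edges$human_observed
  )
  paths <- character(0)
  for (nm in names(classes)) {
    sel <- edges[classes[[nm]], , drop = FALSE]
    path <- file.path(dir, paste0(nm, ".sif"))
    lines <- if (nrow(sel)) paste(sel$central, "sl", sel$cancer, sep = "\t")
             else character(0)
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read and write long kinetic trace tables
#'
#' CSV with header `compound,conc_M,time_min,rfu`.
#'
#' @param traces long trace tibble.
#' @param path file path.
#' @return the trace tibble (reader) / input invisibly (writer).
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(as_tibble(traces), path)
  invisible(traces)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    conc_M = readr::col_double(),
    time_min = readr::col_double(),
    rfu = readr::col_double()
  ))
}

#' Read compound descriptor tables
#'
#' CSV with header `compound_id,mw,clogp,hbd,hba`.
#'
#' @param path file path.
#' @return descriptor tibble.
#' @export
read_descriptors_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    mw = readr::col_double(),
    clogp = readr::col_double(),
    hbd = readr::col_integer(),
    hba = readr::col_integer()
  ))
}
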