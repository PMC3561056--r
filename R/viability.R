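#' Normalize well counts to the silenced control and summarise per condition
#'
#' Each well's relative viability is `100 * nuclei_count / mean(control
#' counts)`; per condition the mean, SEM (`sd / sqrt(n)`) and replicate count
#' of the normalized wells are returned.  Normalization is within a single
#' experiment (batch): wells from different days/batches should be normalized
#' against their own control by separate calls, or via the `experiment`
#' column when present.
#'
#' @param wells tibble of well records (`condition_id`, `genes_targeted`,
#'   `nuclei_count`, as produced by [simulate_plate()] or read with
#'   [read_well_csv()]).
#' @param control_condition condition id of the normalization control
#'   (default `"GAPDH"`).
#' @param experiment_id batch label stamped on every summary row.
#' @return tibble with columns `experiment_id`, `condition_id`,
#'   `genes_targeted`, `mean_viability`, `sem`, `n_wells`, `is_control`.
#'   Viability is percent of control and may exceed 100 (proliferation above
#'   control is not clamped); the control condition summarises to exactly 100.
#' @examples
#' wells <- tibble::tibble(
#'   condition_id = rep(c("GAPDH", "FEN1"), each = 2),
#'   genes_targeted = rep(c("GAPDH", "FEN1"), each = 2),
#'   nuclei_count = c(900, 1100, 400, 600)
#' )
#' normalize_to_control(wells)  # FEN1: mean 50, SEM 10
#' @export
normalize_to_control <- function(wells, control_condition = "GAPDH",
                                 experiment_id = "expt1") {
  wells <- as_tibble(wells)
  check_that(all(c("condition_id", "nuclei_count") %in% names(wells)),
             "wells needs columns condition_id and nuclei_count")
  if (!"genes_targeted" %in% names(wells)) {
    wells$genes_targeted <- wells$condition_id
  }
  ctrl <- wells$nuclei_count[wells$condition_id == control_condition]
  if (length(ctrl) < 2 || !is.finite(mean(ctrl)) || mean(ctrl) <= 0) {
    abort(paste0("control degenerate: condition '", control_condition,
                 "' needs >= 2 wells with positive mean count"),
          class = "synlethnet_validation_error")
  }
  n_per <- table(wells$condition_id)
  if (any(n_per < 2)) {
    abort(paste("conditions with fewer than 2 wells:",
                paste(names(n_per)[n_per < 2], collapse = ", ")),
          class = "synlethnet_validation_error")
  }
  ctrl_mean <- mean(ctrl)
  wells$viability <- 100 * wells$nuclei_count / ctrl_mean
  out <- dplyr::summarise(
    dplyr::group_by(wells, .data$condition_id, .data$genes_targeted),
    mean_viability = mean(.data$viability),
    sem = sd(.data$viability) / sqrt(dplyr::n()),
    n_wells = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    experiment_id = experiment_id,
    is_control = .data$condition_id == control_condition
  )
  dplyr::select(out, "experiment_id", "condition_id", "genes_targeted",
                "mean_viability", "sem", "n_wells", "is_control")
}

#' Average SEM of an experiment
#'
#' The synthetic-lethality threshold is defined relative to the assay noise
#' of the experiment: the arithmetic mean of the per-condition SEMs of a
#' batch.  By default only single-knockdown conditions enter the average:
#' the SEM of a double-knockdown condition scales with its (possibly
#' interaction-suppressed) viability, so including doubles would let the
#' interactions under test shrink the very threshold used to call them.
#' Averaging over singles keeps the threshold a property of assay noise
#' alone.  Alternative conventions are exposed via `conditions`.
#'
#' @param summaries tibble from [normalize_to_control()].
#' @param experiment_id batch to average over; `NULL` (default) requires the
#'   summaries to contain exactly one experiment.
#' @param conditions which conditions' SEMs to average: `"singles"`
#'   (default; non-control conditions targeting exactly one gene),
#'   `"non_control"` (every condition except the normalization control), or
#'   `"all"`.
#' @return the mean SEM, in percent-viability units.
#' @export
average_experiment_sem <- function(summaries, experiment_id = NULL,
                                   conditions = c("singles", "non_control",
                                                  "all")) {
  conditions <- match.arg(conditions)
  summaries <- as_tibble(summaries)
  if (is.null(experiment_id)) {
    ids <- unique(summaries$experiment_id)
    check_that(length(ids) == 1,
               "summaries span several experiments; pass experiment_id")
    experiment_id <- ids
  }
  keep <- summaries$experiment_id == experiment_id
  is_ctrl <- if ("is_control" %in% names(summaries)) summaries$is_control
             else rep(FALSE, nrow(summaries))
  if (conditions != "all") keep <- keep & !is_ctrl
  if (conditions == "singles") {
    keep <- keep & n_genes_targeted(summaries$genes_targeted) == 1L
  }
  sems <- summaries$sem[keep]
  check_that(length(sems) >= 1,
             paste0("no conditions found for experiment '", experiment_id, "'"))
  mean(sems)
}
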