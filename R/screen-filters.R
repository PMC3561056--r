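#' Remove counterscreen-positive (optical artifact) compounds
#'
#' Apparent hits whose inhibition persists against the quencherless substrate
#' are signal artifacts — autofluorescent compounds or fluorescence
#' quenchers — not enzyme inhibitors, and are removed.
#'
#' @param primary_hits character vector of hit compound ids (or a tibble with
#'   a `compound_id` column).
#' @param quencherless_inhibition named numeric vector, or tibble
#'   `compound_id`, `pct_inhibition_quencherless` (the
#'   [simulate_counterscreen()] dialect), giving apparent percent inhibition
#'   against the quencherless substrate.  Every hit must be present.
#' @param threshold quencherless inhibition at or above which a hit is
#'   discarded as an artifact (default 50%).
#' @return tibble `compound_id`, `pct_inhibition_quencherless`, `retained`.
#' @export
counterscreen_filter <- function(primary_hits, quencherless_inhibition,
                                 threshold = 50) {
  if (is.data.frame(primary_hits)) primary_hits <- primary_hits$compound_id
  if (is.data.frame(quencherless_inhibition)) {
    quencherless_inhibition <- setNames(
      quencherless_inhibition$pct_inhibition_quencherless,
      quencherless_inhibition$compound_id
    )
  }
  missing <- setdiff(primary_hits, names(quencherless_inhibition))
  if (length(missing) > 0) {
    abort(paste("no counterscreen measurement for compound(s):",
                paste(missing, collapse = ", ")),
          class = "synlethnet_validation_error")
  }
  qi <- unname(quencherless_inhibition[primary_hits])
  tibble(compound_id = primary_hits,
         pct_inhibition_quencherless = qi,
         retained = qi < threshold)
}

#' Lipinski rule-of-five drug-likeness triage
#'
#' A compound passes when molecular weight < 500 Da, cLogP <= 5, hydrogen
#' bond donors <= 5 and acceptors <= 10.  Any single violation fails the
#' compound; the violated rules are enumerated.
#'
#' @param descriptors tibble/data frame with columns `compound_id`, `mw`
#'   (Daltons), `clogp`, `hbd`, `hba`; no missing values allowed.
#' @return the descriptors with logical `pass` and a `violations` column
#'   (semicolon-joined rule names, `""` when clean).
#' @examples
#' lipinski_filter(tibble::tibble(compound_id = "cpd1", mw = 300,
#'                                clogp = 2, hbd = 2, hba = 4))
#' @export
lipinski_filter <- function(descriptors) {
  descriptors <- as_tibble(descriptors)
  need <- c("compound_id", "mw", "clogp", "hbd", "hba")
  check_that(all(need %in% names(descriptors)),
             paste("descriptors needs columns:", paste(need, collapse = ", ")))
  check_that(!anyNA(descriptors[need]), "descriptors contain missing values")
  check_that(all(descriptors$mw > 0), "mw must be positive")
  check_that(all(descriptors$hbd >= 0) && all(descriptors$hba >= 0),
             "hbd and hba must be non-negative")
  rules <- cbind(mw = descriptors$mw >= 500,
                 clogp = descriptors$clogp > 5,
                 hbd = descriptors$hbd > 5,
                 hba = descriptors$hba > 10)
  descriptors$pass <- rowSums(rules) == 0
  descriptors$violations <- apply(rules, 1L, function(r) {
    paste(colnames(rules)[r], collapse = ";")
  })
  descriptors
}

#' Run the in vitro screening funnel
#'
#' Primary screen -> counterscreen -> rule-of-five triage, mirroring the
#' biochemical screening cascade: initial rates at a single screening dose
#' give percent inhibition against the vehicle; compounds at or above the hit
#' threshold are primary hits; the quencherless counterscreen removes optical
#' artifacts; Lipinski's rule of five removes non-drug-like compounds.
#'
#' @param traces long trace table (`compound`, `conc_M`, `time_min`, `rfu`)
#'   containing the screening dose and a vehicle (`conc_M == 0`) trace per
#'   compound.
#' @param counterscreen quencherless apparent-inhibition table or named
#'   vector (see [counterscreen_filter()]).
#' @param descriptors compound descriptor table (see [lipinski_filter()]).
#' @param screening_conc molar screening dose to evaluate; default the
#'   largest non-zero concentration in `traces`.
#' @param hit_threshold percent inhibition at or above which a compound is a
#'   primary hit (default 50).
#' @param counterscreen_threshold forwarded to [counterscreen_filter()].
#' @param window_fraction forwarded to [initial_rate()].
#' @return tibble with one row per compound: `compound_id`,
#'   `pct_inhibition`, `primary_hit`, `counterscreen_pass`, `lipinski_pass`,
#'   `selected` (conjunction of the three).
#' @export
run_screen <- function(traces, counterscreen, descriptors,
                       screening_conc = NULL, hit_threshold = 50,
                       counterscreen_threshold = 50, window_fraction = 1.0) {
  rates <- screen_rates(traces, window_fraction = window_fraction)
  if (is.null(screening_conc)) screening_conc <- max(rates$conc_M)
  check_that(screening_conc > 0, "screening_conc must be positive")
  check_that(any(rates$conc_M == 0), "traces must include a vehicle (conc 0)")

  # per-compound vehicle rate; pooled across compounds they are replicates of
  # the same uninhibited reaction, but each compound is normalized to its own
  vehicle <- dplyr::filter(rates, .data$conc_M == 0)
  dosed <- dplyr::filter(rates, .data$conc_M == screening_conc)
  check_that(nrow(dosed) > 0, "no traces at the requested screening_conc")
  joined <- dplyr::inner_join(
    dplyr::select(dosed, "compound", "slope"),
    dplyr::select(vehicle, "compound", vehicle_slope = "slope"),
    by = "compound"
  )
  inhibition <- purrr::map2_dbl(joined$slope, joined$vehicle_slope,
                                percent_inhibition)
  out <- tibble(compound_id = joined$compound,
                pct_inhibition = inhibition,
                primary_hit = inhibition >= hit_threshold)

  hits <- out$compound_id[out$primary_hit]
  cs <- counterscreen_filter(hits, counterscreen,
                             threshold = counterscreen_threshold)
  lip <- lipinski_filter(descriptors)
  out$counterscreen_pass <- ifelse(
    out$primary_hit,
    cs$retained[match(out$compound_id, cs$compound_id)],
    NA
  )
  out$lipinski_pass <- lip$pass[match(out$compound_id, lip$compound_id)]
  out$selected <- out$primary_hit &
    !is.na(out$counterscreen_pass) & out$counterscreen_pass &
    !is.na(out$lipinski_pass) & out$lipinski_pass
  out
}
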