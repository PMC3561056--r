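#' Predicted double-knockdown viability under the multiplicative model
#'
#' The null expectation for a double knockdown is the product of the two
#' single-knockdown proliferations.  On the percent-of-control scale the
#' product is `v_a * v_b / 100`, so a wild-type partner (100%) leaves the
#' other viability unchanged.
#'
#' @param v_a,v_b single-knockdown viabilities in percent of control (>= 0).
#' @return predicted double viability in percent; commutative in its
#'   arguments.
#' @examples
#' predict_double_viability(80, 70)  # 56
#' @export
predict_double_viability <- function(v_a, v_b) {
  check_that(all(v_a >= 0) && all(v_b >= 0),
             "viabilities must be non-negative")
  v_a * v_b / 100
}

#' Proliferative defect of a double knockdown
#'
#' Predicted minus observed double-knockdown viability, in percent-viability
#' units.  Positive values mean the double grew worse than the multiplicative
#' expectation (candidate synthetic lethality); negative values indicate an
#' alleviating interaction.
#'
#' @param v_pred predicted double viability (percent).
#' @param v_obs observed double viability (percent).
#' @return `v_pred - v_obs`, percent.
#' @export
proliferative_defect <- function(v_pred, v_obs) {
  v_pred - v_obs
}

#' Call synthetic-lethal interactions with the 3x-average-SEM rule
#'
#' For every double-knockdown condition, computes the multiplicative-model
#' prediction from the two constituent singles of the same experiment, the
#' proliferative defect, and the lethality threshold
#' `threshold_multiplier * average_experiment_sem()`.  A pair is called
#' synthetic lethal when its defect is at or above the threshold (the rule is
#' inclusive).
#'
#' @param summaries tibble from [normalize_to_control()]; double conditions
#'   are rows whose `genes_targeted` holds two semicolon-joined symbols, and
#'   both singles must be present in the same experiment.
#' @param threshold_multiplier multiple of the average experiment SEM
#'   (default 3).
#' @param sem_conditions which conditions define the average experiment SEM
#'   (see [average_experiment_sem()]); default `"singles"`.
#' @param annotate_fdr if `TRUE`, adds a per-pair normal-approximation
#'   p-value (defect against its propagated standard error) and a
#'   Benjamini-Hochberg q-value.  Off by default: the call itself is the
#'   fixed-threshold rule, not a multiplicity-adjusted test.
#' @return tibble with one row per double: `experiment_id`, `central_gene`,
#'   `cancer_gene`, `v_central`, `v_cancer`, `v_obs`, `v_pred`, `defect`,
#'   `threshold`, `is_synthetic_lethal` (plus `p_value`, `q_value` when
#'   requested).
#' @export
call_interactions <- function(summaries, threshold_multiplier = 3,
                              annotate_fdr = FALSE,
                              sem_conditions = c("singles", "non_control",
                                                 "all")) {
  sem_conditions <- match.arg(sem_conditions)
  summaries <- as_tibble(summaries)
  check_that(is.numeric(threshold_multiplier) && threshold_multiplier >= 0,
             "threshold_multiplier must be non-negative")
  n_tgt <- n_genes_targeted(summaries$genes_targeted)
  out <- dplyr::bind_rows(lapply(
    split(seq_len(nrow(summaries)), summaries$experiment_id),
    function(idx) {
      call_experiment(summaries[idx, ], n_tgt[idx], threshold_multiplier,
                      sem_conditions)
    }
  ))
  if (annotate_fdr) {
    z <- out$defect / out$defect_se
    out$p_value <- stats::pnorm(z, lower.tail = FALSE)
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$defect_se <- NULL
  out
}

call_experiment <- function(summ, n_tgt, threshold_multiplier,
                            sem_conditions) {
  doubles <- summ[n_tgt == 2L, ]
  singles <- summ[n_tgt == 1L & !summ$is_control, ]
  if (nrow(doubles) == 0) return(tibble())
  v_single <- setNames(singles$mean_viability, singles$genes_targeted)
  sem_single <- setNames(singles$sem, singles$genes_targeted)

  pairs <- strsplit(doubles$genes_targeted, ";", fixed = TRUE)
  central <- vapply(pairs, `[`, "", 1L)
  cancer <- vapply(pairs, `[`, "", 2L)
  missing <- !(central %in% names(v_single)) | !(cancer %in% names(v_single))
  if (any(missing)) {
    abort(paste("no single-knockdown summary for pair(s):",
                paste(doubles$genes_targeted[missing], collapse = ", ")),
          class = "synlethnet_validation_error")
  }

  threshold <- threshold_multiplier *
    average_experiment_sem(summ, conditions = sem_conditions)
  v_c <- unname(v_single[central])
  v_k <- unname(v_single[cancer])
  v_pred <- predict_double_viability(v_c, v_k)
  defect <- proliferative_defect(v_pred, doubles$mean_viability)
  # delta-method SE of the defect (prediction and observation independent)
  pred_se <- sqrt((v_k / 100)^2 * unname(sem_single[central])^2 +
                    (v_c / 100)^2 * unname(sem_single[cancer])^2)
  tibble(experiment_id = doubles$experiment_id,
         central_gene = central,
         cancer_gene = cancer,
         v_central = v_c,
         v_cancer = v_k,
         v_obs = doubles$mean_viability,
         v_pred = v_pred,
         defect = defect,
         threshold = threshold,
         is_synthetic_lethal = defect >= threshold,
         defect_se = sqrt(pred_se^2 + doubles$sem^2))
}
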