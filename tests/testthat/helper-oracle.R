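# Independent brute-force recomputation of the scoring pipeline from raw
# wells, written with base R only (tapply/loops), so it shares no code path
# with the package implementation it checks.

oracle_summaries <- function(wells, control = "GAPDH") {
  ctrl_mean <- mean(wells$nuclei_count[wells$condition_id == control])
  rel <- 100 * wells$nuclei_count / ctrl_mean
  means <- tapply(rel, wells$condition_id, mean)
  sds <- tapply(rel, wells$condition_id, sd)
  ns <- tapply(rel, wells$condition_id, length)
  data.frame(condition_id = names(means),
             mean_viability = as.numeric(means),
             sem = as.numeric(sds) / sqrt(as.numeric(ns)),
             stringsAsFactors = FALSE)
}

# defect and threshold per double condition, recomputed from scratch;
# the threshold averages SEMs over single-knockdown conditions (one gene,
# not the control, not the non-silencing "NS" condition)
oracle_calls <- function(wells, control = "GAPDH", multiplier = 3) {
  summ <- oracle_summaries(wells, control)
  is_double <- grepl("+", summ$condition_id, fixed = TRUE)
  is_single <- !is_double & !summ$condition_id %in% c(control, "NS")
  avg_sem <- mean(summ$sem[is_single])
  out <- list()
  for (i in which(is_double)) {
    genes <- strsplit(summ$condition_id[i], "+", fixed = TRUE)[[1]]
    v_a <- summ$mean_viability[summ$condition_id == genes[1]]
    v_b <- summ$mean_viability[summ$condition_id == genes[2]]
    v_pred <- v_a * v_b / 100
    defect <- v_pred - summ$mean_viability[i]
    out[[length(out) + 1]] <- data.frame(
      condition_id = summ$condition_id[i], defect = defect,
      threshold = multiplier * avg_sem,
      lethal = defect >= multiplier * avg_sem
    )
  }
  do.call(rbind, out)
}

# tiny noiseless plate config used across tests
tiny_config <- function(noise_cv = 0, seed = 1L, epsilon = NULL,
                        wells_per_condition = 2L) {
  plate_sim_config(
    central_genes = "A", cancer_genes = "B",
    single_viability = c(A = 0.8, B = 0.7),
    epsilon = epsilon, baseline_count = 1000,
    noise_cv = noise_cv, wells_per_condition = wells_per_condition,
    seed = seed
  )
}
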