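#' Build a conservation-network fixture with exact tallies
#'
#' Generates a complete bipartite central x cancer edge table whose
#' yeast-predicted / human-observed flag cross-tabulation matches the
#' requested tallies *exactly* (the tallies are a contract, not an
#' expectation).  Which particular pairs carry which flags is decided by the
#' seed.  The default tallies reproduce the study's test matrix: 30 pairs, 22
#' predicted in yeast, 16 conserved, and a single human-only interaction.
#'
#' @param n_central,n_cancer numbers of central and cancer genes.
#' @param n_yeast_predicted pairs flagged as predicted in yeast
#'   (<= n_central * n_cancer).
#' @param n_conserved predicted pairs also observed in the human assay
#'   (<= n_yeast_predicted).
#' @param n_human_only pairs observed in human cells without a yeast
#'   prediction (<= n_central * n_cancer - n_yeast_predicted).
#' @param central_genes,cancer_genes optional gene symbols; defaults are
#'   synthetic labels `CEN1..` / `CAN1..`.
#' @param seed integer seed deciding the flag placement.
#' @return tibble with columns `central`, `cancer`, `yeast_predicted`,
#'   `human_observed`; `n_central * n_cancer` rows.
#' @examples
#' edges <- make_network_fixture()        # the 3 x 10 study-shaped fixture
#' conservation_summary(edges)
#' @export
make_network_fixture <- function(n_central = 3, n_cancer = 10,
                                 n_yeast_predicted = 22, n_conserved = 16,
                                 n_human_only = 1,
                                 central_genes = NULL, cancer_genes = NULL,
                                 seed = 1L) {
  n_pairs <- n_central * n_cancer
  check_that(n_central >= 1 && n_cancer >= 1, "need at least one gene per side")
  check_that(n_yeast_predicted >= 0 && n_yeast_predicted <= n_pairs,
             "n_yeast_predicted must be between 0 and n_central * n_cancer")
  check_that(n_conserved >= 0 && n_conserved <= n_yeast_predicted,
             "n_conserved must not exceed n_yeast_predicted")
  check_that(n_human_only >= 0 &&
               n_human_only <= n_pairs - n_yeast_predicted,
             "n_human_only must not exceed the number of unpredicted pairs")

  central_genes <- central_genes %||% paste0("CEN", seq_len(n_central))
  cancer_genes <- cancer_genes %||% paste0("CAN", seq_len(n_cancer))
  check_that(length(central_genes) == n_central &&
               length(cancer_genes) == n_cancer,
             "gene name vectors must match n_central / n_cancer")

  edges <- tidyr::expand_grid(central = central_genes, cancer = cancer_genes)
  flags <- withr::with_seed(derive_seed(seed, 3L), {
    predicted_idx <- sample.int(n_pairs, n_yeast_predicted)
    conserved_idx <- predicted_idx[sample.int(max(length(predicted_idx), 1L),
                                              n_conserved)]
    unpredicted <- setdiff(seq_len(n_pairs), predicted_idx)
    human_only_idx <- unpredicted[sample.int(max(length(unpredicted), 1L),
                                             n_human_only)]
    list(predicted = predicted_idx,
         observed = c(conserved_idx, human_only_idx))
  })
  edges$yeast_predicted <- seq_len(n_pairs) %in% flags$predicted
  edges$human_observed <- seq_len(n_pairs) %in% flags$observed
  edges
}
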