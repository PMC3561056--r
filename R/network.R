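#' Assemble the bipartite yeast-vs-human conservation network
#'
#' Combines a yeast-predicted edge list with human synthetic-lethality calls
#' into one edge per tested central x cancer pair, carrying both flags.  The
#' human flag comes from `is_synthetic_lethal`; the yeast flag from
#' membership in the predicted list.  Every predicted pair must have been
#' tested — an untested prediction is an error, not a silent omission.
#' Absence of edges is data: pairs with both flags false stay in the table.
#'
#' @param predicted_edges tibble/data frame with columns `central`, `cancer`
#'   listing yeast-predicted pairs (may have zero rows).
#' @param calls tibble from [call_interactions()].
#' @return edge tibble `central`, `cancer`, `yeast_predicted`,
#'   `human_observed`, one row per tested pair.
#' @export
build_network <- function(predicted_edges, calls) {
  calls <- as_tibble(calls)
  predicted_edges <- as_tibble(predicted_edges)
  if (nrow(predicted_edges) > 0) {
    check_that(all(c("central", "cancer") %in% names(predicted_edges)),
               "predicted_edges needs columns central and cancer")
    tested <- paste(calls$central_gene, calls$cancer_gene)
    pred <- paste(predicted_edges$central, predicted_edges$cancer)
    untested <- setdiff(pred, tested)
    if (length(untested) > 0) {
      abort(paste("predicted pairs missing from calls:",
                  paste(untested, collapse = ", ")),
            class = "synlethnet_validation_error")
    }
    unknown <- unique(c(
      setdiff(predicted_edges$central, calls$central_gene),
      setdiff(predicted_edges$cancer, calls$cancer_gene)
    ))
    if (length(unknown) > 0) {
      warn(paste("unknown gene symbols in predicted edges:",
                 paste(unknown, collapse = ", ")))
    }
  } else {
    pred <- character(0)
  }
  tibble(
    central = calls$central_gene,
    cancer = calls$cancer_gene,
    yeast_predicted = paste(calls$central_gene, calls$cancer_gene) %in% pred,
    human_observed = calls$is_synthetic_lethal
  )
}

#' Conservation tallies of a bipartite interaction network
#'
#' Cross-tabulates the yeast-predicted and human-observed flags:
#' conserved (both), yeast-only, human-only, neither.  Percentages are of the
#' *predicted* edges, rounded half-up to integers, so 16 conserved of 22
#' predicted reports 73% conserved and 27% not conserved.  With no predicted
#' edges the percentages are undefined (`NA`) but the tallies are still
#' returned.
#'
#' @param edges edge tibble (`central`, `cancer`, `yeast_predicted`,
#'   `human_observed`), e.g. from [build_network()] or
#'   [make_network_fixture()].
#' @return one-row tibble: `n_pairs`, `n_predicted`, `n_conserved`,
#'   `n_yeast_only`, `n_human_only`, `pct_conserved`, `pct_not_conserved`.
#' @examples
#' conservation_summary(make_network_fixture())  # 73% conserved
#' @export
conservation_summary <- function(edges) {
  edges <- as_tibble(edges)
  check_that(all(c("yeast_predicted", "human_observed") %in% names(edges)),
             "edges needs logical columns yeast_predicted and human_observed")
  yp <- edges$yeast_predicted
  ho <- edges$human_observed
  n_predicted <- sum(yp)
  n_conserved <- sum(yp & ho)
  n_yeast_only <- sum(yp & !ho)
  if (n_predicted > 0) {
    pct_conserved <- round_half_up(100 * n_conserved / n_predicted)
    pct_not_conserved <- 100 - pct_conserved
  } else {
    pct_conserved <- NA_real_
    pct_not_conserved <- NA_real_
  }
  tibble(n_pairs = length(yp),
         n_predicted = n_predicted,
         n_conserved = n_conserved,
         n_yeast_only = n_yeast_only,
         n_human_only = sum(!yp & ho),
         pct_conserved = pct_conserved,
         pct_not_conserved = pct_not_conserved)
}

#' Rank central genes by interaction degree
#'
#' Degree of each central gene counted over edges carrying the chosen flag;
#' a gene connected to many cancer-mutated partners is a candidate
#' broad-spectrum target.  Ties are broken alphabetically.
#'
#' @param edges edge tibble as in [conservation_summary()].
#' @param by which flag defines an interaction: `"human_observed"` (default)
#'   or `"yeast_predicted"`.
#' @return tibble `central_gene`, `degree`, sorted by descending degree.
#' @export
rank_hubs <- function(edges, by = c("human_observed", "yeast_predicted")) {
  by <- match.arg(by)
  edges <- as_tibble(edges)
  flagged <- edges[edges[[by]], , drop = FALSE]
  degrees <- table(factor(flagged$central, levels = unique(edges$central)))
  out <- tibble(central_gene = names(degrees),
                degree = as.integer(degrees))
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$central_gene)
}
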