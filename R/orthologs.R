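#' Yeast-human ortholog alias table
#'
#' The budding-yeast genes of the chromosome-instability interaction network
#' and their human orthologs (protein-BLAST assignments; one row per
#' yeast-human pair, so one-to-many orthologs such as SCC3 to
#' STAG1/STAG2/STAG3 span several rows).  Human symbols are the canonical
#' naming throughout the package; this table translates yeast-labelled edge
#' lists.
#'
#' @return tibble with columns `yeast_gene`, `human_gene`.
#' @export
ortholog_table <- function() {
  path <- system.file("extdata", "yeast_human_orthologs.tsv",
                      package = "synlethnet", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    yeast_gene = readr::col_character(),
    human_gene = readr::col_character()
  ))
}

#' Translate yeast gene symbols to human orthologs
#'
#' Unknown symbols pass through unchanged with a warning rather than an
#' error, so partially translated edge lists remain usable.  A yeast gene
#' with several human orthologs translates to its first listed ortholog;
#' use [ortholog_table()] directly when the full mapping is needed.
#'
#' @param genes character vector of yeast gene symbols.
#' @return character vector of human symbols, same length.
#' @export
yeast_to_human <- function(genes) {
  tab <- ortholog_table()
  first <- tab[!duplicated(tab$yeast_gene), ]
  idx <- match(genes, first$yeast_gene)
  unknown <- unique(genes[is.na(idx)])
  if (length(unknown) > 0) {
    warn(paste("unknown yeast symbols passed through:",
               paste(unknown, collapse = ", ")))
  }
  ifelse(is.na(idx), genes, first$human_gene[idx])
}
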