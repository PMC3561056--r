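# Shared internal helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; conservation percentages are reported
#' with the conventional half-up rule (16/22 -> 73, 6/22 -> 27).
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop unless `cond` holds, naming the offending field
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "synlethnet_validation_error")
  invisible(TRUE)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index.
# Keeps every derived seed a valid R integer.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(stream)) %%
               .Machine$integer.max)
}

# Join gene symbols into the on-disk representation ("A;B"; "" for none).
join_genes <- function(genes) paste(genes, collapse = ";")

split_genes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

n_genes_targeted <- function(x) {
  ifelse(is.na(x) | !nzchar(x), 0L, lengths(strsplit(x, ";", fixed = TRUE)))
}
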