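#' Configure a simulated double-knockdown plate screen
#'
#' Builds and validates the configuration for [simulate_plate()].  The
#' generator is the generative inverse of the multiplicative scoring model:
#' the expected nuclei count of a double knockdown of genes A and B is
#' `baseline_count * v_A * v_B * (1 - epsilon_AB)`, where `v_A`, `v_B` are the
#' true single-knockdown viability fractions and `epsilon_AB` in \[0, 1\] is
#' the planted interaction strength (0 = no interaction, 1 = fully lethal
#' double).
#'
#' @param central_genes character vector of "central" (hub candidate) gene
#'   symbols.
#' @param cancer_genes character vector of cancer-mutated partner gene symbols.
#' @param single_viability named numeric vector mapping every central and
#'   cancer gene to its true single-knockdown viability fraction in \[0, 1\].
#' @param epsilon tibble/data frame with columns `central`, `cancer`,
#'   `epsilon` giving planted interaction strengths; pairs not listed default
#'   to 0.  `NULL` means no interactions anywhere.
#' @param control_gene symbol of the normalization control (default
#'   `"GAPDH"`); simulated with viability 1.
#' @param baseline_count expected nuclei per control well (positive).
#' @param noise_cv coefficient of variation of well counts (>= 0).  Counts are
#'   drawn from a lognormal law with exactly this CV, rounded to integer and
#'   floored at 0; `0` gives noiseless (rounded expected) counts.
#' @param wells_per_condition replicate wells per condition (>= 2, so that an
#'   SEM is always computable).
#' @param seed integer master seed; per-plate substreams are derived from it.
#' @return a `plate_sim_config` list, validated.
#' @seealso [simulate_plate()], [study_plate_config()]
#' @export
plate_sim_config <- function(central_genes,
                             cancer_genes,
                             single_viability,
                             epsilon = NULL,
                             control_gene = "GAPDH",
                             baseline_count = 1000,
                             noise_cv = 0.05,
                             wells_per_condition = 6L,
                             seed = 1L) {
  genes <- c(central_genes, cancer_genes)
  check_that(length(central_genes) >= 1 && length(cancer_genes) >= 1,
             "central_genes and cancer_genes must each be non-empty")
  check_that(!anyDuplicated(genes), "gene symbols must be unique across lists")
  check_that(!control_gene %in% genes,
             "control_gene must not appear among central/cancer genes")
  check_that(all(genes %in% names(single_viability)),
             paste("single_viability missing genes:",
                   paste(setdiff(genes, names(single_viability)), collapse = ", ")))
  v <- single_viability[genes]
  check_that(all(is.finite(v) & v >= 0 & v <= 1),
             "single_viability values must lie in [0, 1]")
  if (is.null(epsilon)) {
    epsilon <- tibble(central = character(0), cancer = character(0),
                      epsilon = numeric(0))
  }
  epsilon <- as_tibble(epsilon)
  check_that(all(c("central", "cancer", "epsilon") %in% names(epsilon)),
             "epsilon needs columns central, cancer, epsilon")
  check_that(all(epsilon$central %in% central_genes),
             "epsilon$central contains unknown central genes")
  check_that(all(epsilon$cancer %in% cancer_genes),
             "epsilon$cancer contains unknown cancer genes")
  check_that(all(epsilon$epsilon >= 0 & epsilon$epsilon <= 1),
             "epsilon values must lie in [0, 1]")
  check_that(!anyDuplicated(paste(epsilon$central, epsilon$cancer)),
             "epsilon pairs must be unique")
  check_that(is.numeric(baseline_count) && baseline_count > 0,
             "baseline_count must be > 0")
  check_that(is.numeric(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  check_that(wells_per_condition >= 2, "wells_per_condition must be >= 2")
  check_that(is.numeric(seed) && is.finite(seed), "seed must be an integer")

  structure(list(central_genes = central_genes,
                 cancer_genes = cancer_genes,
                 control_gene = control_gene,
                 single_viability = v,
                 epsilon = epsilon,
                 baseline_count = baseline_count,
                 noise_cv = noise_cv,
                 wells_per_condition = as.integer(wells_per_condition),
                 seed = as.integer(seed)),
            class = "plate_sim_config")
}

#' Default configuration emulating the study's 3 x 10 test matrix
#'
#' Three central genes (WDHD1, FEN1, CHTF8) crossed against ten cancer-mutated
#' chromosome-instability genes, single-knockdown viabilities drawn uniformly
#' in \[0.6, 0.9\], 6 wells per condition and 5% well-to-well CV.  Interaction
#' strengths are supplied by the caller; by default none are planted.
#'
#' @param epsilon planted interactions, as in [plate_sim_config()].
#' @param seed master seed (also used to draw the single viabilities).
#' @param noise_cv,wells_per_condition overrides of the default noise model.
#' @return a `plate_sim_config`.
#' @export
study_plate_config <- function(epsilon = NULL, seed = 1L,
                               noise_cv = 0.05, wells_per_condition = 6L) {
  central <- c("WDHD1", "FEN1", "CHTF8")
  cancer <- c("SMC1A", "SMC3", "NIPBL", "STAG1", "STAG2", "STAG3",
              "RNF20", "FBXW7", "MRE11A", "RAD54B")
  genes <- c(central, cancer)
  v <- withr::with_seed(derive_seed(seed, 1L),
                        setNames(runif(length(genes), 0.6, 0.9), genes))
  plate_sim_config(central_genes = central, cancer_genes = cancer,
                   single_viability = v, epsilon = epsilon,
                   noise_cv = noise_cv,
                   wells_per_condition = wells_per_condition, seed = seed)
}

# Expected (noiseless) count for every condition of a config, one row each.
condition_table <- function(config) {
  v <- config$single_viability
  singles <- tibble(
    condition_id = names(v),
    genes_targeted = names(v),
    expected = config$baseline_count * unname(v)
  )
  doubles <- tidyr::expand_grid(central = config$central_genes,
                                cancer = config$cancer_genes)
  doubles <- dplyr::left_join(doubles, config$epsilon,
                              by = c("central", "cancer"))
  doubles$epsilon[is.na(doubles$epsilon)] <- 0
  doubles <- tibble(
    condition_id = paste0(doubles$central, "+", doubles$cancer),
    genes_targeted = paste0(doubles$central, ";", doubles$cancer),
    expected = config$baseline_count * unname(v[doubles$central]) *
      unname(v[doubles$cancer]) * (1 - doubles$epsilon)
  )
  controls <- tibble(
    condition_id = c(config$control_gene, "NS"),
    genes_targeted = c(config$control_gene, ""),
    expected = config$baseline_count
  )
  dplyr::bind_rows(controls, singles, doubles)
}

#' Simulate a double-knockdown siRNA plate screen
#'
#' Emits `wells_per_condition` replicate wells for the control, the
#' non-silencing condition, every single knockdown and every central x cancer
#' double knockdown.  Counts follow a lognormal law with mean equal to the
#' multiplicative-model expectation and the configured CV, rounded to integer
#' nuclei and floored at zero.  Wells are laid out across consecutive 96-well
#' plates; the RNG substream of each plate is derived from the master seed, so
#' output is a pure function of the config.
#'
#' @param config a [plate_sim_config()].
#' @return tibble with columns `plate_id`, `well_id`, `condition_id`,
#'   `genes_targeted` (semicolon-joined, `""` for non-silencing),
#'   `nuclei_count`.
#' @examples
#' cfg <- plate_sim_config(
#'   central_genes = "FEN1", cancer_genes = "FBXW7",
#'   single_viability = c(FEN1 = 0.8, FBXW7 = 0.7),
#'   noise_cv = 0, wells_per_condition = 2, baseline_count = 1000
#' )
#' simulate_plate(cfg)
#' @export
simulate_plate <- function(config) {
  check_that(inherits(config, "plate_sim_config"),
             "config must be built with plate_sim_config()")
  conds <- condition_table(config)
  n_rep <- config$wells_per_condition
  wells <- tidyr::uncount(conds, weights = n_rep)

  # 96-well layout: rows A-H x columns 1-12, spilling onto further plates
  idx <- seq_len(nrow(wells)) - 1L
  plate_no <- idx %/% 96L + 1L
  pos <- idx %% 96L
  wells$plate_id <- sprintf("P%02d", plate_no)
  wells$well_id <- paste0(LETTERS[pos %/% 12L + 1L],
                          sprintf("%02d", pos %% 12L + 1L))

  wells$nuclei_count <- NA_real_
  for (p in unique(plate_no)) {
    sel <- plate_no == p
    mu <- wells$expected[sel]
    wells$nuclei_count[sel] <- withr::with_seed(
      derive_seed(config$seed, p + 1L),
      draw_counts(mu, config$noise_cv)
    )
  }
  wells$nuclei_count <- as.integer(pmax(0, round(wells$nuclei_count)))
  wells[, c("plate_id", "well_id", "condition_id", "genes_targeted",
            "nuclei_count")]
}

# Lognormal draw with mean mu and coefficient of variation cv (exact moments).
draw_counts <- function(mu, cv) {
  if (cv == 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  out <- numeric(length(mu))
  pos <- mu > 0
  out[pos] <- rlnorm(sum(pos), meanlog = log(mu[pos]) - sdlog^2 / 2,
                     sdlog = sdlog)
  out
}
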