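fake_calls <- function(central, cancer, lethal) {
  tibble::tibble(experiment_id = "e1", central_gene = central,
                 cancer_gene = cancer, v_central = 80, v_cancer = 70,
                 v_obs = 50, v_pred = 56, defect = 6, threshold = 5,
                 is_synthetic_lethal = lethal)
}

test_that("build_network combines predictions and calls into flagged edges", {
  grid <- tidyr::expand_grid(central = c("X", "Y", "Z"),
                             cancer = paste0("g", 1:10))
  calls <- fake_calls(grid$central, grid$cancer,
                      lethal = rep(c(TRUE, FALSE), 15))
  predicted <- grid[1:22, ]
  edges <- build_network(predicted, calls)
  expect_equal(nrow(edges), 30)
  expect_equal(sum(edges$yeast_predicted), 22)
  expect_equal(edges$human_observed, calls$is_synthetic_lethal)

  # no predictions, no calls positive: all-false edge table
  none <- build_network(tibble::tibble(central = character(0),
                                       cancer = character(0)),
                        fake_calls(grid$central, grid$cancer, FALSE))
  expect_false(any(none$yeast_predicted) || any(none$human_observed))

  # an observed but unpredicted pair is a human-only edge
  one <- build_network(tibble::tibble(central = "X", cancer = "g1"),
                       fake_calls(c("X", "X"), c("g1", "g2"),
                                  c(TRUE, TRUE)))
  s <- conservation_summary(one)
  expect_equal(s$n_human_only, 1)
  expect_equal(s$n_conserved, 1)

  # predicted pair never tested is an error listing it
  expect_error(
    build_network(tibble::tibble(central = "X", cancer = "g99"),
                  fake_calls("X", "g1", TRUE)),
    "g99"
  )
})

test_that("conservation percentages use half-up integer rounding of predicted", {
  edges <- make_network_fixture(3, 10, 22, 16, 1, seed = 1L)
  s <- conservation_summary(edges)
  expect_equal(s$n_pairs, 30)
  expect_equal(s$pct_conserved, 73)      # 16/22
  expect_equal(s$pct_not_conserved, 27)  # 6/22
  expect_equal(s$n_conserved + s$n_yeast_only, s$n_predicted)

  blank <- conservation_summary(
    tibble::tibble(central = "a", cancer = letters[1:30],
                   yeast_predicted = FALSE, human_observed = FALSE)
  )
  expect_equal(blank$n_pairs, 30)
  expect_true(is.na(blank$pct_conserved) && is.na(blank$pct_not_conserved))
})

test_that("conservation classes partition the edge set", {
  for (seed in 1:10) {
    edges <- make_network_fixture(3, 10, sample(0:30, 1), 0, 0, seed = seed)
    s <- conservation_summary(edges)
    n_neither <- s$n_pairs - s$n_conserved - s$n_yeast_only - s$n_human_only
    expect_equal(s$n_conserved + s$n_yeast_only + s$n_human_only + n_neither,
                 s$n_pairs)
  }
})

test_that("hub ranking sorts by degree with alphabetical tie-break", {
  edges <- tibble::tibble(
    central = rep(c("WDHD1", "FEN1", "CHTF8"), each = 10),
    cancer = rep(paste0("g", 1:10), 3),
    yeast_predicted = FALSE,
    human_observed = c(rep(TRUE, 5), rep(FALSE, 5),    # WDHD1: 5
                       rep(TRUE, 7), rep(FALSE, 3),    # FEN1: 7
                       rep(TRUE, 4), rep(FALSE, 6))    # CHTF8: 4
  )
  ranks <- rank_hubs(edges)
  expect_equal(ranks$central_gene, c("FEN1", "WDHD1", "CHTF8"))
  expect_equal(ranks$degree, c(7L, 5L, 4L))
  # handshake: degrees sum to the flagged edge count
  expect_equal(sum(ranks$degree), sum(edges$human_observed))

  # no flagged edges: all zero, alphabetical
  edges$human_observed <- FALSE
  ranks0 <- rank_hubs(edges)
  expect_equal(ranks0$central_gene, c("CHTF8", "FEN1", "WDHD1"))
  expect_equal(ranks0$degree, rep(0L, 3))
})

test_that("edges round-trip through TSV and SIF with identical summaries", {
  edges <- make_network_fixture(3, 10, 22, 16, 1, seed = 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(edges, path)
  expect_equal(conservation_summary(read_edges_tsv(path)),
               conservation_summary(edges))

  dir <- withr::local_tempdir()
  paths <- write_edges_sif(edges, dir)
  conserved <- readLines(file.path(dir, "conserved.sif"))
  expect_length(conserved, 16)
  expect_match(conserved, "\tsl\t")
  expect_length(readLines(file.path(dir, "yeast_only.sif")), 6)
  expect_length(readLines(file.path(dir, "human_only.sif")), 1)
})

test_that("yeast symbols translate to canonical human orthologs", {
  expect_equal(yeast_to_human(c("RAD27", "CTF4", "SMC3")),
               c("FEN1", "WDHD1", "SMC3"))
  # one-to-many orthologs keep all rows in the table itself
  tab <- ortholog_table()
  expect_setequal(tab$human_gene[tab$yeast_gene == "SCC3"],
                  c("STAG1", "STAG2", "STAG3"))
  expect_warning(out <- yeast_to_human(c("RAD27", "NOTAGENE")), "NOTAGENE")
  expect_equal(out, c("FEN1", "NOTAGENE"))
})
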