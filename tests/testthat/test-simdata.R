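test_that("noiseless double-knockdown counts follow the multiplicative model", {
  wells <- simulate_plate(tiny_config())
  dbl <- wells$nuclei_count[wells$condition_id == "A+B"]
  expect_equal(dbl, rep(560L, 2))  # 1000 * 0.8 * 0.7
  expect_equal(wells$nuclei_count[wells$condition_id == "A"], rep(800L, 2))
  expect_equal(wells$nuclei_count[wells$condition_id == "GAPDH"], rep(1000L, 2))
  # non-silencing control is emitted alongside the silenced control
  expect_equal(wells$genes_targeted[wells$condition_id == "NS"], rep("", 2))
})

test_that("full interaction strength drives the double to zero", {
  eps <- tibble::tibble(central = "A", cancer = "B", epsilon = 1)
  wells <- simulate_plate(tiny_config(epsilon = eps, noise_cv = 0.1))
  expect_equal(wells$nuclei_count[wells$condition_id == "A+B"], rep(0L, 2))
})

test_that("identical config and seed give byte-identical well tables", {
  cfg <- study_plate_config(seed = 7L)
  expect_identical(simulate_plate(cfg), simulate_plate(cfg))
  # a different seed must actually change the draws
  cfg2 <- study_plate_config(seed = 8L)
  expect_false(identical(simulate_plate(cfg), simulate_plate(cfg2)))
})

test_that("generator is calibrated: control mean within 3 true SEM of baseline", {
  # true SEM of the configured noise law: cv * baseline / sqrt(n); the
  # estimated-SEM version is a 5-df t statistic with only ~97% coverage
  true_sem <- 0.05 * 1000 / sqrt(6)
  hits <- vapply(1:1000, function(s) {
    cfg <- tiny_config(noise_cv = 0.05, seed = s, wells_per_condition = 6L)
    ctrl <- simulate_plate(cfg)$nuclei_count[1:6]
    abs(mean(ctrl) - 1000) <= 3 * true_sem
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("empirical double-knockdown mean recovers v_a * v_b * (1 - eps)", {
  eps <- tibble::tibble(central = "A", cancer = "B", epsilon = 0.4)
  cfg <- plate_sim_config(
    central_genes = "A", cancer_genes = "B",
    single_viability = c(A = 0.8, B = 0.7), epsilon = eps,
    baseline_count = 1000, noise_cv = 0.1,
    wells_per_condition = 10000L, seed = 3L
  )
  wells <- simulate_plate(cfg)
  dbl <- wells$nuclei_count[wells$condition_id == "A+B"]
  expect_equal(mean(dbl), 1000 * 0.8 * 0.7 * 0.6, tolerance = 0.01)
})

test_that("invalid plate configs are rejected with the offending field named", {
  expect_error(plate_sim_config("A", "B", c(A = 1.2, B = 0.5)),
               "single_viability")
  expect_error(plate_sim_config("A", "B", c(A = 0.5)), "missing genes")
  expect_error(tiny_config(wells_per_condition = 1L), "wells_per_condition")
  expect_error(plate_sim_config("A", "B", c(A = 0.5, B = 0.5),
                                baseline_count = 0), "baseline_count")
  expect_error(plate_sim_config("A", "B", c(A = 0.5, B = 0.5),
                                epsilon = data.frame(central = "A",
                                                     cancer = "B",
                                                     epsilon = 2)),
               "epsilon")
})

test_that("kinetic traces follow first-order kinetics with logistic dose law", {
  cfg <- kinetic_sim_config(
    tibble::tibble(compound_id = "cpd", true_ic50 = 1e-6, hill = 1,
                   is_fluorescent_artifact = FALSE),
    f_max = 1000, k_uninhibited = 0.2, baseline = 0,
    read_times = c(0, 5, 10), noise_sd = 0
  )
  traces <- simulate_kinetic_screen(cfg, c(0, 1e-6))
  # vehicle: k_eff = k, closed form at t = 5: 1000 * (1 - exp(-1))
  veh5 <- traces$rfu[traces$conc_M == 0 & traces$time_min == 5]
  expect_equal(veh5, 1000 * (1 - exp(-1)), tolerance = 1e-12)
  # at C = IC50 with hill 1 the rate halves
  half5 <- traces$rfu[traces$conc_M == 1e-6 & traces$time_min == 5]
  expect_equal(half5, 1000 * (1 - exp(-0.1 * 5)), tolerance = 1e-12)
  expect_error(simulate_kinetic_screen(cfg, numeric(0)), "concentrations")
  expect_error(
    kinetic_sim_config(cfg$compounds, read_times = numeric(0)),
    "read_times"
  )
})

test_that("kinetic generation is a pure function of the seed", {
  cfg <- kinetic_sim_config(
    tibble::tibble(compound_id = c("a", "b"), true_ic50 = c(1e-6, 1e-7),
                   hill = 1, is_fluorescent_artifact = c(FALSE, TRUE)),
    noise_sd = 5, seed = 11L
  )
  expect_identical(simulate_kinetic_screen(cfg, c(0, 1e-6)),
                   simulate_kinetic_screen(cfg, c(0, 1e-6)))
})

test_that("network fixtures honour requested tallies exactly", {
  edges <- make_network_fixture(3, 10, 22, 16, 1, seed = 5L)
  expect_equal(nrow(edges), 30)
  expect_equal(sum(edges$yeast_predicted), 22)
  expect_equal(sum(edges$yeast_predicted & edges$human_observed), 16)
  expect_equal(sum(!edges$yeast_predicted & edges$human_observed), 1)

  single <- make_network_fixture(1, 1, 0, 0, 0)
  expect_equal(nrow(single), 1)
  expect_false(any(single$yeast_predicted) || any(single$human_observed))

  full <- make_network_fixture(2, 2, 4, 4, 0)
  expect_true(all(full$yeast_predicted & full$human_observed))

  expect_error(make_network_fixture(2, 2, 5, 0, 0), "n_yeast_predicted")
  expect_error(make_network_fixture(2, 2, 3, 4, 0), "n_conserved")
  expect_error(make_network_fixture(2, 2, 3, 1, 2), "n_human_only")
})

test_that("fixture tallies are exact across random feasible specs", {
  set.seed(42)
  for (i in 1:25) {
    n_c <- sample(1:4, 1)
    n_k <- sample(1:8, 1)
    n_pairs <- n_c * n_k
    n_pred <- sample(0:n_pairs, 1)
    n_cons <- sample(0:n_pred, 1)
    n_ho <- sample(0:(n_pairs - n_pred), 1)
    edges <- make_network_fixture(n_c, n_k, n_pred, n_cons, n_ho, seed = i)
    s <- conservation_summary(edges)
    expect_equal(s$n_pairs, n_pairs)
    expect_equal(s$n_predicted, n_pred)
    expect_equal(s$n_conserved, n_cons)
    expect_equal(s$n_human_only, n_ho)
  }
})
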