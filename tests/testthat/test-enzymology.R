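test_that("initial rate is the OLS slope with r-squared reported", {
  r <- initial_rate(tibble::tibble(time_min = 0:2, rfu = c(0, 10, 20)))
  expect_equal(r$slope, 10)
  expect_equal(r$r_squared, 1)

  flat <- initial_rate(tibble::tibble(time_min = 0:5, rfu = rep(7, 6)))
  expect_equal(flat$slope, 0)

  expect_error(initial_rate(tibble::tibble(time_min = 0:1, rfu = 0:1)),
               "3 points")
  expect_error(initial_rate(tibble::tibble(time_min = rep(1, 3), rfu = 1:3)),
               "time variance")
})

test_that("slope of a gently curved trace approximates the initial tangent", {
  # k = 0.05/min over 0-10 min: tangent k * f_max = 50 RFU/min
  cfg <- kinetic_sim_config(
    tibble::tibble(compound_id = "v", true_ic50 = 1, hill = 1,
                   is_fluorescent_artifact = FALSE),
    f_max = 1000, k_uninhibited = 0.05, baseline = 0,
    read_times = seq(0, 10, 0.5), noise_sd = 0
  )
  tr <- simulate_kinetic_screen(cfg, 0)
  r <- initial_rate(tr)
  # closed-form OLS slope of 1000 * (1 - exp(-0.05 t)) over these reads
  t <- seq(0, 10, 0.5)
  oracle_slope <- unname(coef(lm(1000 * (1 - exp(-0.05 * t)) ~ t))[2])
  expect_equal(r$slope, oracle_slope, tolerance = 1e-10)
  # full-window curvature drags the slope ~20% under the tangent; a short
  # window recovers the tangent to within 15%
  r_short <- initial_rate(tr, window_fraction = 0.3)
  expect_equal(r_short$slope, 50, tolerance = 0.15)
  expect_lt(abs(r_short$slope - 50), abs(r$slope - 50))
})

test_that("percent inhibition is the slope ratio complement, capped at 100", {
  expect_equal(percent_inhibition(0, 50), 100)
  expect_equal(percent_inhibition(50, 50), 0)
  expect_equal(percent_inhibition(25, 50), 50)
  expect_equal(percent_inhibition(-2, 50), 100)   # capped
  expect_equal(percent_inhibition(75, 50), -50)   # activation, unclamped
  expect_error(percent_inhibition(10, 0), "degenerate vehicle")

  # antitone in slope for fixed vehicle
  slopes <- seq(0, 60, by = 5)
  expect_false(is.unsorted(rev(percent_inhibition(slopes, 50))))
})

test_that("noiseless 4PL data are recovered to machine-level accuracy", {
  conc <- 10^seq(-8, -4, by = 0.5)
  act <- 0 + (100 - 0) / (1 + (conc / 1e-6)^1)
  fit <- fit_ic50(conc, act)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1e-6, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  expect_equal(abs(fit$bottom), 0, tolerance = 1e-3)
})

test_that("IC50 fit is equivariant under concentration rescaling", {
  conc <- 10^seq(-8, -4, by = 0.5)
  act <- 5 + 90 / (1 + (conc / 5e-7)^1.3)
  fit_m <- fit_ic50(conc, act)
  fit_um <- fit_ic50(conc * 1e6, act)  # same doses in micromolar
  expect_equal(fit_um$ic50, fit_m$ic50 * 1e6, tolerance = 1e-6)
  expect_equal(fit_um$hill, fit_m$hill, tolerance = 1e-6)
})

test_that("flat responses are flagged instead of yielding a spurious IC50", {
  conc <- 10^seq(-8, -4, by = 0.5)
  fit <- fit_ic50(conc, rep(100, length(conc)))
  expect_true(!fit$converged || !fit$ic50_in_range)
  expect_error(fit_ic50(c(1e-6, 2e-6, 3e-6), c(90, 50, 10)), "4 distinct")
  expect_error(fit_ic50(c(-1e-6, 1e-6, 2e-6, 4e-6), c(99, 90, 50, 10)),
               "positive")
})

test_that("tidy, glance and autoplot expose the 4PL fit", {
  conc <- 10^seq(-8, -4, by = 0.5)
  fit <- fit_ic50(conc, 100 / (1 + conc / 1e-6))
  td <- tidy(fit)
  expect_equal(td$term, c("bottom", "top", "ic50", "hill"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, length(conc))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("counterscreen removes hits whose inhibition persists", {
  res <- counterscreen_filter(
    c("a", "b"),
    c(a = 75, b = 5)
  )
  expect_equal(res$retained, c(FALSE, TRUE))
  expect_error(counterscreen_filter(c("a", "zz"), c(a = 10)), "zz")
})

test_that("counterscreen identifies exactly the planted artifact compounds", {
  cfg <- kinetic_sim_config(
    tibble::tibble(
      compound_id = paste0("c", 1:6),
      true_ic50 = c(1e-6, 5e-7, 2e-6, 1e-6, 3e-6, 1),
      hill = 1,
      is_fluorescent_artifact = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
    ),
    noise_sd = 0, seed = 2L
  )
  cs <- simulate_counterscreen(cfg, 1e-5)
  res <- counterscreen_filter(cfg$compounds$compound_id, cs)
  expect_equal(!res$retained, cfg$compounds$is_fluorescent_artifact)
})

test_that("rule-of-five triage enumerates violations with stated boundaries", {
  d <- tibble::tibble(
    compound_id = c("ok", "heavy", "greasy", "sticky", "boundary"),
    mw = c(300, 650, 400, 400, 499.9),
    clogp = c(2, 2, 6.5, 2, 5.0),
    hbd = c(2, 2, 2, 6, 5),
    hba = c(4, 4, 4, 11, 10)
  )
  res <- lipinski_filter(d)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$violations[2], "mw")
  expect_equal(res$violations[3], "clogp")
  expect_equal(res$violations[4], "hbd;hba")
  expect_equal(res$violations[5], "")  # <500 strict, <= elsewhere
  expect_error(lipinski_filter(d[, -2]), "needs columns")
  d$mw[1] <- NA
  expect_error(lipinski_filter(d), "missing")
})

test_that("selectivity test wraps one-way ANOVA with Tukey HSD", {
  # near-identical groups: tiny F, no significant pairs
  d0 <- tibble::tibble(genotype = rep(c("WT", "KO"), each = 6),
                       viability = rep(100, 12) +
                         withr::with_seed(1, rnorm(12, 0, 0.1)))
  t0 <- selectivity_test(d0)
  expect_lt(glance(t0)$f_statistic, 4)
  expect_true(all(tidy(t0)$adj_p_value > 0.05))

  # widely separated constant-ish groups flag the pair
  d1 <- tibble::tibble(genotype = rep(c("WT", "KO"), each = 10),
                       viability = c(rep(100, 10), rep(50, 10)) +
                         withr::with_seed(2, rnorm(20, 0, 0.5)))
  expect_lt(tidy(selectivity_test(d1))$adj_p_value, 0.001)

  # three groups, one shifted: only pairs involving the shifted group flagged
  d2 <- tibble::tibble(genotype = rep(c("A", "B", "C"), each = 8),
                       viability = c(rep(100, 16), rep(40, 8)) +
                         withr::with_seed(3, rnorm(24, 0, 2)))
  t2 <- tidy(selectivity_test(d2))
  hit <- t2$adj_p_value < 0.05
  expect_equal(sort(t2$comparison[hit]), c("C-A", "C-B"))
  expect_error(selectivity_test(d2[1:8, ]), "2 genotypes")
})
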