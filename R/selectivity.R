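#' Genotype-selectivity test: one-way ANOVA with Tukey's HSD
#'
#' Compares cell viability across genotypes (e.g. CDC4 wild type vs knockout
#' under compound treatment) with a one-way ANOVA followed by Tukey's honest
#' significant difference test — the standard analysis for multi-genotype
#' proliferation comparisons.  A thin wrapper over [stats::aov()] and
#' [stats::TukeyHSD()].
#'
#' @param data data frame of replicate measurements.
#' @param viability column (bare name) holding the response.
#' @param genotype column (bare name) holding the group label.
#' @return object of class `selectivity_test` with the ANOVA F statistic and
#'   p-value and the Tukey pairwise table; `tidy()` returns the pairwise
#'   comparisons, `glance()` the omnibus test.
#' @examples
#' d <- data.frame(genotype = rep(c("WT", "KO"), each = 6),
#'                 viability = c(rnorm(6, 100, 3), rnorm(6, 60, 3)))
#' tidy(selectivity_test(d, viability, genotype))
#' @export
selectivity_test <- function(data, viability = viability, genotype = genotype) {
  data <- as_tibble(data)
  y <- dplyr::pull(data, {{ viability }})
  g <- factor(dplyr::pull(data, {{ genotype }}))
  check_that(nlevels(g) >= 2, "need at least 2 genotypes")
  check_that(all(table(g) >= 2), "need at least 2 replicates per genotype")
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  pairs <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"]
  )
  structure(list(f_statistic = tab[["F value"]][1L],
                 p_value = tab[["Pr(>F)"]][1L],
                 df_between = tab[["Df"]][1L],
                 df_within = tab[["Df"]][2L],
                 pairwise = pairs,
                 fit = fit),
            class = "selectivity_test")
}

#' @export
print.selectivity_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn selectivity_test Tukey pairwise comparisons, one row each.
#' @param x a `selectivity_test`.
#' @param ... unused.
#' @export
tidy.selectivity_test <- function(x, ...) x$pairwise

#' @describeIn selectivity_test one-row omnibus ANOVA summary.
#' @export
glance.selectivity_test <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df_between, df_within = x$df_within)
}
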