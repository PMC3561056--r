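#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Least-squares fit of
#' `activity = bottom + (top - bottom) / (1 + (C / IC50)^hill)` by
#' Levenberg-Marquardt, with the IC50 parameterised on the log10 scale so the
#' fit is invariant to concentration-unit rescaling.  The bottom plateau is
#' constrained to >= -10% activity so read noise cannot drag it to absurd
#' values.  Poor fits set `converged = FALSE` rather than raising — including
#' fits whose estimated dynamic range (`top - bottom`) is under 10 percentage
#' points, where no IC50 is identifiable; an IC50
#' landing outside the tested dose range is flagged via `ic50_in_range`
#' (typical of inactive, flat-response compounds).
#'
#' @param concentrations molar doses (> 0; at least 4 distinct values).
#' @param pct_activity percent remaining activity at each dose (100 =
#'   uninhibited).
#' @return an object of class `dose_response_fit`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods, and [autoplot.dose_response_fit()].
#' @examples
#' conc <- 10^seq(-8, -4.5, by = 0.5)
#' act <- 100 / (1 + (conc / 1e-6))
#' fit <- fit_ic50(conc, act)
#' glance(fit)
#' @export
fit_ic50 <- function(concentrations, pct_activity) {
  check_that(length(concentrations) == length(pct_activity),
             "concentrations and pct_activity must have equal length")
  check_that(all(concentrations > 0), "concentrations must be positive")
  check_that(length(unique(concentrations)) >= 4,
             "need at least 4 distinct concentrations")
  dat <- tibble(conc = as.numeric(concentrations),
                activity = as.numeric(pct_activity))

  # starting values: plateaus from the data extremes, IC50 from the dose
  # closest to half-maximal response
  top0 <- max(dat$activity)
  bottom0 <- max(min(dat$activity), -10)
  half <- (top0 + bottom0) / 2
  lic0 <- log10(dat$conc[which.min(abs(dat$activity - half))])

  lconc <- log10(dat$conc)
  predict_4pl <- function(p) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["hill"]] * (lconc - p[["lic50"]])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(bottom = bottom0, top = top0, lic50 = lic0, hill = 1),
      lower = c(bottom = -10, top = -10, lic50 = -30, hill = 1e-3),
      upper = c(bottom = Inf, top = Inf, lic50 = 10, hill = 20),
      fn = function(p) dat$activity - predict_4pl(p),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    pars <- c(bottom = NA_real_, top = NA_real_, lic50 = NA_real_,
              hill = NA_real_)
    rss <- NA_real_
    converged <- FALSE
    fitted_vals <- rep(NA_real_, nrow(dat))
  } else {
    pars <- fit$par
    rss <- fit$deviance
    # info 1-3: converged on ftol/ptol; 4: residual orthogonal to jacobian.
    # A dynamic range under 10 percentage points means the IC50 is
    # unidentifiable (flat response), reported as non-convergence.
    converged <- fit$info %in% 1:4 && all(is.finite(pars)) &&
      (pars[["top"]] - pars[["bottom"]]) > 10
    fitted_vals <- predict_4pl(pars)
  }
  ic50 <- unname(10^pars["lic50"])
  structure(
    list(ic50 = ic50,
         hill = unname(pars["hill"]),
         top = unname(pars["top"]),
         bottom = unname(pars["bottom"]),
         rss = rss,
         converged = converged,
         ic50_in_range = isTRUE(ic50 >= min(dat$conc) &
                                  ic50 <= max(dat$conc)),
         n = nrow(dat),
         data = dplyr::mutate(dat, fitted = fitted_vals),
         fit = fit),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  if (x$converged) {
    cat(sprintf("  IC50: %.4g M  (hill %.3g, top %.4g, bottom %.4g)\n",
                x$ic50, x$hill, x$top, x$bottom))
    if (!x$ic50_in_range) cat("  note: IC50 outside tested dose range\n")
  } else {
    cat("  fit did not converge\n")
  }
  invisible(x)
}

#' @describeIn fit_ic50 one row per 4PL parameter (`term`, `estimate`).
#' @param x a `dose_response_fit`.
#' @param ... unused.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "ic50", "hill"),
         estimate = c(x$bottom, x$top, x$ic50, x$hill))
}

#' @describeIn fit_ic50 one-row fit summary (`ic50`, `hill`, `top`, `bottom`,
#'   `rss`, `converged`, `ic50_in_range`, `n`).
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
         rss = x$rss, converged = x$converged,
         ic50_in_range = x$ic50_in_range, n = x$n)
}

#' Plot a fitted dose-response curve
#'
#' Observed percent activity against log10 concentration with the fitted 4PL
#' curve and the IC50 marked.
#'
#' @param object a [fit_ic50()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$conc, y = .data$activity)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "activity (% of vehicle)")
  if (object$converged) {
    grid <- tibble(conc = 10^seq(log10(min(dat$conc)), log10(max(dat$conc)),
                                 length.out = 200))
    grid$activity <- object$bottom + (object$top - object$bottom) /
      (1 + (grid$conc / object$ic50)^object$hill)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                          colour = "grey40")
  }
  p
}
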