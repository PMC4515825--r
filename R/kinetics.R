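#' Fractional activity under hyperbolic inhibition
#'
#' The full-inhibition hyperbola `Y = Ki_app / (Ki_app + I)`: fractional
#' activity Y (rate with inhibitor over uninhibited rate) as a function of
#' inhibitor concentration at fixed, quasi-saturating substrate
#' concentrations. Y(0) = 1 and Y(Ki_app) = 1/2 exactly. An optional
#' partial-inhibition floor `f` gives `Y = (1 - f) Ki/(Ki + I) + f`.
#'
#' @param I Inhibitor concentration(s), mM; non-negative.
#' @param Ki_app Apparent inhibition constant, mM; positive.
#' @param floor Residual activity fraction at saturating inhibitor
#'   (default 0, full inhibition).
#' @return Fractional activity in (0, 1].
#' @export
fractional_activity <- function(I, Ki_app, floor = 0) {
  if (any(I < 0) || any(is.na(I))) {
    tt_abort("Inhibitor concentrations must be non-negative.", "domain_error")
  }
  if (!is.numeric(Ki_app) || Ki_app <= 0) {
    tt_abort("`Ki_app` must be positive.", "domain_error")
  }
  if (floor < 0 || floor >= 1) {
    tt_abort("`floor` must lie in [0, 1).", "domain_error")
  }
  (1 - floor) * Ki_app / (Ki_app + I) + floor
}

#' Fit the hyperbolic inhibition curve
#'
#' Least-squares estimate of the apparent inhibition constant from
#' (inhibitor concentration, fractional activity) pairs, the analysis used
#' for inhibitor titrations at quasi-saturating substrates.
#'
#' @param data Data frame with columns `I` (mM) and `Y` (fractional
#'   activity); at least 3 distinct inhibitor levels.
#' @param partial Fit the partial-inhibition variant with a free floor
#'   term (default `FALSE`, full inhibition).
#' @return A `hyperbolic_fit`: `Ki_app` (mM), its standard error, residual
#'   sigma, `floor` estimate, `n_points`, and the underlying `nls` fit.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' d <- tibble::tibble(I = c(1, 2.5, 5, 9, 15, 30))
#' d$Y <- fractional_activity(d$I, 6.6)
#' fit_hyperbolic(d)
#' @export
fit_hyperbolic <- function(data, partial = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("I", "Y") %in% names(data))) {
    tt_abort("`data` needs columns I and Y.", "fit_error")
  }
  if (dplyr::n_distinct(data$I) < 3L) {
    tt_abort("At least 3 distinct inhibitor levels are required.", "fit_error")
  }
  if (any(data$Y <= 0) || any(data$Y > 1.5)) {
    tt_abort("Fractional activities must lie in (0, 1.5].", "domain_error")
  }
  if (any(data$I < 0)) {
    tt_abort("Inhibitor concentrations must be non-negative.", "domain_error")
  }
  inhibited <- data$I > 0 & data$Y < 1
  if (max(1 - data$Y[data$I > 0], 0) < 0.02) {
    tt_abort(
      "No inhibition detected: fractional activity is flat near 1.",
      "no_inhibition"
    )
  }
  ki0 <- stats::median(data$I[inhibited] * data$Y[inhibited] / (1 - data$Y[inhibited]))
  if (!is.finite(ki0) || ki0 <= 0) ki0 <- stats::median(data$I[data$I > 0])
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 500)
  fit <- tryCatch(
    if (partial) {
      minpack.lm::nlsLM(
        Y ~ (1 - f) * Ki / (Ki + I) + f,
        data = data,
        start = list(Ki = ki0, f = 0.05),
        lower = c(1e-9, 0), upper = c(Inf, 0.999),
        control = ctrl
      )
    } else {
      minpack.lm::nlsLM(
        Y ~ Ki / (Ki + I),
        data = data,
        start = list(Ki = ki0),
        lower = 1e-9,
        control = ctrl
      )
    },
    error = function(e) {
      tt_abort(
        paste0("Hyperbolic fit did not converge: ", conditionMessage(e)),
        "fit_error"
      )
    }
  )
  est <- coef(fit)
  if (est[["Ki"]] > 1e4 * max(data$I)) {
    tt_abort(
      "No inhibition detected: fitted Ki is unbounded relative to the I range.",
      "no_inhibition"
    )
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"], error = function(e) NA_real_)
  structure(
    list(
      Ki_app = unname(est[["Ki"]]),
      se = unname(if (is.null(names(se))) se[1] else se[["Ki"]]),
      floor = if (partial) unname(est[["f"]]) else 0,
      sigma = summary(fit)$sigma,
      n_points = nrow(data),
      fit = fit
    ),
    class = "hyperbolic_fit"
  )
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(
    sprintf(
      "<hyperbolic_fit> Ki_app = %.4g mM (se %.2g), n = %d\n",
      x$Ki_app, x$se, x$n_points
    )
  )
  invisible(x)
}

mechanisms <- function() c("competitive", "uncompetitive", "non-competitive", "mixed")

#' Initial rate under a reversible-inhibition rate law
#'
#' The four textbook single-substrate laws, each reducing to
#' Michaelis-Menten at `I = 0`:
#' competitive `v = Vmax S / (Km (1 + I/Ki) + S)`;
#' uncompetitive `v = Vmax S / (Km + S (1 + I/Ki))`;
#' non-competitive `v = Vmax S / ((1 + I/Ki)(Km + S))`;
#' mixed `v = Vmax S / (Km (1 + I/Ki) + S (1 + I/Kip))`.
#'
#' @param S Substrate concentration(s), mM; positive.
#' @param I Inhibitor concentration(s), mM; non-negative.
#' @param mechanism One of `"competitive"`, `"uncompetitive"`,
#'   `"non-competitive"`, `"mixed"`.
#' @param Km Michaelis constant, mM.
#' @param Vmax Maximal rate (unit-free for fitting purposes).
#' @param Ki Inhibition constant, mM.
#' @param Kip Second inhibition constant (mixed mechanism only), mM.
#' @return Initial rate(s), same length as `S`/`I` after recycling.
#' @export
rate_law <- function(S, I, mechanism, Km, Vmax, Ki, Kip = NULL) {
  mechanism <- match.arg(mechanism, mechanisms())
  if (any(S <= 0)) tt_abort("Substrate concentrations must be positive.", "domain_error")
  if (any(I < 0)) tt_abort("Inhibitor concentrations must be non-negative.", "domain_error")
  if (Km <= 0 || Vmax <= 0 || Ki <= 0) {
    tt_abort("Km, Vmax and Ki must be positive.", "domain_error")
  }
  if (mechanism == "mixed") {
    if (is.null(Kip) || Kip <= 0) {
      tt_abort("The mixed mechanism needs a positive `Kip`.", "domain_error")
    }
    return(Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / Kip)))
  }
  switch(mechanism,
    competitive = Vmax * S / (Km * (1 + I / Ki) + S),
    uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)),
    `non-competitive` = Vmax * S / ((1 + I / Ki) * (Km + S))
  )
}

#' Lineweaver-Burk analysis with secondary plots
#'
#' Ordinary least squares on the double-reciprocal transform (1/v vs 1/S),
#' one line per inhibitor level, plus the secondary (replot) lines of the
#' per-level slopes and intercepts against inhibitor concentration. For a
#' competitive inhibitor the slope replot crosses zero at `I = -Ki`; for the
#' intercept replot of non-competitive/uncompetitive inhibition the
#' x-intercept is `-Ki` as well, so both replot-based estimates are
#' reported.
#'
#' @param data Data frame with columns `S`, `I`, `v` (all concentrations
#'   mM; all rates positive). Replicates are used as-is.
#' @return A `lineweaver_burk` object: `per_level` tibble (I, slope,
#'   intercept, n), `slope_replot` and `intercept_replot` coefficient
#'   lists, and `estimates` (Vmax, Km from the uninhibited line;
#'   `Ki_slope`, `Ki_intercept` from the replot x-intercepts). [autoplot()]
#'   draws the primary and secondary plots.
#' @export
lineweaver_burk <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("S", "I", "v") %in% names(data))) {
    tt_abort("`data` needs columns S, I, v.", "fit_error")
  }
  if (any(data$v <= 0)) {
    tt_abort("All rates must be positive for the reciprocal transform.", "domain_error")
  }
  per_level <- data |>
    dplyr::group_by(I = .data$I) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$S) < 2L) {
        tt_abort(
          "Each inhibitor level needs at least 2 distinct substrate levels.",
          "singular_fit"
        )
      }
      f <- lm(I(1 / v) ~ I(1 / S), data = d)
      tibble::tibble(
        slope = unname(coef(f)[2]),
        intercept = unname(coef(f)[1]),
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$I)

  rep_slope <- lm(slope ~ I, data = per_level)
  rep_int <- lm(intercept ~ I, data = per_level)
  xint <- function(f) {
    b <- unname(coef(f))
    if (abs(b[2]) < 1e-12 * max(abs(b[1]), 1)) NA_real_ else -b[1] / b[2]
  }
  base <- per_level[which.min(per_level$I), ]
  # replot x-intercepts sit at -Ki (slope replot, competitive component)
  # and -Ki' (intercept replot, uncompetitive component)
  estimates <- list(
    Vmax = 1 / base$intercept,
    Km = base$slope / base$intercept,
    slope_xint = xint(rep_slope),
    intercept_xint = xint(rep_int),
    Ki_slope = -xint(rep_slope),
    Ki_intercept = -xint(rep_int)
  )
  structure(
    list(
      per_level = per_level,
      slope_replot = list(
        intercept = unname(coef(rep_slope)[1]),
        slope = unname(coef(rep_slope)[2])
      ),
      intercept_replot = list(
        intercept = unname(coef(rep_int)[1]),
        slope = unname(coef(rep_int)[2])
      ),
      estimates = estimates,
      data = data
    ),
    class = "lineweaver_burk"
  )
}

#' @export
print.lineweaver_burk <- function(x, ...) {
  cat(
    sprintf(
      "<lineweaver_burk> %d inhibitor level(s); Vmax=%.4g, Km=%.4g, Ki(slope replot)=%.4g, Ki(intercept replot)=%.4g\n",
      nrow(x$per_level), x$estimates$Vmax, x$estimates$Km,
      x$estimates$Ki_slope, x$estimates$Ki_intercept
    )
  )
  invisible(x)
}

## Gaussian AICc from the residual sum of squares (constants dropped;
## only differences between models matter). The RSS is floored at a
## scale-relative epsilon so that exact (noise-free) fits from nested
## models compare by parameter count rather than by rounding noise.
aicc_of <- function(fit, n, rss_floor) {
  k <- length(coef(fit)) + 1 # + residual variance
  rss <- max(sum(stats::resid(fit)^2), rss_floor)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

fit_one_mechanism <- function(data, mechanism, starts) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)
  formulas <- list(
    competitive = v ~ Vmax * S / (Km * (1 + I / Ki) + S),
    uncompetitive = v ~ Vmax * S / (Km + S * (1 + I / Ki)),
    `non-competitive` = v ~ Vmax * S / ((1 + I / Ki) * (Km + S)),
    mixed = v ~ Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / Kip))
  )
  start <- list(Km = starts$Km, Vmax = starts$Vmax, Ki = starts$Ki)
  lower <- c(1e-9, 1e-9, 1e-9)
  if (mechanism == "mixed") {
    start$Kip <- starts$Kip %||% starts$Ki
    lower <- c(lower, 1e-9)
  }
  tryCatch(
    minpack.lm::nlsLM(
      formulas[[mechanism]],
      data = data, start = start, lower = lower, control = ctrl
    ),
    error = function(e) NULL
  )
}

#' Classify the inhibition mechanism and estimate Ki
#'
#' Globally fits all four single-substrate inhibition rate laws to an
#' initial-rate dataset by nonlinear least squares (Lineweaver-Burk
#' estimates seed the optimizer) and selects the mechanism by corrected
#' AIC. Among models within 2 AICc of the best, the one with fewest
#' parameters is chosen (parsimony tie-break) and the fit is flagged
#' ambiguous. The headline Ki comes from the winning global fit;
#' Lineweaver-Burk diagnostics are attached for reporting.
#'
#' @param data Data frame with columns `S`, `I`, `v` (and optionally
#'   `replicate`); at least 3 inhibitor levels including 0, and at least 4
#'   substrate levels.
#' @return A `mechanism_fit`: `mechanism`, estimates `Km`, `Vmax`, `Ki`
#'   (and `Kip` for mixed), standard errors, the per-model AICc table,
#'   `ambiguous` flag, the `lineweaver_burk` diagnostics and the winning
#'   `nls` fit. [tidy()], [glance()] and [autoplot()] methods are
#'   provided.
#' @examples
#' sim <- gen_kinetics(
#'   "competitive",
#'   Km = 0.1, Vmax = 1, Ki = 2.2,
#'   S_grid = c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
#'   I_grid = c(0, 1, 2.5, 5, 9, 15),
#'   replicates = 3, noise_cv = 0.02, seed = 7
#' )
#' fit <- classify_mechanism(sim$data)
#' glance(fit)
#' @export
classify_mechanism <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("S", "I", "v") %in% names(data))) {
    tt_abort("`data` needs columns S, I, v.", "fit_error")
  }
  i_levels <- sort(unique(data$I))
  if (length(i_levels) < 3L || !any(i_levels == 0)) {
    tt_abort(
      "Mechanism classification needs >= 3 inhibitor levels including 0.",
      "insufficient_inhibitor_levels"
    )
  }
  if (dplyr::n_distinct(data$S) < 4L) {
    tt_abort(
      "Mechanism classification needs >= 4 substrate levels.",
      "insufficient_substrate_levels"
    )
  }
  lb <- lineweaver_burk(data)
  # replot x-intercepts sit at -Ki; their magnitudes seed the global fit
  ki_lb <- abs(c(lb$estimates$Ki_slope, lb$estimates$Ki_intercept))
  ki_lb <- ki_lb[is.finite(ki_lb) & ki_lb > 0]
  ki0 <- if (length(ki_lb) > 0L) stats::median(ki_lb) else stats::median(data$I[data$I > 0])
  starts <- list(
    Km = max(lb$estimates$Km, 1e-6),
    Vmax = max(lb$estimates$Vmax, 1e-6),
    Ki = max(ki0, 1e-6)
  )

  n <- nrow(data)
  rss_floor <- n * (1e-7 * max(abs(data$v)))^2
  fits <- lapply(mechanisms(), function(m) fit_one_mechanism(data, m, starts))
  names(fits) <- mechanisms()
  aicc <- vapply(
    fits,
    function(f) if (is.null(f)) Inf else aicc_of(f, n, rss_floor),
    numeric(1)
  )
  npar <- c(competitive = 3L, uncompetitive = 3L, `non-competitive` = 3L, mixed = 4L)
  if (all(!is.finite(aicc))) {
    tt_abort("No mechanism model converged.", "fit_error")
  }
  aic_table <- tibble::tibble(
    mechanism = mechanisms(),
    npar = unname(npar[mechanisms()]),
    aicc = unname(aicc),
    delta = unname(aicc - min(aicc))
  )
  within <- aic_table$delta <= 2 & is.finite(aic_table$aicc)
  cand <- aic_table[within, ]
  cand <- cand[order(cand$npar, cand$aicc), ]
  winner <- cand$mechanism[1]
  ambiguous <- sum(within) > 1L
  fit <- fits[[winner]]
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"], error = function(e) {
    setNames(rep(NA_real_, length(est)), names(est))
  })
  structure(
    list(
      mechanism = winner,
      Km = unname(est[["Km"]]),
      Vmax = unname(est[["Vmax"]]),
      Ki = unname(est[["Ki"]]),
      Kip = if (winner == "mixed") unname(est[["Kip"]]) else NA_real_,
      se = se,
      aic_table = aic_table,
      ambiguous = ambiguous,
      lb = lb,
      fit = fit,
      fits = fits,
      data = data,
      n = n
    ),
    class = "mechanism_fit"
  )
}

#' @export
print.mechanism_fit <- function(x, ...) {
  cat(
    sprintf(
      "<mechanism_fit> %s%s: Ki = %.4g mM, Km = %.4g mM, Vmax = %.4g (n = %d)\n",
      x$mechanism, if (x$ambiguous) " (ambiguous, dAICc < 2)" else "",
      x$Ki, x$Km, x$Vmax, x$n
    )
  )
  if (x$mechanism == "mixed") cat(sprintf("  Kip = %.4g mM\n", x$Kip))
  invisible(x)
}
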