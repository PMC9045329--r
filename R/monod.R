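# The rate-law layer: simulated growth curves, phenomenological Monod
# parameter extraction, the alternative and Gaussian-amended Monod forms,
# control-coefficient approximations, and mechanistic composite parameters.

#' Simulate a steady-state growth curve over a methanol grid
#'
#' Solves the model to steady state at each external methanol concentration
#' (warm-started along the grid) and records the specific growth rate.
#'
#' @param model an `mb_network`
#' @param grid methanol concentrations, mol/L; the default spans 1 uM to
#'   1 M with `per_decade` points per decade (the top decade supports the
#'   maximum-growth-rate extraction)
#' @param per_decade grid density of the default grid
#' @param ... passed to [steady_state()]
#' @return object of class `growth_curve`: data.frame with `methanol`
#'   (mol/L) and `mu` (d-1)
#' @export
growth_curve <- function(model, grid = NULL, per_decade = 16, ...) {
  if (is.null(grid)) grid <- 10^seq(-6, 0, by = 1 / per_decade)
  grid <- sort(grid)
  mus <- numeric(length(grid)); warm <- NULL; conv <- logical(length(grid))
  for (i in seq_along(grid)) {
    ss <- steady_state(model, methanol = grid[i], polish = TRUE,
                       init = warm, ...)
    warm <- ss$reduced
    mus[i] <- per_day(ss$mu); conv[i] <- ss$converged
  }
  structure(data.frame(methanol = grid, mu = mus, converged = conv),
            class = c("growth_curve", "data.frame"))
}

#' Monod-family rate laws
#'
#' `monod()` is the hyperbolic law `mu_max C / (C + k_m)`; `alt_monod()` is
#' its alternative form parameterized by the specific affinity,
#' `mu_max alpha C / (mu_max + alpha C)` (identical to `monod()` when
#' `k_m = mu_max / alpha`); `first_order()` is `alpha C`; `liebig()` is the
#' minimum law `min(alpha C, mu_max)`.
#'
#' @param C substrate concentration, mol/L
#' @param mu_max maximum specific growth rate (any rate unit; the result is
#'   in the same unit)
#' @param k_m half-saturation constant, mol/L
#' @param alpha specific affinity, (mol/L)-1 per rate unit
#' @return growth rate(s)
#' @export
#' @examples
#' monod(4e-4, 1, 4e-4)            # half saturation
#' alt_monod(0.625e-3, 1, 1600)    # alpha C == mu_max -> mu_max/2
monod <- function(C, mu_max, k_m) mu_max * C / (C + k_m)

#' @rdname monod
#' @export
alt_monod <- function(C, mu_max, alpha) mu_max * alpha * C / (mu_max + alpha * C)

#' @rdname monod
#' @export
first_order <- function(C, alpha) alpha * C

#' @rdname monod
#' @export
liebig <- function(C, mu_max, alpha) pmin(alpha * C, mu_max)

#' Gaussian-amended alternative Monod law
#'
#' Adds a log-normal-in-concentration error peak to the alternative Monod
#' form: `mu = alt_monod(C) + mu_o exp[-pi (ln(mu_max/(alpha C)) / beta)^2]`,
#' with the dimensionless breadth `beta` switching from `beta_low` to
#' `beta_high` at `C = mu_max/alpha` (the correction is continuous there
#' because its argument vanishes).
#'
#' @inheritParams monod
#' @param mu_o peak height of the correction (rate units)
#' @param beta_low,beta_high integral-breadth parameters below and above
#'   `C = mu_max / alpha`
#' @return growth rate(s)
#' @export
amended_monod <- function(C, mu_max, alpha, mu_o, beta_low, beta_high) {
  z <- log(mu_max / (alpha * C))
  beta <- ifelse(z > 0, beta_low, beta_high)
  alt_monod(C, mu_max, alpha) + mu_o * exp(-pi * (z / beta)^2)
}

#' Monod-form approximations of the MCR and MTA control coefficients
#'
#' Under the alternative Monod law with its parameters tied to the two
#' rate-determining enzymes, the flux control coefficients follow
#' `eps_MCR = alpha C / (alpha C + mu_max)` and
#' `eps_MTA = mu_max / (alpha C + mu_max)`; they sum to 1 identically.
#'
#' @inheritParams monod
#' @return data.frame with `C`, `eps_MCR`, `eps_MTA`
#' @export
approx_control <- function(C, mu_max, alpha) {
  data.frame(C = C, eps_MCR = alpha * C / (alpha * C + mu_max),
             eps_MTA = mu_max / (alpha * C + mu_max))
}

#' Extract the phenomenological Monod parameters from a growth curve
#'
#' Follows the phenomenological protocol: `mu_max` is the growth rate at 1 M
#' methanol; `K_M` is the concentration driving growth at half of `mu_max`
#' (monotone interpolation on log-concentration); `alpha` is the
#' zero-intercept least-squares slope over the points below 10 uM.
#'
#' @param curve a `growth_curve` (or data.frame with `methanol` in mol/L and
#'   `mu`)
#' @param at concentration at which `mu_max` is read (default 1 M; the curve
#'   must reach it)
#' @return `extract_mu_max`: rate at `at`; `extract_k_m`: mol/L;
#'   `extract_alpha`: M-1 per rate unit
#' @export
extract_mu_max <- function(curve, at = 1) {
  if (max(curve$methanol) < at)
    stopf("curve does not reach %g M methanol", at)
  stats::approx(log(curve$methanol), curve$mu, xout = log(at))$y
}

#' @rdname extract_mu_max
#' @param mu_max the maximum rate (from [extract_mu_max()])
#' @export
extract_k_m <- function(curve, mu_max) {
  if (min(curve$mu) > mu_max / 2 || max(curve$mu) < mu_max / 2)
    stopf("curve does not bracket mu_max / 2; cannot extract K_M")
  exp(stats::approx(curve$mu, log(curve$methanol), xout = mu_max / 2,
                    ties = "ordered")$y)
}

#' @rdname extract_mu_max
#' @param c_max upper end of the first-order window used for the slope fit
#'   (default 10 uM)
#' @details The specific-affinity fit is a zero-intercept least-squares
#'   slope over the sub-`c_max` points, weighted by `1/C^2` (i.e. least
#'   squares on the relative residuals). The weighting removes the
#'   `O(C/K_M)` bias a plain slope fit picks up from the onset of
#'   saturation, so an exact Monod curve returns `alpha = mu_max/K_M`.
#' @export
extract_alpha <- function(curve, c_max = 1e-5) {
  k <- curve$methanol < c_max
  if (sum(k) < 2) stopf("fewer than 2 points below %g M; cannot fit alpha", c_max)
  mean(curve$mu[k] / curve$methanol[k])
}

#' Fit the Gaussian amendment to a growth curve
#'
#' The residual of the simulated curve above the alternative Monod form is
#' summarized by its peak `mu_o` and fitted, separately below and above
#' `C = mu_max/alpha`, with the Gaussian
#' `mu_o exp[-pi (z/beta)^2]`, `z = ln(mu_max/(alpha C))`, by least squares
#' on the normalized residuals (points with residual above
#' `threshold * mu_o`).
#'
#' @inheritParams extract_mu_max
#' @param mu_max,alpha phenomenological parameters of the curve
#' @param threshold inclusion threshold as a fraction of the peak residual
#' @return list with `mu_o`, `beta_low`, `beta_high`, `degenerate` (TRUE if
#'   the residual is numerically zero and beta is meaningless)
#' @export
fit_gaussian_amendment <- function(curve, mu_max, alpha, threshold = 0.02) {
  resid <- curve$mu - alt_monod(curve$methanol, mu_max, alpha)
  mu_o <- max(resid)
  if (mu_o <= 1e-10 * mu_max)
    return(list(mu_o = 0, beta_low = NA_real_, beta_high = NA_real_,
                degenerate = TRUE))
  z <- log(mu_max / (alpha * curve$methanol))
  fit_side <- function(sel) {
    ok <- sel & resid > threshold * mu_o
    if (sum(ok) < 2) return(NA_real_)
    stats::optimize(function(b)
      sum((resid[ok] / mu_o - exp(-pi * (z[ok] / b)^2))^2),
      interval = c(0.2, 15))$minimum
  }
  list(mu_o = mu_o, beta_low = fit_side(z > 0), beta_high = fit_side(z < 0),
       degenerate = FALSE)
}

#' Fit the Monod-family description of a simulated growth curve
#'
#' The one-stop phenomenological fit: extracts `mu_max`, `K_M` and `alpha`
#' by the standard protocol (see [extract_mu_max()]) and fits the Gaussian
#' amendment of the alternative Monod law. Returns a classed model object
#' with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and
#' `plot` methods.
#'
#' @param curve a `growth_curve` (from [growth_curve()]) or any data.frame
#'   with columns `methanol` (mol/L) and `mu`
#' @param threshold passed to [fit_gaussian_amendment()]
#' @return object of class `monod_fit`
#' @export
#' @examples
#' cv <- data.frame(methanol = 10^seq(-6, 0, 0.05))
#' cv$mu <- monod(cv$methanol, 1.0, 4e-4)
#' fit <- monod_fit(cv)
#' coef(fit)
monod_fit <- function(curve, threshold = 0.02) {
  stopifnot(all(c("methanol", "mu") %in% names(curve)))
  mu_max <- extract_mu_max(curve)
  k_m <- extract_k_m(curve, mu_max)
  alpha <- extract_alpha(curve)
  ga <- fit_gaussian_amendment(curve, mu_max, alpha, threshold = threshold)
  structure(list(curve = curve, mu_max = mu_max, k_m = k_m, alpha = alpha,
                 mu_o = ga$mu_o, beta_low = ga$beta_low,
                 beta_high = ga$beta_high, degenerate = ga$degenerate),
            class = "monod_fit")
}

#' @export
coef.monod_fit <- function(object, ...) {
  c(mu_max = object$mu_max, k_m = object$k_m, alpha = object$alpha,
    mu_o = object$mu_o, beta_low = object$beta_low,
    beta_high = object$beta_high)
}

#' @export
print.monod_fit <- function(x, ...) {
  cat("<monod_fit>\n")
  cat(sprintf("  mu_max = %.4g d-1 (at 1 M)   K_M = %.4g mM   alpha = %.4g /M/d\n",
              x$mu_max, 1e3 * x$k_m, x$alpha))
  if (x$degenerate) cat("  Gaussian amendment: degenerate (curve is alt-Monod)\n")
  else cat(sprintf("  amendment: mu_o = %.4g, beta = %.3g (C < mu_max/alpha) / %.3g\n",
                   x$mu_o, x$beta_low, x$beta_high))
  invisible(x)
}

#' @export
summary.monod_fit <- function(object, ...) {
  print(object)
  rl <- rate_law_comparison(object$curve, object)
  cat(sprintf("  max |rel.diff| vs Monod: %.1f%%; vs alternative form: %.1f%%; vs amended: %.1f%%\n",
              100 * max(abs(rl$rd_monod)), 100 * max(abs(rl$rd_alt)),
              100 * max(abs(rl$rd_amended))))
  invisible(rl)
}

#' @export
predict.monod_fit <- function(object, newdata = NULL,
                              type = c("amended", "monod", "alt",
                                       "first_order", "liebig"), ...) {
  type <- match.arg(type)
  C <- if (is.null(newdata)) object$curve$methanol
       else if (is.data.frame(newdata)) newdata$methanol else newdata
  switch(type,
    monod = monod(C, object$mu_max, object$k_m),
    alt = alt_monod(C, object$mu_max, object$alpha),
    first_order = first_order(C, object$alpha),
    liebig = liebig(C, object$mu_max, object$alpha),
    amended = if (object$degenerate) alt_monod(C, object$mu_max, object$alpha)
              else amended_monod(C, object$mu_max, object$alpha, object$mu_o,
                                 object$beta_low, object$beta_high))
}

#' @export
fitted.monod_fit <- function(object, ...) predict(object)

#' @export
residuals.monod_fit <- function(object, ...) object$curve$mu - fitted(object)

#' @export
plot.monod_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$methanol * 1e3, cv$mu, log = "x", pch = 16, cex = 0.6,
                 xlab = "methanol (mM)", ylab = expression(mu ~ (d^-1)), ...)
  C <- 10^seq(log10(min(cv$methanol)), log10(max(cv$methanol)), length.out = 300)
  graphics::lines(C * 1e3, monod(C, x$mu_max, x$k_m), lty = 2, col = "blue")
  graphics::lines(C * 1e3, alt_monod(C, x$mu_max, x$alpha), lty = 3)
  graphics::lines(C * 1e3, predict(x, C), col = "red")
  graphics::legend("topleft", bty = "n",
                   legend = c("simulated", "Monod", "alternative", "amended"),
                   lty = c(NA, 2, 3, 1), pch = c(16, NA, NA, NA),
                   col = c("black", "blue", "black", "red"))
  invisible(x)
}

#' Relative difference between rate laws and the simulated curve
#'
#' Per grid point, `(simulated - rate law) / simulated` for the Monod law
#' (with the extracted half-saturation constant), the alternative form
#' (with the extracted specific affinity), and the Gaussian-amended form.
#'
#' @param curve growth curve data.frame (`methanol`, `mu`)
#' @param fit a `monod_fit`
#' @return data.frame with `methanol_mM`, `mu`, `rd_monod`, `rd_alt`,
#'   `rd_amended`
#' @export
rate_law_comparison <- function(curve, fit) {
  stopifnot(inherits(fit, "monod_fit"))
  C <- curve$methanol
  data.frame(methanol_mM = 1e3 * C, mu = curve$mu,
             rd_monod = (curve$mu - predict(fit, C, type = "monod")) / curve$mu,
             rd_alt = (curve$mu - predict(fit, C, type = "alt")) / curve$mu,
             rd_amended = (curve$mu - predict(fit, C, type = "amended")) / curve$mu)
}

#' Mechanistic composite parameters of the Monod curve
#'
#' The specific affinity and maximum growth rate recovered from enzyme-level
#' constants rather than from the curve: the apparent MTA rate constant is
#' the catalytic constant discounted by coenzyme M occupancy at vanishing
#' methanol, `k_MTA,app = k_MTA C_CoM,0 / (C_CoM,0 + K_m,CoM)`, giving
#' `alpha = phi_MTA Y_P/CH3OH k_MTA,app / K_m,CH3OH`; the apparent
#' MCR constant is discounted by the methyl-CoM and CoB moiety saturations
#' at high methanol, `k_MCR,app = k_MCR T_CoM/(T_CoM + K_m,MCoM) *
#' T_CoB/(T_CoB + K_m,CoB)`, giving `mu_max = phi_MCR Y_P/CH4 k_MCR,app`.
#' The protein yields carry the protein-to-dry-mass conversion, so both
#' composites are on the same per-dry-mass scale as the simulated rates
#' (see the methods vignette). A low-methanol steady state supplies
#' `C_CoM,0`; the high-methanol one documents the saturation regime the
#' formulas assume.
#' @param model an `mb_network`
#' @param ss_low steady state well below 0.2 mM methanol
#' @param ss_high steady state well above 15 mM methanol
#' @return list with `k_mta_app`, `k_mcr_app` (mol/g/s), `c_com_0` (mol/L),
#'   `alpha` (M-1 s-1), `mu_max` (s-1), and `cob_saturation`
#' @export
composite_params <- function(model, ss_low, ss_high) {
  rx <- model$reactions
  c_com_0 <- ss_low$state$conc[["HS_CoM"]]
  km_com <- rx$MTA$km[["HS_CoM"]]
  km_meoh <- rx$MTA$km[["CH3OH_c"]]
  k_mta_app <- rx$MTA$kcat * c_com_0 / (c_com_0 + km_com)
  t_com <- model$moieties$CoM$total
  t_cob <- model$moieties$CoB$total
  km_mcom <- rx$MCR$km[["CH3_CoM"]]
  km_cob <- rx$MCR$km[["HS_CoB"]]
  cob_sat <- t_cob / (t_cob + km_cob)
  k_mcr_app <- rx$MCR$kcat * t_com / (t_com + km_mcom) * cob_sat
  list(k_mta_app = k_mta_app, k_mcr_app = k_mcr_app, c_com_0 = c_com_0,
       cob_saturation = cob_sat,
       alpha = rx$MTA$phi * model$biomass$y_p_ch3oh * k_mta_app / km_meoh,
       mu_max = rx$MCR$phi * model$biomass$y_p_ch4 * k_mcr_app)
}

#' Write a growth curve / Monod fit report
#'
#' @param fit a `monod_fit`
#' @param path JSON output path
#' @return `path`, invisibly
#' @export
write_monod_report <- function(fit, path) {
  jsonlite::write_json(as.list(coef(fit)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
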