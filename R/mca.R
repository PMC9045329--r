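# Metabolic control analysis: scaled flux control coefficients of enzymes
# and diffusion processes, and flux response coefficients of conserved
# moiety pools, by finite-difference perturbation with steady-state
# re-solution.

# return a model with component `id` perturbed by factor (1 + delta), plus a
# warm-start state consistent with the perturbation
perturb_component <- function(model, id, delta, base_state = NULL) {
  init <- base_state
  if (id %in% names(model$reactions)) {
    model$reactions[[id]]$phi <- model$reactions[[id]]$phi * (1 + delta)
  } else if (!is.null(model$diffusions) && id %in% model$diffusions$id) {
    k <- match(id, model$diffusions$id)
    model$diffusions$d_coeff[k] <- model$diffusions$d_coeff[k] * (1 + delta)
  } else if (id %in% names(model$moieties)) {
    mem <- model$moieties[[id]]$members
    model$moieties[[id]]$total <- model$moieties[[id]]$total * (1 + delta)
    k <- model$species$id %in% mem
    model$species$conc_init[k] <- model$species$conc_init[k] * (1 + delta)
    if (!is.null(init)) {
      nm <- names(init) %in% mem
      init[nm] <- init[nm] * (1 + delta)
    }
  } else stopf("unknown network component '%s'", id)
  list(model = model, init = init)
}

# flux observable of a steady state
flux_observable <- function(ss, flux) {
  if (identical(flux, "mu")) ss$mu else ss$velocities[[flux]]
}

#' Scaled flux control coefficient of an enzyme or diffusion process
#'
#' `epsilon = (phi / J) dJ/dphi`, evaluated by a forward finite difference:
#' the proteome fraction of the enzyme (or the diffusion coefficient of the
#' process) is increased by `delta` (default 1%), the steady state is
#' re-solved from the baseline state, and the fractional change of the flux
#' observable (the specific growth rate by default) is divided by `delta`.
#'
#' @param model an `mb_network`
#' @param id enzyme reaction id, diffusion process id, or moiety pool id
#' @param methanol external methanol, mol/L (default: the model's current)
#' @param delta fractional perturbation (default 0.01)
#' @param flux observable: `"mu"` (default) or a reaction id whose steady
#'   velocity is the flux of interest
#' @param base optional precomputed baseline `mb_steady_state`
#' @param central use a central difference instead of the forward one
#' @param ... passed to [steady_state()]
#' @return scaled coefficient (dimensionless)
#' @export
flux_control_coefficient <- function(model, id, methanol = NULL, delta = 0.01,
                                     flux = "mu", base = NULL, central = FALSE,
                                     ...) {
  if (!is.null(methanol)) model <- set_methanol(model, methanol)
  if (is.null(base)) base <- steady_state(model, polish = TRUE, ...)
  if (!base$converged) stopf("baseline steady state did not converge")
  solve_at <- function(d) {
    p <- perturb_component(model, id, d, base$reduced)
    ss <- steady_state(p$model, polish = TRUE, init = p$init, ...)
    if (!ss$converged)
      stopf("perturbed steady state for '%s' did not converge", id)
    flux_observable(ss, flux)
  }
  J0 <- flux_observable(base, flux)
  if (central) (solve_at(delta) - solve_at(-delta)) / (2 * delta * J0)
  else (solve_at(delta) - J0) / (delta * J0)
}

#' @rdname flux_control_coefficient
#' @details `response_coefficient()` is the same scaled sensitivity for the
#'   total concentration of a conserved moiety pool; all member species are
#'   rescaled proportionally before re-solving, preserving intra-pool
#'   ratios.
#' @export
response_coefficient <- function(model, id, methanol = NULL, delta = 0.01,
                                 flux = "mu", base = NULL, central = FALSE,
                                 ...) {
  if (!(id %in% names(model$moieties)))
    stopf("'%s' is not a moiety pool of the model", id)
  flux_control_coefficient(model, id, methanol = methanol, delta = delta,
                           flux = flux, base = base, central = central, ...)
}

#' Control and response coefficient profile across methanol concentrations
#'
#' Computes scaled flux control coefficients for every enzyme reaction and
#' diffusion process, and scaled flux response coefficients for every moiety
#' pool, at each methanol concentration of the grid. Steady states are
#' continued along the grid (warm starts), and the summation-theorem
#' residual (sum of enzyme + diffusion coefficients, which should be 1) is
#' reported per grid point.
#'
#' @param model an `mb_network`
#' @param grid methanol concentrations, mol/L
#' @param components optional subset of component ids (default: all enzymes,
#'   diffusion processes and moiety pools)
#' @param delta fractional perturbation
#' @param flux observable (see [flux_control_coefficient()])
#' @return object of class `mb_control_profile`: data.frame with columns
#'   `methanol_mM`, `component`, `kind` (enzyme/diffusion/moiety),
#'   `epsilon`; the per-point summation residual is in
#'   `attr(, "summation")`.
#' @export
control_profile <- function(model, grid, components = NULL, delta = 0.01,
                            flux = "mu") {
  enz <- names(Filter(function(r) r$type == "enzyme", model$reactions))
  dif <- if (is.null(model$diffusions)) character(0) else model$diffusions$id
  moi <- names(model$moieties)
  all_ids <- c(enz, dif, moi)
  kinds <- c(rep("enzyme", length(enz)), rep("diffusion", length(dif)),
             rep("moiety", length(moi)))
  if (!is.null(components)) {
    keep <- all_ids %in% components
    all_ids <- all_ids[keep]; kinds <- kinds[keep]
  }
  rows <- list(); sums <- data.frame(methanol_mM = numeric(), summation = numeric())
  warm <- NULL
  if (is.null(grid)) grid <- NA_real_   # single profile at the current state
  for (C in sort(grid, na.last = TRUE)) {
    mC <- if (is.na(C)) model else set_methanol(model, C)
    base <- steady_state(mC, polish = TRUE, init = warm)
    warm <- base$reduced
    eps <- vapply(all_ids, function(id) {
      tryCatch(flux_control_coefficient(mC, id, delta = delta, flux = flux,
                                        base = base),
               error = function(e) NA_real_)
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      methanol_mM = if (is.na(C)) NA_real_ else 1e3 * C,
      component = all_ids, kind = kinds,
      epsilon = unname(eps), row.names = NULL)
    ssum <- sum(eps[kinds != "moiety"], na.rm = TRUE)
    sums[nrow(sums) + 1L, ] <- list(1e3 * C, ssum)
  }
  structure(do.call(rbind, rows), class = c("mb_control_profile", "data.frame"),
            summation = sums, flux = flux, delta = delta)
}

#' @export
print.mb_control_profile <- function(x, ...) {
  cat(sprintf("<mb_control_profile> %d components x %d methanol levels\n",
              length(unique(x$component)), length(unique(x$methanol_mM))))
  s <- attr(x, "summation")
  cat(sprintf("  summation residual (enzymes + diffusion): %.3f .. %.3f\n",
              min(s$summation), max(s$summation)))
  invisible(x)
}

#' Write a control profile as tab-separated values
#'
#' @param profile an `mb_control_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
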