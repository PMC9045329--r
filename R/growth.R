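# Herbert-Pirt coupling of pathway fluxes to biomass synthesis and
# maintenance, and steady-state yield reporting.

#' Maintenance ATP flux of a cell
#'
#' Constant ATP-hydrolysis flux of the maintenance pseudo-reaction:
#' `maintenance_atp` (mol ATP per g dry weight per s) times the cell dry
#' mass.
#'
#' @param cell cell-parameter list (fields `maintenance_atp`, `dry_mass`)
#' @return flux in mol ATP/s per cell
#' @export
maintenance_flux <- function(cell) {
  (cell$maintenance_atp %||% 0) * cell$dry_mass
}

#' Growth fluxes from the ATP balance
#'
#' Implements the Herbert-Pirt partition: the biomass pseudo-reaction flux is
#' driven by the ATP surplus of ATP synthase over maintenance,
#' `biomass_flux = max(0, v_atp_synthase - maint) / atp_per_g`, and the
#' biosynthetic drains of reduced cofactors and acetyl-CoA are proportional
#' to it. The gross specific growth rate `mu = v_atp_synthase /
#' (atp_per_g * dry_mass)` is the rate the growth-curve analysis uses; the
#' net rate subtracts the maintenance-equivalent rate.
#'
#' @param v_atp_synthase ATP synthase flux, mol/s per cell
#' @param maint maintenance ATP flux, mol/s per cell
#' @param bio biomass-stoichiometry list (`atp_per_g`, `fdred_per_g`,
#'   `f420h2_per_g`, `accoa_per_g`)
#' @param cell cell-parameter list (`dry_mass`)
#' @return list with `biomass_flux` (g/s), `mu` and `mu_net` (s-1), and
#'   `drains` (mol/s consumed per cofactor)
#' @export
#' @examples
#' cell <- list(dry_mass = 2e-12)
#' bio <- list(atp_per_g = 0.14, fdred_per_g = 0.011,
#'             f420h2_per_g = 0.011, accoa_per_g = 0.014)
#' growth_rate_from_fluxes(3e-18, 1e-19, bio, cell)
growth_rate_from_fluxes <- function(v_atp_synthase, maint, bio, cell) {
  if (is.null(bio$atp_per_g) || bio$atp_per_g <= 0)
    stopf("biomass stoichiometry must have atp_per_g > 0")
  b <- max(0, v_atp_synthase - maint) / bio$atp_per_g
  list(biomass_flux = b,
       mu = v_atp_synthase / (bio$atp_per_g * cell$dry_mass),
       mu_net = (v_atp_synthase - maint) / (bio$atp_per_g * cell$dry_mass),
       drains = c(Fd_red = (bio$fdred_per_g %||% 0) * b,
                  F420H2 = (bio$f420h2_per_g %||% 0) * b,
                  AcCoA = (bio$accoa_per_g %||% 0) * b,
                  ATP = bio$atp_per_g * b))
}

#' Steady-state product yields per methanol
#'
#' Moles of CO2 and CH4 released to the environment per mole of methanol
#' consumed, from the converged diffusive fluxes. Both fall below the
#' catabolic stoichiometry (1/4 and 3/4) when biosynthetic drains divert
#' methyl groups and CO2 into acetyl-CoA.
#'
#' @param ss an `mb_steady_state`
#' @return list with `ch4_per_methanol`, `co2_per_methanol`,
#'   `methanol_influx` (mol/s), and `carbon_to_biomass` (mol C/s)
#' @export
yield_report <- function(ss) {
  J <- ss$fluxes
  j_meoh <- J[["DIFF_CH3OH"]]
  if (!is.finite(j_meoh) || j_meoh <= 0)
    stopf("yield_report: no net methanol influx at this state")
  ch4 <- -J[["DIFF_CH4"]]
  co2 <- -J[["DIFF_CO2"]]
  list(ch4_per_methanol = ch4 / j_meoh,
       co2_per_methanol = co2 / j_meoh,
       methanol_influx = j_meoh,
       carbon_to_biomass = j_meoh - ch4 - co2)
}

#' Steady-state carbon balance residual
#'
#' Relative imbalance between methanol carbon influx and the sum of CH4 and
#' CO2 efflux plus carbon drained into biomass (two carbons per acetyl-CoA:
#' the methyl group and a CO2 withheld from the efflux).
#'
#' @param ss an `mb_steady_state`
#' @return relative residual (dimensionless, ~0 at a converged state)
#' @export
carbon_balance <- function(ss) {
  J <- ss$fluxes
  # influx = CH4 efflux + net CO2 efflux + 2 C per acetyl-CoA formed (the
  # methyl group plus the CO2 molecule retained from the efflux)
  res <- J[["DIFF_CH3OH"]] + J[["DIFF_CO2"]] + J[["DIFF_CH4"]] -
    2 * ss$velocities[["ACS"]]
  res / abs(J[["DIFF_CH3OH"]])
}

#' Growth report across methanol concentrations
#'
#' @param model an `mb_network`
#' @param methanol vector of external methanol concentrations, mol/L
#' @param ... passed to [steady_state()]
#' @return data.frame with methanol (mM), mu and mu_net (d-1), yields and
#'   ATP fluxes
#' @export
growth_report <- function(model, methanol, ...) {
  ss <- NULL
  out <- lapply(sort(methanol), function(C) {
    ss <<- steady_state(model, methanol = C, init = ss$reduced, ...)
    y <- tryCatch(yield_report(ss), error = function(e) list(
      ch4_per_methanol = NA_real_, co2_per_methanol = NA_real_))
    data.frame(methanol_mM = 1e3 * C, mu_per_day = per_day(ss$mu),
               mu_net_per_day = per_day(ss$mu_net),
               ch4_yield = y$ch4_per_methanol, co2_yield = y$co2_per_methanol,
               v_atp_synthase = ss$velocities[["AHA"]],
               converged = ss$converged)
  })
  do.call(rbind, out)
}
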