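# Reaction thermodynamics and velocities: reversible multiplicative
# Michaelis-Menten rate law with a thermodynamic driving-force factor, and
# diffusive exchange with the environment.

#' Gibbs free energy change of a reaction at a metabolic state
#'
#' Computes `dG = RT ln(Q/K) + cC F dpsi` where `Q` is the mass-action
#' reaction quotient over all reactants and products (clamped species enter
#' at their clamped values), `K` the equilibrium constant, and `cC` the
#' number of charges translocated out of the cytoplasm per turnover, so that
#' a cytoplasm-negative membrane potential (positive `psi`) opposes outward
#' charge translocation.
#'
#' @param rxn a reaction entry of an `mb_network` (see
#'   `model$reactions[["MCR"]]`), or a reaction id together with `model`
#' @param conc named numeric vector of concentrations (mol/L; activities for
#'   water)
#' @param psi membrane potential in V (cytoplasm-negative positive)
#' @param cell cell-parameter list of the model (needs `temperature`)
#' @param model optional `mb_network` used to look up `rxn` by id
#' @return list with `delta_g` (J/mol), `quotient`, `keq`, `charge_term`
#'   (J/mol)
#' @export
#' @examples
#' m <- build_network(fixture_barkeri())
#' st <- initial_state(m)
#' reaction_gibbs("MCR", st$conc, st$psi, m$cell)$delta_g
reaction_gibbs <- function(rxn, conc, psi = 0, cell = list(temperature = 310.15),
                           model = NULL) {
  if (is.character(rxn)) {
    if (is.null(model)) stopf("supply `model` to look reactions up by id")
    rxn <- model$reactions[[rxn]] %||% stopf("unknown reaction '%s'", rxn)
  }
  if (rxn$type != "enzyme")
    stopf("reaction %s is a pseudo-reaction without a thermodynamic rate law", rxn$id)
  s <- rxn$stoich
  cs <- conc[names(s)]
  if (any(is.na(cs)))
    stopf("state lacks species: %s",
          paste(setdiff(names(s), names(conc)), collapse = ", "))
  if (any(cs <= 0))
    stopf("non-positive concentration in quotient of %s: %s", rxn$id,
          paste(names(s)[cs <= 0], collapse = ", "))
  RT <- .GAS_CONST * cell$temperature
  lnQ <- sum(s * log(cs))
  charge <- rxn$charge_out * .FARADAY * psi
  list(delta_g = RT * (lnQ - log(rxn$keq)) + charge,
       quotient = exp(lnQ), keq = rxn$keq, charge_term = charge)
}

#' Thermodynamic driving-force factor
#'
#' `1 - exp(dG / (chi R T))`: 1 at infinite forward driving force, 0 at
#' equilibrium, negative (reverse flux) beyond it. `chi` is the
#' stoichiometric number of electrons transferred or charges translocated.
#'
#' @param delta_g Gibbs energy change, J/mol
#' @param chi stoichiometric number (>= 1)
#' @param temperature K
#' @return dimensionless factor in (-Inf, 1)
#' @export
thermo_factor <- function(delta_g, chi = 1, temperature = 310.15) {
  1 - exp(delta_g / (chi * .GAS_CONST * temperature))
}

# saturation (occupancy) factor of the generalized reversible MM law:
#   numerator   prod_S (C_S/Km_S)^|c|
#   denominator prod_S (1+C_S/Km_S)^|c| + prod_P (1+C_P/Km_P)^|c| - 1
# Species without a Km entry are treated as saturating and enter neither
# term. Reduces to the textbook (C_S/Km_S) / (1 + C_S/Km_S + C_P/Km_P)
# reversible form for one substrate and one product.
saturation_factor <- function(rxn, conc) {
  km <- rxn$km
  if (!length(km)) return(1)
  s <- rxn$stoich[names(km)]
  r <- conc[names(km)] / km
  p <- abs(s)
  sub <- s < 0
  numer <- prod(r[sub]^p[sub])
  denom <- prod((1 + r[sub])^p[sub]) + prod((1 + r[!sub])^p[!sub]) - 1
  numer / denom
}

#' Reaction velocity under the thermodynamically constrained rate law
#'
#' `v = W_prot * kcat * phi * saturation * [1 - exp(dG/(chi R T))]` in mol/s
#' per cell. The saturation factor is the generalized reversible
#' multiplicative Michaelis-Menten occupancy (see the methods vignette for
#' the multi-reactant form); velocity is exactly zero at thermodynamic
#' equilibrium and negative beyond it.
#'
#' @inheritParams reaction_gibbs
#' @return list with `v` (mol/s), `saturation_factor`, `thermo_factor`,
#'   `delta_g` (J/mol)
#' @export
reaction_velocity <- function(rxn, conc, psi = 0,
                              cell = list(temperature = 310.15, w_prot = 1),
                              model = NULL) {
  if (is.character(rxn)) {
    if (is.null(model)) stopf("supply `model` to look reactions up by id")
    rxn <- model$reactions[[rxn]] %||% stopf("unknown reaction '%s'", rxn)
  }
  th <- reaction_gibbs(rxn, conc, psi, cell)
  sat <- saturation_factor(rxn, conc)
  tf <- thermo_factor(th$delta_g, rxn$chi, cell$temperature)
  list(v = cell$w_prot * rxn$kcat * rxn$phi * sat * tf,
       saturation_factor = sat, thermo_factor = tf, delta_g = th$delta_g)
}

#' Diffusive flux of a dissolved gas into a spherical cell
#'
#' `J = 4 pi D r (C_env - C_cyto)` for a cell of radius `r`; positive values
#' are net influx. Concentrations are supplied in mol/L and converted to
#' mol/m3 internally to match the SI diffusion coefficient.
#'
#' @param d_coeff diffusion coefficient, m2/s
#' @param radius cell radius, m
#' @param c_env,c_cyto environmental and cytoplasmic concentrations, mol/L
#' @return flux in mol/s (positive into the cell)
#' @export
#' @examples
#' diffusive_flux(1e-9, 1e-6, 1e-3, 0)  # 1.2566e-14 mol/s
diffusive_flux <- function(d_coeff, radius, c_env, c_cyto) {
  4 * pi * d_coeff * radius * (c_env - c_cyto) * 1000
}
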