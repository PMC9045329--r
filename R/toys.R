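# Toy networks with closed-form steady states: oracles for the integrator
# and for finite-difference control analysis.

#' Irreversible Michaelis-Menten chain with a closed-form steady state
#'
#' Builds a linear chain `S0 -> S1 -> ... -> Sn` of `n` effectively
#' irreversible Michaelis-Menten enzymes between a clamped substrate `S0`
#' and a clamped sink `Sn`. The steady state has the closed form
#' `J = Vmax_1 s0 / (K_1 + s0)` (the first enzyme sets the flux) and
#' `s_i = K_{i+1} J / (Vmax_{i+1} - J)` for the intermediates, and the
#' scaled flux control coefficients are exactly `(1, 0, ..., 0)`.
#'
#' @param n number of enzymes (1 to 4)
#' @param vmax maximum velocities, mol/s (recycled to length `n`); the
#'   downstream capacities must exceed the entry flux
#' @param km Michaelis constants, mol/L (recycled)
#' @param s0 clamped upstream substrate concentration, mol/L
#' @return list with `model` (an `mb_network`), `flux` (mol/s),
#'   `concentrations` (named, the analytic intermediates), and
#'   `control` (analytic scaled flux control coefficients)
#' @export
#' @examples
#' toy <- toy_linear_chain(2)
#' ss <- steady_state(toy$model, t_end = 1e5)
#' ss$velocities[["E1"]] / toy$flux   # ~1
toy_linear_chain <- function(n = 2, vmax = 1e-18, km = 1e-4, s0 = 2e-4) {
  stopifnot(n >= 1, n <= 4)
  vmax <- rep_len(vmax, n); km <- rep_len(km, n)
  J <- vmax[1] * s0 / (km[1] + s0)
  if (n > 1 && any(vmax[-1] <= J))
    stopf("downstream vmax must exceed the entry flux %g", J)
  conc <- if (n > 1) km[-1] * J / (vmax[-1] - J) else numeric(0)

  rows <- list()
  add <- function(section, id, param, species = "", value, unit = "", prov = "calibrated")
    rows[[length(rows) + 1L]] <<- data.frame(section = section, id = id,
      param = param, species = species, value = as.character(value),
      unit = unit, provenance = prov)
  add("compartment", "cytoplasm", "volume", "", 1e-15, "L")
  add("compartment", "membrane", "volume", "", 1e-17, "L")
  sp <- c("S0", paste0("S", seq_len(n)))
  init <- c(s0, if (n > 1) conc else NULL, 1e-12)
  fixed <- c(TRUE, rep(FALSE, n - 1), TRUE)
  for (i in seq_along(sp)) {
    add("metabolite", sp[i], "compartment", "", "cytoplasm")
    add("metabolite", sp[i], "conc_init", "", format(init[i], digits = 12), "mol/L")
    add("metabolite", sp[i], "fixed", "", tolower(fixed[i]))
  }
  for (i in seq_len(n)) {
    id <- paste0("E", i)
    add("reaction", id, "compartment", "", "cytoplasm")
    add("reaction", id, "stoich", sp[i], -1)
    add("reaction", id, "stoich", sp[i + 1], 1)
    add("reaction", id, "km", sp[i], format(km[i], digits = 12), "mol/L")
    add("reaction", id, "kcat", "", format(vmax[i], digits = 12), "mol/g/s")
    add("reaction", id, "phi", "", 1)
    add("reaction", id, "keq", "", 1e12)   # effectively irreversible
    add("reaction", id, "chi", "", 1)
    add("reaction", id, "charge_out", "", 0)
  }
  add("cell", "cell", "radius", "", 1e-6, "m")
  add("cell", "cell", "capacitance", "", 1e-13, "F")
  add("cell", "cell", "w_prot", "", 1, "g")    # so Vmax = kcat * phi
  add("cell", "cell", "dry_mass", "", 1, "g")
  add("cell", "cell", "temperature", "", 310.15, "K")
  add("cell", "cell", "psi_init", "", 0, "V")
  model <- build_network(do.call(rbind, rows))
  list(model = model, flux = J,
       concentrations = stats::setNames(conc, if (n > 1) sp[2:n] else character(0)),
       control = stats::setNames(c(1, rep(0, n - 1)), paste0("E", seq_len(n))))
}

#' Two-step serial toy for allocation tests
#'
#' A chain `S0 <-> S1 <-> S2` of two identical *reversible* enzymes
#' (unit equilibrium constants, symmetric Michaelis constants well above
#' the operating concentrations) between clamped boundary pools held
#' slightly out of equilibrium. In this near-linear regime each enzyme acts
#' as a resistor proportional to `1/phi`, so the flux-maximizing allocation
#' of the shared proteome budget is the exactly even split. Both enzymes
#' are membrane-assigned so they form the decision set of
#' [optimize_membrane_enzymes()].
#'
#' @param kcat catalytic constants, mol/g/s (recycled to length 2)
#' @param km Michaelis constants, mol/L (recycled; applied to substrate and
#'   product alike)
#' @param s0,s2 clamped boundary concentrations, mol/L (`s0 > s2` drives
#'   forward flux)
#' @param phi initial proteome fractions (sum defines the budget)
#' @return an `mb_network`
#' @export
toy_serial_pair <- function(kcat = 2e-18, km = 1e-3, s0 = 1.1e-4, s2 = 0.9e-4,
                            phi = c(0.06, 0.04)) {
  kcat <- rep_len(kcat, 2); km <- rep_len(km, 2)
  rows <- list()
  add <- function(section, id, param, species = "", value, unit = "", prov = "calibrated")
    rows[[length(rows) + 1L]] <<- data.frame(section = section, id = id,
      param = param, species = species, value = as.character(value),
      unit = unit, provenance = prov)
  add("compartment", "cytoplasm", "volume", "", 1e-15, "L")
  add("compartment", "membrane", "volume", "", 1e-17, "L")
  sp <- c("S0", "S1", "S2")
  init <- c(s0, (s0 + s2) / 2, s2)
  fixed <- c(TRUE, FALSE, TRUE)
  for (i in seq_along(sp)) {
    add("metabolite", sp[i], "compartment", "", "cytoplasm")
    add("metabolite", sp[i], "conc_init", "", format(init[i], digits = 12), "mol/L")
    add("metabolite", sp[i], "fixed", "", tolower(fixed[i]))
  }
  for (i in 1:2) {
    id <- paste0("E", i)
    add("reaction", id, "compartment", "", "membrane")
    add("reaction", id, "stoich", sp[i], -1)
    add("reaction", id, "stoich", sp[i + 1], 1)
    add("reaction", id, "km", sp[i], format(km[i], digits = 12), "mol/L")
    add("reaction", id, "km", sp[i + 1], format(km[i], digits = 12), "mol/L")
    add("reaction", id, "kcat", "", format(kcat[i], digits = 12), "mol/g/s")
    add("reaction", id, "phi", "", phi[i])
    add("reaction", id, "keq", "", 1)
    add("reaction", id, "chi", "", 1)
    add("reaction", id, "charge_out", "", 0)
  }
  add("cell", "cell", "radius", "", 1e-6, "m")
  add("cell", "cell", "capacitance", "", 1e-13, "F")
  add("cell", "cell", "w_prot", "", 1, "g")
  add("cell", "cell", "dry_mass", "", 1, "g")
  add("cell", "cell", "temperature", "", 310.15, "K")
  add("cell", "cell", "psi_init", "", 0, "V")
  add("cell", "cell", "phi_membrane_total", "", sum(phi))
  build_network(do.call(rbind, rows))
}
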