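# Steady-state validation diagnostics: electron-flux partition between the
# hydrogen-cycling and direct F420-oxidation routes, the distribution of
# reaction Gibbs energies, and the metabolite-vs-Michaelis-constant census.

#' Partition of oxidation-to-reduction electron flux
#'
#' Electrons released by methyl-group oxidation reach the methanophenazine
#' pool either through hydrogen cycling (F420-reducing and Ech hydrogenases
#' produce H2, the methanophenazine-dependent hydrogenase re-oxidizes it) or
#' directly through the membrane F420H2 dehydrogenase. The share of each
#' route is the fraction of the methanophenazine-reducing electron flux it
#' carries.
#'
#' @param ss an `mb_steady_state` of the default network (reactions VHT and
#'   FPO present)
#' @return list with `h2_share`, `f420_share` (sum to 1) and the absolute
#'   electron fluxes (mol 2e-pairs per s)
#' @export
electron_flux_partition <- function(ss) {
  v <- ss$velocities
  if (!all(c("VHT", "FPO") %in% names(v)))
    stopf("state lacks the VHT/FPO electron-routing reactions")
  tot <- v[["VHT"]] + v[["FPO"]]
  if (tot <= 0) stopf("no net electron flux at this state")
  list(h2_share = v[["VHT"]] / tot, f420_share = v[["FPO"]] / tot,
       via_h2 = v[["VHT"]], via_f420 = v[["FPO"]])
}

#' Gibbs free energy census of the enzyme reactions
#'
#' @param ss an `mb_steady_state`
#' @return data.frame with `reaction`, `delta_g_kj` (kJ/mol), `velocity`
#'   (mol/s), sorted by Gibbs energy
#' @export
delta_g_census <- function(ss) {
  k <- !is.na(ss$delta_g)
  out <- data.frame(reaction = names(ss$delta_g)[k],
                    delta_g_kj = unname(ss$delta_g[k]) / 1e3,
                    velocity = unname(ss$velocities[k]), row.names = NULL)
  out[order(out$delta_g_kj), ]
}

#' Census of metabolite concentrations against Michaelis constants
#'
#' Every (metabolite, reaction) pair with a Michaelis constant contributes
#' one point (a metabolite engaging several enzymes is counted once per
#' enzyme); the summary is the fraction of pairs whose steady-state
#' concentration exceeds the constant.
#'
#' @param ss an `mb_steady_state`
#' @param model the `mb_network` the state belongs to
#' @return list with `fraction` (in 0..1) and `table` (data.frame with
#'   `reaction`, `species`, `conc`, `km`, `above`)
#' @export
km_census <- function(ss, model) {
  rows <- list()
  for (rx in Filter(function(r) r$type == "enzyme", model$reactions))
    for (s in names(rx$km))
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = rx$id, species = s, conc = ss$state$conc[[s]],
        km = rx$km[[s]], above = ss$state$conc[[s]] > rx$km[[s]])
  tab <- do.call(rbind, rows)
  list(fraction = mean(tab$above), table = tab)
}

#' One-call validation summary of a steady state
#'
#' Bundles the validation diagnostics: membrane potential, dissolved H2,
#' product yields, electron-flux partition, the Gibbs-energy range and the
#' concentration-vs-Km census.
#'
#' @inheritParams km_census
#' @return named list of diagnostics
#' @export
validation_summary <- function(ss, model) {
  dg <- delta_g_census(ss)
  ef <- electron_flux_partition(ss)
  yl <- yield_report(ss)
  list(psi_mV = 1e3 * ss$state$psi,
       h2_uM = 1e6 * ss$state$conc[["H2"]],
       ch4_per_methanol = yl$ch4_per_methanol,
       co2_per_methanol = yl$co2_per_methanol,
       h2_electron_share = ef$h2_share,
       delta_g_min_kj = min(dg$delta_g_kj),
       delta_g_max_kj = max(dg$delta_g_kj),
       km_census_fraction = km_census(ss, model)$fraction,
       mu_per_day = per_day(ss$mu))
}
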