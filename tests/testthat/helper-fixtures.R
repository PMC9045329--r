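# Shared, lazily computed test fixtures. The default-model growth curve and
# reference steady state are expensive, so they are built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

fixture_model <- function() memo("model", build_network(fixture_barkeri()))

# reference steady state at 100 mM methanol, Newton-polished
fixture_ss100 <- function() memo("ss100", {
  steady_state(fixture_model(), methanol = 0.1, polish = TRUE)
})

# steady-state growth curve, 16 points per decade, 1 uM .. 1 M
fixture_curve <- function() memo("curve", {
  growth_curve(fixture_model(), per_decade = 16)
})

fixture_fit <- function() memo("fit", monod_fit(fixture_curve()))

# warm-started steady state at arbitrary methanol (continued from 100 mM)
fixture_ss_at <- function(C) {
  key <- paste0("ss_", format(C, digits = 8))
  memo(key, steady_state(fixture_model(), methanol = C, polish = TRUE))
}

# tiny closed two-species system (A <-> B, nothing clamped): for exact mass
# conservation along trajectories
closed_pair_model <- function(keq = 2) {
  rows <- list()
  add <- function(section, id, param, species = "", value, unit = "", prov = "calibrated")
    rows[[length(rows) + 1L]] <<- data.frame(section = section, id = id,
      param = param, species = species, value = as.character(value),
      unit = unit, provenance = prov)
  add("compartment", "cytoplasm", "volume", "", 1e-15, "L")
  add("compartment", "membrane", "volume", "", 1e-17, "L")
  for (s in c("A", "B")) {
    add("metabolite", s, "compartment", "", "cytoplasm")
    add("metabolite", s, "conc_init", "", if (s == "A") 2e-4 else 1e-5, "mol/L")
    add("metabolite", s, "fixed", "", "false")
  }
  add("reaction", "E1", "compartment", "", "cytoplasm")
  add("reaction", "E1", "stoich", "A", -1)
  add("reaction", "E1", "stoich", "B", 1)
  add("reaction", "E1", "km", "A", 1e-4, "mol/L")
  add("reaction", "E1", "km", "B", 1e-4, "mol/L")
  add("reaction", "E1", "kcat", "", 1e-18, "mol/g/s")
  add("reaction", "E1", "phi", "", 1)
  add("reaction", "E1", "keq", "", keq)
  add("reaction", "E1", "chi", "", 1)
  add("reaction", "E1", "charge_out", "", 0)
  add("cell", "cell", "radius", "", 1e-6, "m")
  add("cell", "cell", "capacitance", "", 1e-13, "F")
  add("cell", "cell", "w_prot", "", 1, "g")
  add("cell", "cell", "dry_mass", "", 1, "g")
  add("cell", "cell", "temperature", "", 310.15, "K")
  add("cell", "cell", "psi_init", "", 0, "V")
  build_network(do.call(rbind, rows))
}
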