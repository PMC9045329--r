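# Herbert-Pirt coupling and yield accounting.

test_that("maintenance flux is specific rate times dry mass", {
  expect_equal(maintenance_flux(list(maintenance_atp = 0, dry_mass = 2e-12)), 0)
  expect_equal(maintenance_flux(list(maintenance_atp = 3e-7, dry_mass = 2e-12)),
               6e-19)
})

test_that("growth fluxes follow the ATP-surplus bookkeeping", {
  bio <- list(atp_per_g = 0.14, fdred_per_g = 0.011, f420h2_per_g = 0.011,
              accoa_per_g = 0.014)
  cell <- list(dry_mass = 2e-12)
  # maintenance-only regime: no biomass, zero net growth
  g0 <- growth_rate_from_fluxes(1e-18, 1e-18, bio, cell)
  expect_equal(g0$biomass_flux, 0)
  expect_equal(g0$mu_net, 0)
  expect_gt(g0$mu, 0)
  # the 0.14 mol ATP / g stoichiometry: unit surplus gives 1/0.14 g biomass
  g1 <- growth_rate_from_fluxes(0.14 + 0.05, 0.05, bio, cell)
  expect_equal(g1$biomass_flux, 1)
  expect_equal(unname(g1$drains[["AcCoA"]]), 0.014)
  expect_equal(unname(g1$drains[["Fd_red"]]), 0.011)
  expect_error(growth_rate_from_fluxes(1, 0, list(atp_per_g = 0), cell),
               "atp_per_g")
})

test_that("reference-state yields fall below the catabolic stoichiometry", {
  y <- yield_report(fixture_ss100())
  expect_lt(y$ch4_per_methanol, 0.75)
  expect_lt(y$co2_per_methanol, 0.25)
  expect_gt(y$carbon_to_biomass, 0)
})

test_that("disabling biosynthesis recovers the pure catabolic 1/4 : 3/4 split", {
  m <- fixture_model()
  m$biomass$fdred_per_g <- 0
  m$biomass$f420h2_per_g <- 0
  m$biomass$accoa_per_g <- 0
  m$reactions$BIOMASS$stoich[c("Fd_red", "Fd_ox", "F420H2", "F420",
                               "AcCoA", "CoA")] <- 0
  m$reactions$ACS$phi <- 0
  ss <- steady_state(m, methanol = 0.1, polish = TRUE)
  y <- yield_report(ss)
  expect_equal(y$ch4_per_methanol, 0.75, tolerance = 1e-3)
  expect_equal(y$co2_per_methanol, 0.25, tolerance = 1e-3)
})

test_that("yield reporting requires a methanol influx", {
  ss <- fixture_ss100()
  ss$fluxes[["DIFF_CH3OH"]] <- 0
  expect_error(yield_report(ss), "influx")
})

test_that("carbon closes at steady state", {
  expect_lt(abs(carbon_balance(fixture_ss100())), 1e-6)
})

test_that("net growth decomposes as gross minus the maintenance-equivalent rate", {
  ss <- fixture_ss100()
  m <- fixture_model()
  m_rate <- maintenance_flux(m$cell) / (m$biomass$atp_per_g * m$cell$dry_mass)
  expect_equal(ss$mu - ss$mu_net, m_rate, tolerance = 1e-12)
})
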