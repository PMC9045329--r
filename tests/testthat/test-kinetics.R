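# Reaction thermodynamics and the reversible rate law.

RT310 <- 8.3145 * 310.15

test_that("the Gibbs energy decomposes into mass-action and charge terms", {
  m <- fixture_model()
  st <- initial_state(m)
  # equilibrium: force Q = K by scaling keq
  rx <- m$reactions$MCR
  g0 <- reaction_gibbs(rx, st$conc, psi = 0, m$cell)
  rx_eq <- rx; rx_eq$keq <- g0$quotient
  expect_equal(reaction_gibbs(rx_eq, st$conc, 0, m$cell)$delta_g, 0,
               tolerance = 1e-9)
  # Q = 10 K at zero charge -> RT ln 10
  rx10 <- rx; rx10$keq <- g0$quotient / 10
  expect_equal(reaction_gibbs(rx10, st$conc, 0, m$cell)$delta_g,
               RT310 * log(10), tolerance = 1e-9)   # 5.938 kJ/mol
  # charge term alone: c_C = 2 at 135 mV is 26.05 kJ/mol
  rx2 <- rx_eq; rx2$charge_out <- 2
  expect_equal(reaction_gibbs(rx2, st$conc, 0.135, m$cell)$delta_g,
               2 * 96485 * 0.135, tolerance = 1e-9)
})

test_that("non-positive concentrations in the quotient raise a domain error", {
  m <- fixture_model()
  st <- initial_state(m)
  st$conc[["CH3_CoM"]] <- 0
  expect_error(reaction_gibbs("MCR", st$conc, 0, m$cell, model = m), "CH3_CoM")
})

test_that("velocity is half-maximal at C = Km with full driving force", {
  toy <- toy_linear_chain(1, vmax = 1e-18, km = 1e-4, s0 = 1e-4)
  rx <- toy$model$reactions$E1
  conc <- c(S0 = 1e-4, S1 = 1e-12)
  v <- reaction_velocity(rx, conc, 0, toy$model$cell)
  expect_equal(v$v, 0.5e-18, tolerance = 1e-6)
  # saturation limit: C >> Km approaches Vmax
  conc_sat <- c(S0 = 1, S1 = 1e-12)
  expect_equal(reaction_velocity(rx, conc_sat, 0, toy$model$cell)$v, 1e-18,
               tolerance = 1e-3)
})

test_that("velocity vanishes exactly at thermodynamic equilibrium", {
  m <- closed_pair_model(keq = 2)
  rx <- m$reactions$E1
  conc <- c(A = 1e-4, B = 2e-4)   # Q = K
  v <- reaction_velocity(rx, conc, 0, m$cell)
  expect_equal(v$thermo_factor, 0, tolerance = 1e-12)
  expect_equal(v$v, 0, tolerance = 1e-30)
})

test_that("velocity sign follows the thermodynamic sign law (property)", {
  m <- closed_pair_model(keq = 3)
  rx <- m$reactions$E1
  set.seed(42)
  for (i in 1:200) {
    conc <- c(A = 10^stats::runif(1, -7, -2), B = 10^stats::runif(1, -7, -2))
    v <- reaction_velocity(rx, conc, 0, m$cell)
    expect_lte(v$v * v$delta_g, 0)
    if (v$delta_g != 0) expect_true(v$v != 0)
    if (v$delta_g <= 0) expect_lte(abs(v$thermo_factor), 1)
  }
})

test_that("velocity is monotone in substrate at fixed driving force", {
  toy <- toy_linear_chain(1)
  rx <- toy$model$reactions$E1
  vs <- vapply(10^seq(-7, -2, 0.25), function(s)
    reaction_velocity(rx, c(S0 = s, S1 = 1e-12), 0, toy$model$cell)$v, 0)
  expect_true(all(diff(vs) > 0))
})

test_that("the thermodynamic factor has the correct limits", {
  expect_equal(thermo_factor(-1e9, 1), 1)
  # near equilibrium the factor is linear: 1 - exp(dG/chi RT) ~ -dG/(chi RT),
  # recovering mass-action linearity (first-order Taylor)
  dg <- -1
  expect_equal(thermo_factor(dg, 1, 310.15), -dg / RT310, tolerance = 1e-3)
  expect_equal(thermo_factor(0, 2), 0)
})

test_that("diffusive flux follows 4 pi D r (Cenv - Ccyto) and is antisymmetric", {
  expect_equal(diffusive_flux(1e-9, 1e-6, 1e-3, 0), 1.2566e-14,
               tolerance = 1e-4)
  expect_identical(diffusive_flux(1e-9, 1e-6, 5e-4, 5e-4), 0)
  expect_equal(diffusive_flux(1e-9, 1e-6, 0, 1e-3),
               -diffusive_flux(1e-9, 1e-6, 1e-3, 0))
})
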