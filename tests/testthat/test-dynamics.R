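# ODE assembly, conservation, integration and steady-state location.

test_that("the membrane-potential derivative is F v cC / Cm", {
  # one charge-translocating reaction at v = 1e-18 mol/s with Cm = 1e-13 F
  # gives dpsi/dt = 96485e-18/1e-13 = 0.96485 V/s
  toy <- toy_linear_chain(1, vmax = 2e-18, km = 1e-4, s0 = 1e-4)  # v = 1e-18
  m <- toy$model
  m$reactions$E1$charge_out <- 1
  odes <- assemble_odes(m)
  d <- odes$func(0, odes$y0, NULL)[[1]]
  expect_equal(unname(d[length(d)]), 0.96485, tolerance = 1e-6)
})

test_that("mass balance signs are correct for a single reaction", {
  m <- closed_pair_model()
  odes <- assemble_odes(m)
  d <- odes$func(0, odes$y0, NULL)[[1]]
  v <- eval_velocities(odes$cc, full_conc(odes$cc, odes$y0), 0)$v
  V <- m$compartments$volume[1]
  expect_equal(unname(d[1]), -v[1] / V)   # A consumed
  expect_equal(unname(d[2]), v[1] / V)    # B produced
})

test_that("zero-capacity models have zero derivatives", {
  m <- fixture_model()
  for (id in names(m$reactions))
    if (m$reactions[[id]]$type == "enzyme") m$reactions[[id]]$phi <- 0
  m$cell$maintenance_atp <- 0
  # gases equilibrate with the environment; clamp them to their ambient
  # values so every flux is zero at the initial state
  for (s in c("CH3OH_c", "CO2_c", "CH4_c"))
    m$species$conc_init[m$species$id == s] <-
      m$species$conc_init[m$species$id == sub("_c", "_e", s)]
  odes <- assemble_odes(m)
  d <- odes$func(0, odes$y0, NULL)[[1]]
  expect_true(all(abs(d) < 1e-25))
})

test_that("a zero-length integration returns the initial state", {
  m <- closed_pair_model()
  tr <- integrate_network(m, t_end = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$A, 2e-4)
})

test_that("a closed system conserves total mass along the trajectory", {
  m <- closed_pair_model()
  tr <- integrate_network(m, t_end = 1e5)
  tot <- tr$A + tr$B
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-10)
})

test_that("moiety pools are conserved along default-model trajectories", {
  m <- fixture_model()
  # start displaced within the conserving manifold
  odes <- assemble_odes(set_methanol(m, 0.01))
  y0 <- odes$y0
  y0[["HS_CoM"]] <- y0[["HS_CoM"]] * 1.5
  y0[["CH3_CoM"]] <- y0[["CH3_CoM"]] * 0.2
  tr <- integrate_network(set_methanol(m, 0.01), times = 10^seq(-2, 4, 0.5),
                          init = y0)
  for (i in seq_len(nrow(tr))) {
    conc <- full_conc(odes$cc, unlist(tr[i, -1]))
    names(conc) <- m$species$id
    for (p in m$moieties) {
      s <- sum(conc[p$members])
      expect_lt(abs(s / p$total - 1), 1e-9)
    }
  }
})

test_that("the toy chain converges to its closed-form steady state", {
  toy <- toy_linear_chain(3, vmax = c(1e-18, 2.5e-18, 1.6e-18))
  ss <- steady_state(toy$model, t_end = 1e6)
  expect_true(ss$converged)
  expect_equal(unname(ss$velocities[["E1"]]), toy$flux, tolerance = 1e-6)
  for (s in names(toy$concentrations))
    expect_equal(unname(ss$state$conc[[s]]), unname(toy$concentrations[[s]]),
                 tolerance = 1e-6)
})

test_that("the default steady state converges and is reported in volts", {
  ss <- fixture_ss100()
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-8)
  expect_gt(ss$state$psi, 0.1)
  expect_lt(ss$state$psi, 0.2)
})

test_that("the steady state is independent of the initialization", {
  m <- set_methanol(fixture_model(), 0.1)
  ref <- fixture_ss100()
  odes <- assemble_odes(m)
  set.seed(11)
  for (rep in 1:3) {
    y0 <- odes$y0
    k <- seq_along(y0) != length(y0)   # perturb concentrations, not psi
    y0[k] <- y0[k] * exp(stats::rnorm(sum(k), 0, 0.3))
    # re-impose moiety conservation by rescaling members of each pool
    conc <- full_conc(odes$cc, y0); names(conc) <- m$species$id
    for (p in m$moieties) {
      fac <- p$total / sum(conc[p$members])
      for (mm in p$members) if (mm %in% names(y0))
        y0[[mm]] <- y0[[mm]] * fac
    }
    ss <- steady_state(m, polish = TRUE, init = y0)
    expect_true(ss$converged)
    expect_equal(ss$mu, ref$mu, tolerance = 1e-6)
    expect_equal(ss$state$psi, ref$state$psi, tolerance = 1e-6)
  }
})

test_that("steady-state flux balance closes for every free metabolite", {
  ss <- fixture_ss100()
  m <- fixture_model()
  cc <- ss$cc
  d <- reduced_rhs(cc, ss$reduced)
  expect_lt(max(abs(d) / pmax(abs(ss$reduced), 1e-12)), 1e-8)
})

test_that("trajectories and steady states export as tidy tables", {
  ss <- fixture_ss100()
  tab <- steady_state_table(ss)
  expect_true(all(c("kind", "id", "quantity", "value", "unit") %in% names(tab)))
  expect_equal(sum(tab$kind == "species"), 35)
  expect_equal(sum(tab$quantity == "velocity"), 18)
})
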