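# Control analysis against closed-form oracles on toy networks.

test_that("a single enzyme carries all control", {
  toy <- toy_linear_chain(1)
  eps <- flux_control_coefficient(toy$model, "E1", flux = "E1")
  expect_equal(eps, 1, tolerance = 1e-3)
})

test_that("finite-difference coefficients match the analytic chain values", {
  toy <- toy_linear_chain(2, vmax = c(1e-18, 1.8e-18))
  base <- steady_state(toy$model, polish = TRUE)
  for (id in names(toy$control)) {
    eps <- flux_control_coefficient(toy$model, id, flux = "E2", base = base)
    expect_equal(eps, unname(toy$control[[id]]), tolerance = 1e-3)
  }
})

test_that("scaling all capacities scales the flux and leaves control unchanged", {
  toy1 <- toy_linear_chain(2, vmax = c(1e-18, 1.8e-18))
  toy2 <- toy_linear_chain(2, vmax = 2 * c(1e-18, 1.8e-18))
  ss1 <- steady_state(toy1$model, polish = TRUE)
  ss2 <- steady_state(toy2$model, polish = TRUE)
  expect_equal(ss2$velocities[["E2"]] / ss1$velocities[["E2"]], 2,
               tolerance = 1e-6)
  e1 <- flux_control_coefficient(toy1$model, "E1", flux = "E2", base = ss1)
  e2 <- flux_control_coefficient(toy2$model, "E1", flux = "E2", base = ss2)
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("the summation theorem holds on the toy chain", {
  toy <- toy_linear_chain(3, vmax = c(1e-18, 2.2e-18, 1.7e-18))
  base <- steady_state(toy$model, polish = TRUE)
  s <- sum(vapply(paste0("E", 1:3), function(id)
    flux_control_coefficient(toy$model, id, flux = "E3", base = base), 0))
  expect_equal(s, 1, tolerance = 0.02)
})

test_that("halving the perturbation changes fixture coefficients by < 5%", {
  m <- set_methanol(fixture_model(), 1e-3)
  base <- fixture_ss_at(1e-3)
  for (id in c("MTA", "MCR")) {
    e1 <- flux_control_coefficient(m, id, delta = 0.01, base = base)
    e2 <- flux_control_coefficient(m, id, delta = 0.005, base = base)
    expect_lt(abs(e2 / e1 - 1), 0.05)
  }
})

test_that("a moiety pool saturating its only consumer has no control", {
  # B is held far above the consumer Km through a large conserved pool, so
  # rescaling the pool leaves the flux unchanged
  toy <- toy_linear_chain(2, vmax = c(1e-18, 1.8e-18))
  tab <- toy$model$params
  add <- data.frame(section = "moiety", id = "Spool",
                    param = c("member", "total"), species = c("S1", ""),
                    value = c("", "1e-2"), unit = "", provenance = "calibrated")
  tab$value[tab$id == "S1" & tab$param == "conc_init"] <- "1e-2"
  m <- build_network(rbind(tab, add))
  eps <- response_coefficient(m, "Spool", flux = "E2")
  expect_lt(abs(eps), 1e-2)
})

test_that("control profiles tabulate all components with a summation record", {
  toy <- toy_linear_chain(2, vmax = c(1e-18, 1.8e-18))
  pr <- control_profile(toy$model, grid = NULL, flux = "E2")
  expect_s3_class(pr, "mb_control_profile")
  expect_setequal(unique(pr$component), c("E1", "E2"))
  s <- attr(pr, "summation")
  expect_equal(s$summation, 1, tolerance = 0.02)
  f <- tempfile(fileext = ".tsv")
  write_profile(pr, f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.delim(f)), nrow(pr))
})
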