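# Proteome allocation by growth/flux maximization.

test_that("a symmetric serial pair is split evenly at the optimum", {
  toy <- toy_serial_pair()
  opt <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]], maxit = 500))
  expect_equal(unname(opt$phi[1]), 0.05, tolerance = 1e-3)
  expect_equal(unname(opt$phi[2]), 0.05, tolerance = 1e-3)
  expect_gte(opt$value, opt$start_value)
})

test_that("a rate-limiting enzyme attracts nearly the whole budget", {
  toy <- toy_serial_pair(kcat = c(2e-18, 2e-15))   # E2 1000x faster per phi
  opt <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]], maxit = 500))
  expect_gt(unname(opt$phi[1]), 0.9 * 0.1)
})

test_that("the budget constraint holds exactly at the returned point", {
  toy <- toy_serial_pair()
  opt <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]], maxit = 200))
  expect_equal(sum(opt$phi), 0.10, tolerance = 1e-12)
  expect_true(all(opt$phi >= 0))
})

test_that("random starts are deterministic given the seed", {
  toy <- toy_serial_pair()
  o1 <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]],
    start = "random", seed = 9, maxit = 50))
  o2 <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]],
    start = "random", seed = 9, maxit = 50))
  expect_identical(o1$phi, o2$phi)
})

test_that("the toy optimum beats random feasible allocations", {
  toy <- toy_serial_pair()
  opt <- suppressWarnings(optimize_membrane_enzymes(
    toy, objective = function(ss) ss$velocities[["E2"]], maxit = 500))
  set.seed(21)
  for (k in 1:20) {
    w <- stats::rexp(2); phi <- 0.10 * w / sum(w)
    m2 <- toy
    m2$reactions$E1$phi <- phi[1]; m2$reactions$E2$phi <- phi[2]
    ss <- steady_state(m2, polish = TRUE)
    expect_gte(opt$value * (1 + 1e-9), ss$velocities[["E2"]])
  }
})
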