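# Network data model: construction, validation, parameter-table round trips.

test_that("the default model has the expected network dimensions", {
  m <- fixture_model()
  expect_equal(nrow(m$species), 35)
  expect_length(m$reactions, 18)                      # 16 enzymes + 2 pseudo
  expect_equal(nrow(m$diffusions), 3)                 # 21 processes in total
  enz <- Filter(function(r) r$type == "enzyme", m$reactions)
  expect_length(enz, 16)
  expect_length(membrane_enzymes(m), 7)
  expect_length(Filter(function(r) r$compartment == "cytoplasm", enz), 9)
  expect_length(m$moieties, 8)
})

test_that("membrane-enzyme proteome fractions sum to the membrane budget", {
  m <- fixture_model()
  phis <- vapply(membrane_enzymes(m), function(id) m$reactions[[id]]$phi, 0)
  expect_equal(sum(phis), m$cell$phi_membrane_total, tolerance = 1e-12)
  expect_equal(m$cell$phi_membrane_total, 0.10)
})

test_that("printed constants are carried by the fixture table", {
  tab <- fixture_barkeri()
  row <- function(id, param, species = NULL) {
    k <- tab$id == id & tab$param == param
    if (!is.null(species)) k <- k & tab$species == species
    as.numeric(tab$value[k])
  }
  expect_equal(row("MCR", "km", "HS_CoB"), 5.9e-5)        # K_m,CoB
  expect_equal(row("CoB", "total"), 1.7e-3)               # CoB moiety pool
  expect_equal(row("ATP", "conc_init"), 0.01)
  expect_equal(row("ADP", "conc_init"), 0.001)
  expect_equal(row("Pi", "conc_init"), 0.01)
  expect_equal(row("biomass", "atp_per_g"), 0.14)
  expect_equal(row("biomass", "accoa_per_g"), 0.014)
  expect_equal(row("MTA", "km", "CH3OH_c"), 0.05)
})

test_that("a deleted Michaelis constant is reported against its reaction", {
  tab <- fixture_barkeri()
  drop <- tab$id == "MCR" & tab$param == "kcat"
  expect_error(build_network(tab[!drop, ]), "MCR")
})

test_that("the validator reports violations without throwing", {
  m <- fixture_model()
  expect_equal(nrow(validate_network(m)), 0)

  bad <- m
  bad$species$conc_init[bad$species$id == "H2"] <- -1e-6
  v <- validate_network(bad)
  expect_true(any(grepl("negative", v$message)))

  bad2 <- m
  bad2$moieties$CoM$total <- bad2$moieties$CoM$total * 2
  v2 <- validate_network(bad2)
  expect_true(any(grepl("CoM", v2$where)))
})

test_that("initial moiety member concentrations sum to the pool totals", {
  m <- fixture_model()
  for (p in m$moieties) {
    s <- sum(m$species$conc_init[match(p$members, m$species$id)])
    expect_equal(s, p$total, tolerance = 1e-12)
  }
})

test_that("the parameter table round-trips through TSV unchanged", {
  tab <- fixture_barkeri()
  f <- tempfile(fileext = ".tsv")
  write_params(tab, f)
  tab2 <- read_params(f)
  expect_equal(tab2, tab)
  m1 <- build_network(tab); m2 <- build_network(tab2)
  expect_equal(m2$reactions, m1$reactions)
  expect_equal(m2$species, m1$species)
})

test_that("parameter jitter is deterministic per seed and protects printed rows", {
  tab <- fixture_barkeri()
  expect_equal(perturb_params(tab, seed = 3, cv = 0), tab)
  j1 <- perturb_params(tab, seed = 3, cv = 0.1)
  j2 <- perturb_params(tab, seed = 3, cv = 0.1)
  expect_equal(j1, j2)
  j3 <- perturb_params(tab, seed = 4, cv = 0.1)
  expect_false(isTRUE(all.equal(j1$value, j3$value)))
  printed <- tab$provenance == "printed" & tab$param %in% c("km", "kcat", "keq")
  expect_equal(j1$value[printed], tab$value[printed])
})
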