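# SBML Level 3 interchange.

test_that("the default model round-trips through SBML field by field", {
  m <- fixture_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_equal(m2$species$id, m$species$id)
  expect_equal(m2$species$conc_init, m$species$conc_init, tolerance = 1e-14)
  expect_equal(m2$species$fixed, m$species$fixed)
  expect_equal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    a <- m$reactions[[id]]; b <- m2$reactions[[id]]
    expect_equal(b$stoich[names(a$stoich)], a$stoich)
    expect_equal(b$km[names(a$km)], a$km, tolerance = 1e-14)
    if (a$type == "enzyme") {
      expect_equal(b$kcat, a$kcat, tolerance = 1e-14)
      expect_equal(b$keq, a$keq, tolerance = 1e-14)
      expect_equal(b$phi, a$phi)
      expect_equal(b$chi, a$chi)
      expect_equal(b$charge_out, a$charge_out)
    }
  }
  expect_equal(m2$moieties, m$moieties)
  expect_equal(m2$diffusions, m$diffusions, tolerance = 1e-14)
  expect_equal(m2$cell[order(names(m2$cell))],
               m$cell[order(names(m$cell))], tolerance = 1e-14)
  # provenance flags survive
  expect_equal(sort(unique(m2$params$provenance)),
               sort(unique(m$params$provenance)))
})

test_that("toy models export to SBML and solve identically after reload", {
  toy <- toy_linear_chain(2, vmax = c(1e-18, 1.8e-18))
  f <- tempfile(fileext = ".xml")
  write_sbml(toy$model, f)
  m2 <- read_sbml(f)
  ss <- steady_state(m2, t_end = 1e6)
  expect_equal(unname(ss$velocities[["E1"]]), toy$flux, tolerance = 1e-6)
})

test_that("a missing chi annotation defaults to 1 with a warning", {
  toy <- toy_linear_chain(1)
  f <- tempfile(fileext = ".xml")
  write_sbml(toy$model, f)
  doc <- xml2::read_xml(f)
  xml2::xml_ns_strip(doc)
  chi <- xml2::xml_find_first(doc, "//localParameter[@id='chi']")
  xml2::xml_remove(chi)
  f2 <- tempfile(fileext = ".xml")
  xml2::write_xml(doc, f2)
  expect_warning(m2 <- read_sbml(f2), "chi")
  expect_equal(m2$reactions$E1$chi, 1)
})

test_that("malformed files raise parse errors", {
  f <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", f)
  expect_error(read_sbml(f), "parse")
})
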