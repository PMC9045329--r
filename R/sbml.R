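# SBML Level 3 import/export. Covers the constructs this package uses:
# compartments, species (with boundary/constant flags), reactions with
# stoichiometry and local kinetic parameters (kcat, phi, keq, chi,
# charge_out, per-species km), and custom annotations for moiety pools,
# diffusion processes, cell geometry and biomass stoichiometry. Written
# directly with xml2; round-trips files produced by this package.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MK_NS <- "https://methanokin.r-pkg/annotations"

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a network model as SBML Level 3
#'
#' @param model an `mb_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
#' @examples
#' \donttest{
#' m <- build_network(fixture_barkeri())
#' f <- tempfile(fileext = ".xml")
#' write_sbml(m, f)
#' m2 <- read_sbml(f)
#' }
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = .SBML_NS, level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "methanokin_model")

  ann <- xml2::xml_add_child(mdl, "annotation")
  mk <- xml2::xml_add_child(ann, "methanokin", xmlns = .MK_NS)
  cellx <- xml2::xml_add_child(mk, "cell")
  for (p in names(model$cell))
    xml2::xml_set_attr(cellx, p, format(model$cell[[p]], digits = 17))
  biox <- xml2::xml_add_child(mk, "biomassStoichiometry")
  for (p in names(model$biomass))
    xml2::xml_set_attr(biox, p, format(model$biomass[[p]], digits = 17))
  moix <- xml2::xml_add_child(mk, "moieties")
  for (pool in model$moieties) {
    px <- xml2::xml_add_child(moix, "pool", id = pool$id,
                              total = format(pool$total, digits = 17))
    for (mm in pool$members) xml2::xml_add_child(px, "member", species = mm)
  }
  if (!is.null(model$diffusions)) {
    difx <- xml2::xml_add_child(mk, "diffusion")
    for (i in seq_len(nrow(model$diffusions)))
      xml2::xml_add_child(difx, "process",
        id = model$diffusions$id[i], species = model$diffusions$species[i],
        envSpecies = model$diffusions$env_species[i],
        dCoeff = format(model$diffusions$d_coeff[i], digits = 17))
  }
  provx <- xml2::xml_add_child(mk, "provenance")
  prov <- model$params
  if (!is.null(prov)) {
    keep <- prov$provenance == "printed"
    for (i in which(keep))
      xml2::xml_add_child(provx, "printed", section = prov$section[i],
                          id = prov$id[i], param = prov$param[i],
                          species = prov$species[i])
  }

  cmps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments)))
    xml2::xml_add_child(cmps, "compartment",
      id = sbml_id(model$compartments$id[i]),
      size = format(model$compartments$volume[i], digits = 17),
      constant = "true", spatialDimensions = "3")

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    xml2::xml_add_child(sps, "species", id = sbml_id(s$id), name = s$id,
      compartment = sbml_id(s$compartment),
      initialConcentration = format(s$conc_init, digits = 17),
      boundaryCondition = tolower(s$fixed), constant = "false",
      hasOnlySubstanceUnits = "false")
  }

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rx in model$reactions) {
    rnode <- xml2::xml_add_child(rxs, "reaction", id = sbml_id(rx$id),
                                 reversible = "true")
    xml2::xml_set_attr(rnode, "type", rx$type)
    xml2::xml_set_attr(rnode, "compartment", rx$compartment)
    rlist <- xml2::xml_add_child(rnode, "listOfReactants")
    plist <- xml2::xml_add_child(rnode, "listOfProducts")
    for (s in names(rx$stoich)) {
      coef <- rx$stoich[[s]]
      xml2::xml_add_child(if (coef < 0) rlist else plist, "speciesReference",
        species = sbml_id(s), stoichiometry = format(abs(coef), digits = 17),
        constant = "true")
    }
    if (rx$type == "enzyme") {
      kl <- xml2::xml_add_child(rnode, "kineticLaw")
      lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
      addp <- function(id, value)
        xml2::xml_add_child(lp, "localParameter", id = id,
                            value = format(value, digits = 17))
      addp("kcat", rx$kcat); addp("phi", rx$phi); addp("keq", rx$keq)
      addp("chi", rx$chi); addp("charge_out", rx$charge_out)
      for (s in names(rx$km)) addp(paste0("km_", sbml_id(s)), rx$km[[s]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network model from SBML Level 3
#'
#' Reads files written by [write_sbml()] (and minimal SBML L3 documents
#' using the same constructs). A reaction without a `chi` local parameter is
#' loaded with `chi = 1` and a warning.
#'
#' @param path SBML file
#' @return an `mb_network`
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("cannot parse SBML file %s: %s",
                                            path, conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stopf("%s: no <model> element", path)

  rows <- list()
  add <- function(section, id, param, species = "", value, unit = "",
                  prov = "calibrated")
    rows[[length(rows) + 1L]] <<- data.frame(section = section, id = id,
      param = param, species = species, value = as.character(value),
      unit = unit, provenance = prov)

  for (nd in xml2::xml_find_all(mdl, ".//listOfCompartments/compartment"))
    add("compartment", xml2::xml_attr(nd, "id"), "volume", "",
        xml2::xml_attr(nd, "size"))

  for (nd in xml2::xml_find_all(mdl, ".//listOfSpecies/species")) {
    id <- xml2::xml_attr(nd, "name")
    if (is.na(id)) id <- xml2::xml_attr(nd, "id")
    add("metabolite", id, "compartment", "", xml2::xml_attr(nd, "compartment"))
    ic <- xml2::xml_attr(nd, "initialConcentration")
    add("metabolite", id, "conc_init", "", if (is.na(ic)) "0" else ic)
    add("metabolite", id, "fixed", "",
        tolower(identical(xml2::xml_attr(nd, "boundaryCondition"), "true")))
  }
  name_of <- stats::setNames(
    vapply(xml2::xml_find_all(mdl, ".//listOfSpecies/species"), function(nd) {
      nm <- xml2::xml_attr(nd, "name")
      if (is.na(nm)) xml2::xml_attr(nd, "id") else nm
    }, ""),
    vapply(xml2::xml_find_all(mdl, ".//listOfSpecies/species"),
           function(nd) xml2::xml_attr(nd, "id"), ""))

  for (pool in xml2::xml_find_all(mdl, ".//moieties/pool")) {
    pid <- xml2::xml_attr(pool, "id")
    for (mm in xml2::xml_find_all(pool, ".//member"))
      add("moiety", pid, "member", name_of[[xml2::xml_attr(mm, "species")]], "")
    add("moiety", pid, "total", "", xml2::xml_attr(pool, "total"))
  }

  for (nd in xml2::xml_find_all(mdl, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(nd, "id")
    type <- xml2::xml_attr(nd, "type")
    if (is.na(type)) type <- "enzyme"
    comp <- xml2::xml_attr(nd, "compartment")
    if (!is.na(type) && type != "enzyme") add("reaction", rid, "type", "", type)
    add("reaction", rid, "compartment", "",
        if (is.na(comp)) "cytoplasm" else comp)
    for (sr in xml2::xml_find_all(nd, ".//listOfReactants/speciesReference"))
      add("reaction", rid, "stoich", name_of[[xml2::xml_attr(sr, "species")]],
          -as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    for (sr in xml2::xml_find_all(nd, ".//listOfProducts/speciesReference"))
      add("reaction", rid, "stoich", name_of[[xml2::xml_attr(sr, "species")]],
          as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    if (type == "enzyme") {
      lps <- xml2::xml_find_all(nd, ".//kineticLaw//localParameter")
      got_chi <- FALSE
      for (lp in lps) {
        pid <- xml2::xml_attr(lp, "id"); val <- xml2::xml_attr(lp, "value")
        if (startsWith(pid, "km_")) {
          add("reaction", rid, "km", name_of[[substring(pid, 4)]], val)
        } else {
          if (pid == "chi") got_chi <- TRUE
          add("reaction", rid, pid, "", val)
        }
      }
      if (!got_chi) {
        warnf("reaction %s: no chi annotation in SBML, defaulting to 1", rid)
        add("reaction", rid, "chi", "", 1)
      }
    }
  }

  for (nd in xml2::xml_find_all(mdl, ".//diffusion/process")) {
    did <- xml2::xml_attr(nd, "id")
    add("diffusion", did, "species",
        name_of[[xml2::xml_attr(nd, "species")]],
        name_of[[xml2::xml_attr(nd, "species")]])
    add("diffusion", did, "env_species",
        name_of[[xml2::xml_attr(nd, "envSpecies")]],
        name_of[[xml2::xml_attr(nd, "envSpecies")]])
    add("diffusion", did, "d_coeff", "", xml2::xml_attr(nd, "dCoeff"))
  }

  cellnd <- xml2::xml_find_first(mdl, ".//cell")
  if (!inherits(cellnd, "xml_missing"))
    for (at in names(xml2::xml_attrs(cellnd)))
      add("cell", "cell", at, "", xml2::xml_attr(cellnd, at))
  biond <- xml2::xml_find_first(mdl, ".//biomassStoichiometry")
  if (!inherits(biond, "xml_missing"))
    for (at in names(xml2::xml_attrs(biond)))
      add("biomass", "biomass", at, "", xml2::xml_attr(biond, at))

  tab <- do.call(rbind, rows)
  # restore provenance flags if recorded
  pv <- xml2::xml_find_all(mdl, ".//provenance/printed")
  if (length(pv)) {
    for (nd in pv) {
      k <- tab$section == xml2::xml_attr(nd, "section") &
        tab$id == xml2::xml_attr(nd, "id") &
        tab$param == xml2::xml_attr(nd, "param") &
        tab$species == (function(x) if (is.na(x)) "" else x)(xml2::xml_attr(nd, "species"))
      tab$provenance[k] <- "printed"
    }
  }
  build_network(tab)
}
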