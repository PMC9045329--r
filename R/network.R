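# Network data model: parse the flat parameter table into a validated
# network object (compartments, species, moiety pools, reactions, diffusion,
# cell geometry, biomass stoichiometry).

#' Build a metabolic network model from a parameter table
#'
#' Parses the long-format parameter table (one row per item: compartment
#' volumes, metabolite initial state, moiety pools, reaction stoichiometry and
#' kinetic constants, diffusion processes, cell geometry, biomass
#' stoichiometry) into a validated `mb_network` object. The default
#' *M. barkeri* methylotrophic-methanogenesis parameterization is returned by
#' [fixture_barkeri()].
#'
#' Reaction parameters follow the thermodynamically constrained reversible
#' Michaelis-Menten rate law (see [reaction_velocity()]): `kcat` in
#' mol g-1 s-1, `phi` the proteome mass fraction, `keq` the equilibrium
#' constant, `chi` the number of electrons transferred or charges
#' translocated, and `charge_out` the charges moved out of the cytoplasm per
#' turnover (negative for inward translocation).
#'
#' @param params data.frame as produced by [fixture_barkeri()] or
#'   [read_params()], with columns `section`, `id`, `param`, `species`,
#'   `value`, `unit`, `provenance`.
#' @return An object of class `mb_network`.
#' @export
#' @examples
#' model <- build_network(fixture_barkeri())
#' model
build_network <- function(params) {
  need <- c("section", "id", "param", "species", "value")
  if (!all(need %in% names(params)))
    stopf("parameter table must have columns %s", paste(need, collapse = ", "))
  params$section <- as.character(params$section)
  params$id <- as.character(params$id)
  params$param <- as.character(params$param)
  params$species <- as.character(params$species)
  params$value <- as.character(params$value)

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) stopf("non-numeric value where number expected: %s", what)
    v
  }
  rows <- function(section, id = NULL, param = NULL) {
    k <- params$section == section
    if (!is.null(id)) k <- k & params$id == id
    if (!is.null(param)) k <- k & params$param == param
    params[k, , drop = FALSE]
  }

  ## compartments ------------------------------------------------------------
  cr <- rows("compartment", param = "volume")
  compartments <- data.frame(id = cr$id,
                             volume = num(cr$value, "compartment volume"),
                             stringsAsFactors = FALSE)

  ## species -----------------------------------------------------------------
  sp_ids <- unique(rows("metabolite")$id)
  species <- data.frame(id = sp_ids, compartment = NA_character_,
                        conc_init = NA_real_, fixed = FALSE,
                        stringsAsFactors = FALSE)
  for (i in seq_along(sp_ids)) {
    id <- sp_ids[i]
    species$compartment[i] <- rows("metabolite", id, "compartment")$value[1]
    species$conc_init[i] <- num(rows("metabolite", id, "conc_init")$value[1],
                                paste0("conc_init of ", id))
    fx <- rows("metabolite", id, "fixed")
    species$fixed[i] <- nrow(fx) > 0 && tolower(fx$value[1]) %in% c("true", "1", "yes")
  }

  ## moiety pools ------------------------------------------------------------
  pools <- list()
  for (pid in unique(rows("moiety")$id)) {
    mem <- rows("moiety", pid, "member")$species
    tot <- num(rows("moiety", pid, "total")$value[1], paste0("total of ", pid))
    pools[[pid]] <- list(id = pid, members = mem, total = tot)
  }

  ## reactions ---------------------------------------------------------------
  reactions <- list()
  for (rid in unique(rows("reaction")$id)) {
    st <- rows("reaction", rid, "stoich")
    km <- rows("reaction", rid, "km")
    scal <- function(p, default = NULL) {
      r <- rows("reaction", rid, p)
      if (nrow(r) == 0) {
        if (is.null(default)) stopf("reaction %s: missing parameter '%s'", rid, p)
        return(default)
      }
      num(r$value[1], paste(rid, p))
    }
    cmp <- rows("reaction", rid, "compartment")
    type <- rows("reaction", rid, "type")
    type <- if (nrow(type)) type$value[1] else "enzyme"
    rx <- list(
      id = rid, type = type,
      compartment = if (nrow(cmp)) cmp$value[1] else "cytoplasm",
      stoich = stats::setNames(num(st$value, paste(rid, "stoich")), st$species),
      km = if (nrow(km)) stats::setNames(num(km$value, paste(rid, "km")), km$species)
           else stats::setNames(numeric(0), character(0)))
    if (type == "enzyme") {
      rx$kcat <- scal("kcat")
      rx$phi <- scal("phi")
      rx$keq <- scal("keq")
      rx$chi <- scal("chi", 1)
      rx$charge_out <- scal("charge_out", 0)
    }
    reactions[[rid]] <- rx
  }

  ## diffusion ---------------------------------------------------------------
  dr <- rows("diffusion")
  diffusions <- NULL
  if (nrow(dr)) {
    ids <- unique(dr$id)
    diffusions <- data.frame(
      id = ids,
      species = vapply(ids, function(i) rows("diffusion", i, "species")$value[1], ""),
      env_species = vapply(ids, function(i) rows("diffusion", i, "env_species")$value[1], ""),
      d_coeff = vapply(ids, function(i)
        num(rows("diffusion", i, "d_coeff")$value[1], "d_coeff"), 0),
      stringsAsFactors = FALSE)
  }

  ## cell and biomass --------------------------------------------------------
  cellrows <- rows("cell")
  cell <- as.list(stats::setNames(num(cellrows$value, "cell"), cellrows$param))
  biorows <- rows("biomass")
  biomass <- as.list(stats::setNames(num(biorows$value, "biomass"), biorows$param))

  model <- structure(list(
    compartments = compartments, species = species, moieties = pools,
    reactions = reactions, diffusions = diffusions,
    cell = cell, biomass = biomass, params = params), class = "mb_network")

  viol <- validate_network(model)
  hard <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(hard))
    stopf("invalid network model:\n%s",
          paste(sprintf("- [%s] %s", hard$where, hard$message), collapse = "\n"))
  model
}

#' Validate a network model
#'
#' Checks structural consistency: compartment references, positivity of
#' volumes and concentrations, moiety membership and pool closure (the sum of
#' member concentrations must equal the pool total), presence of kinetic
#' parameters for enzyme reactions, and Michaelis constants for every
#' rate-law reactant. Returns a report instead of throwing.
#'
#' @param model an `mb_network`
#' @return data.frame with columns `where`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows for a valid model.
#' @export
validate_network <- function(model) {
  out <- data.frame(where = character(), severity = character(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(where, message, severity = "error")
    out[nrow(out) + 1L, ] <<- list(where, severity, message)

  sp <- model$species
  if (any(duplicated(sp$id))) add("species", "duplicated species ids")
  if (any(sp$conc_init < 0))
    add("species", sprintf("negative initial concentration: %s",
                           paste(sp$id[sp$conc_init < 0], collapse = ", ")))
  bad <- !sp$compartment %in% model$compartments$id
  if (any(bad))
    add("species", sprintf("unknown compartment for: %s",
                           paste(sp$id[bad], collapse = ", ")))
  if (any(model$compartments$volume <= 0)) add("compartment", "non-positive volume")

  for (p in model$moieties) {
    miss <- setdiff(p$members, sp$id)
    if (length(miss))
      add(paste0("moiety:", p$id),
          sprintf("unknown member(s): %s", paste(miss, collapse = ", ")))
    if (length(p$members) == 0) add(paste0("moiety:", p$id), "empty pool")
    s <- sum(sp$conc_init[match(p$members, sp$id)])
    if (is.finite(s) && abs(s - p$total) > 1e-9 * max(p$total, 1e-30))
      add(paste0("moiety:", p$id),
          sprintf("member concentrations sum to %.6g, pool total is %.6g",
                  s, p$total))
  }

  for (rx in model$reactions) {
    miss <- setdiff(names(rx$stoich), sp$id)
    if (length(miss))
      add(paste0("reaction:", rx$id),
          sprintf("unknown species in stoichiometry: %s", paste(miss, collapse = ", ")))
    if (rx$type == "enzyme") {
      for (f in c("kcat", "phi", "keq"))
        if (is.null(rx[[f]]) || !is.finite(rx[[f]]))
          add(paste0("reaction:", rx$id), sprintf("missing %s", f))
      if (!is.null(rx$phi) && (rx$phi < 0 || rx$phi > 1))
        add(paste0("reaction:", rx$id), "phi outside [0, 1]")
      if (!is.null(rx$chi) && rx$chi < 1)
        add(paste0("reaction:", rx$id), "chi must be >= 1")
      mk <- setdiff(names(rx$km), names(rx$stoich))
      if (length(mk))
        add(paste0("reaction:", rx$id),
            sprintf("K_m given for species not in stoichiometry: %s",
                    paste(mk, collapse = ", ")))
    }
  }

  if (!is.null(model$diffusions)) {
    if (any(model$diffusions$d_coeff <= 0)) add("diffusion", "non-positive d_coeff")
    miss <- setdiff(c(model$diffusions$species, model$diffusions$env_species), sp$id)
    if (length(miss))
      add("diffusion", sprintf("unknown species: %s", paste(miss, collapse = ", ")))
  }

  for (f in c("radius", "capacitance", "w_prot", "dry_mass", "temperature"))
    if (is.null(model$cell[[f]]) || model$cell[[f]] <= 0)
      add("cell", sprintf("missing or non-positive %s", f))
  pm <- model$cell$phi_membrane_total
  if (!is.null(pm) && pm > 1) add("cell", "phi_membrane_total > 1")

  out
}

#' @export
print.mb_network <- function(x, ...) {
  nrx <- length(x$reactions)
  nenz <- sum(vapply(x$reactions, function(r) r$type == "enzyme", TRUE))
  ndif <- if (is.null(x$diffusions)) 0L else nrow(x$diffusions)
  cat("<mb_network>\n")
  cat(sprintf("  %d metabolites in %d compartments, %d moiety pools\n",
              nrow(x$species), nrow(x$compartments), length(x$moieties)))
  cat(sprintf("  %d reactions (%d enzymatic, %d pseudo) + %d diffusion processes\n",
              nrx + ndif, nenz, nrx - nenz, ndif))
  cat(sprintf("  external methanol: %g mM\n", 1e3 * get_methanol(x)))
  invisible(x)
}

#' @export
summary.mb_network <- function(object, ...) {
  x <- object
  print(x)
  enz <- Filter(function(r) r$type == "enzyme", x$reactions)
  df <- data.frame(
    id = vapply(enz, `[[`, "", "id"),
    compartment = vapply(enz, `[[`, "", "compartment"),
    kcat = vapply(enz, `[[`, 0, "kcat"),
    phi = vapply(enz, `[[`, 0, "phi"),
    keq = vapply(enz, `[[`, 0, "keq"),
    chi = vapply(enz, `[[`, 0, "chi"),
    charge_out = vapply(enz, `[[`, 0, "charge_out"),
    row.names = NULL)
  print(df, digits = 3)
  invisible(df)
}

#' Get or set the external methanol concentration of a model
#'
#' @param model an `mb_network`
#' @param conc external methanol concentration, mol/L
#' @return `set_methanol()` returns the modified model; `get_methanol()` the
#'   current external concentration in mol/L.
#' @export
set_methanol <- function(model, conc) {
  stopifnot(conc >= 0)
  i <- match("CH3OH_e", model$species$id)
  if (is.na(i)) stopf("model has no external methanol species CH3OH_e")
  model$species$conc_init[i] <- conc
  model
}

#' @rdname set_methanol
#' @export
get_methanol <- function(model) {
  i <- match("CH3OH_e", model$species$id)
  if (is.na(i)) return(NA_real_)
  model$species$conc_init[i]
}

#' Membrane enzyme ids of a model
#'
#' Enzyme reactions assigned to the membrane compartment; in the default
#' model these are the seven respiratory-chain and transport enzymes whose
#' proteome fractions are constrained to sum to `phi_membrane_total`.
#'
#' @param model an `mb_network`
#' @return character vector of reaction ids
#' @export
membrane_enzymes <- function(model) {
  enz <- Filter(function(r) r$type == "enzyme" && r$compartment == "membrane",
                model$reactions)
  vapply(enz, `[[`, "", "id")
}
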