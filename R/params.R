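# Parameter-table I/O and the packaged default parameterization.

#' Default *M. barkeri* parameter table
#'
#' Returns the packaged parameterization of the methylotrophic
#' methanogenesis network: 16 enzyme reactions (9 cytoplasmic, 7
#' membrane-associated), maintenance and biomass pseudo-reactions, 3
#' diffusion processes, 35 metabolites in two compartments, 8 conserved
#' moiety pools, cell geometry and biomass stoichiometry. Every row carries a
#' `provenance` flag: `"printed"` for values fixed from published
#' measurements (e.g. K_m,CH3OH ~ 50 mM, K_m,CoB = 59 uM, T_CoB = 1.7 mM,
#' clamped ATP/ADP/Pi at 10/1/10 mM, phi_M = 10%, the biomass coefficients),
#' `"calibrated"` for values tuned once so that the assembled model
#' reproduces the reference steady-state behaviour (see the methods
#' vignette and `tools/calibrate.R` in the source repository for the full
#' derivation).
#'
#' @return data.frame with columns `section`, `id`, `param`, `species`,
#'   `value`, `unit`, `provenance`
#' @export
#' @examples
#' tab <- fixture_barkeri()
#' subset(tab, id == "MCR" & param == "km")
fixture_barkeri <- function() {
  path <- system.file("extdata", "barkeri_params.tsv", package = "methanokin",
                      mustWork = TRUE)
  read_params(path)
}

#' Read / write a parameter table as TSV
#'
#' The flat tab-separated layout mirrors a one-row-per-(item, parameter)
#' structure and is diffable; [build_network()] consumes it directly.
#'
#' @param path file path
#' @param params data.frame as returned by [fixture_barkeri()]
#' @return `read_params()` returns the data.frame; `write_params()` its path,
#'   invisibly.
#' @export
read_params <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = NULL, quote = "")
  need <- c("section", "id", "param", "species", "value", "unit", "provenance")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("parameter file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jitter a parameter table for robustness studies
#'
#' Applies deterministic multiplicative log-normal noise to the kinetic
#' entries (`km`, `kcat`, `keq`) of a parameter table. Rows whose provenance
#' is `"printed"` can be protected.
#'
#' @param params parameter table
#' @param seed integer seed (same seed, same output)
#' @param cv coefficient of variation of the multiplicative noise (>= 0)
#' @param protect_printed keep rows flagged `printed` unchanged
#' @return jittered parameter table
#' @export
perturb_params <- function(params, seed = 1L, cv = 0.1, protect_printed = TRUE) {
  stopifnot(cv >= 0)
  if (cv == 0) return(params)
  k <- params$param %in% c("km", "kcat", "keq")
  if (protect_printed) k <- k & params$provenance != "printed"
  n <- sum(k)
  if (n == 0) return(params)
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fac <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  params$value[k] <- as.character(as.numeric(params$value[k]) * fac)
  params
}
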