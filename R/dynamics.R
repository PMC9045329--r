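# ODE assembly (mass balance + membrane potential + moiety elimination),
# stiff integration, and steady-state location.

# Precompile index structures for fast right-hand-side evaluation.
compile_network <- function(model) {
  sp <- model$species
  n <- nrow(sp)
  idx <- stats::setNames(seq_len(n), sp$id)
  vol <- model$compartments$volume[match(sp$compartment, model$compartments$id)]

  # one eliminated member per pool (the last-listed), computed sequentially
  elim <- integer(0); elim_pool <- list()
  for (p in model$moieties) {
    mi <- idx[p$members]
    e <- mi[length(mi)]
    if (e %in% elim) stopf("moiety %s: eliminated member already used", p$id)
    elim <- c(elim, e)
    elim_pool[[length(elim_pool) + 1L]] <- list(e = e, others = mi[-length(mi)],
                                                total = p$total)
  }
  free <- which(!sp$fixed & !(seq_len(n) %in% elim))

  rx <- model$reactions
  rids <- names(rx)
  enz <- which(vapply(rx, function(r) r$type == "enzyme", TRUE))
  S <- matrix(0, n, length(rx), dimnames = list(sp$id, rids))
  for (j in seq_along(rx)) S[idx[names(rx[[j]]$stoich)], j] <- rx[[j]]$stoich

  RT <- .GAS_CONST * model$cell$temperature
  comp <- lapply(rx, function(r) {
    out <- list(id = r$id, type = r$type,
                s_idx = idx[names(r$stoich)], s_coef = unname(r$stoich))
    if (r$type == "enzyme") {
      kmn <- names(r$km)
      st <- r$stoich[kmn]
      out$cap <- model$cell$w_prot * r$kcat * r$phi
      out$lnK <- log(r$keq)
      out$chiRT <- r$chi * RT
      out$cF <- r$charge_out * .FARADAY
      out$km_idx <- idx[kmn]
      out$km <- unname(r$km)
      out$km_pow <- abs(unname(st))
      out$km_sub <- unname(st) < 0
    }
    out
  })

  dif <- model$diffusions
  dif_idx <- if (is.null(dif)) NULL else
    list(cyt = idx[dif$species], env = idx[dif$env_species],
         fac = 4 * pi * dif$d_coeff * model$cell$radius * 1000)

  maint_v <- (model$cell$maintenance_atp %||% 0) * model$cell$dry_mass
  # biomass precursor species consumed by the pseudo-reaction (negative
  # stoichiometry, not clamped): their availability regularizes the drain
  bio_j <- which(vapply(rx, function(r) r$type == "biomass", TRUE))
  bio_idx <- integer(0)
  if (length(bio_j)) {
    bst <- rx[[bio_j]]$stoich
    cand <- names(bst)[bst < 0]
    bio_idx <- idx[cand[!sp$fixed[idx[cand]]]]
  }
  list(idx = idx, vol = vol, elim = elim_pool, free = free,
       fixed_template = ifelse(sp$fixed | seq_len(n) %in% elim, sp$conc_init, NA),
       conc_init = sp$conc_init, S = S, comp = comp, enz = enz,
       rids = rids, aha = match("AHA", rids),
       biomassj = which(vapply(rx, function(r) r$type == "biomass", TRUE)),
       maintj = which(vapply(rx, function(r) r$type == "maintenance", TRUE)),
       dif = dif_idx, dif_ids = if (is.null(dif)) character(0) else dif$id,
       bio_idx = bio_idx, bio_k = model$biomass$precursor_km %||% 2e-6,
       maint_v = maint_v, RT = RT,
       atp_per_g = model$biomass$atp_per_g %||% NA_real_,
       drains = model$biomass,
       FoverCm = .FARADAY / model$cell$capacitance,
       cC = vapply(rx, function(r) (r$charge_out %||% 0), 0))
}

# full concentration vector from reduced state (free species + psi last)
full_conc <- function(cc, y) {
  conc <- cc$fixed_template
  conc[cc$free] <- y[seq_along(cc$free)]
  for (p in cc$elim) conc[p$e] <- p$total - sum(conc[p$others])
  conc
}

# velocities of all reactions + diffusive fluxes at a state
eval_velocities <- function(cc, conc, psi, detail = FALSE) {
  concp <- pmax(conc, 1e-30)
  lnc <- log(concp)
  nv <- length(cc$comp)
  v <- numeric(nv); dg <- rep(NA_real_, nv); satv <- thv <- rep(NA_real_, nv)
  for (j in cc$enz) {
    r <- cc$comp[[j]]
    g <- cc$RT * (sum(r$s_coef * lnc[r$s_idx]) - r$lnK) + r$cF * psi
    rat <- concp[r$km_idx] / r$km
    sub <- r$km_sub
    numer <- prod(rat[sub]^r$km_pow[sub])
    denom <- prod((1 + rat[sub])^r$km_pow[sub]) +
      prod((1 + rat[!sub])^r$km_pow[!sub]) - 1
    sat <- numer / denom
    th <- 1 - exp(g / r$chiRT)
    v[j] <- r$cap * sat * th
    dg[j] <- g; satv[j] <- sat; thv[j] <- th
  }
  if (length(cc$maintj)) v[cc$maintj] <- cc$maint_v
  if (length(cc$biomassj)) {
    surplus <- if (!is.na(cc$aha)) v[cc$aha] - cc$maint_v else 0
    # precursor-availability factor: ~1 in normal operation, turns the drain
    # off smoothly if a biosynthetic precursor pool is exhausted
    avail <- prod(concp[cc$bio_idx] / (concp[cc$bio_idx] + cc$bio_k))
    v[cc$biomassj] <- avail * max(0, surplus) / cc$atp_per_g   # g biomass / s
  }
  J <- NULL
  if (!is.null(cc$dif))
    J <- cc$dif$fac * (concp[cc$dif$env] - concp[cc$dif$cyt])
  if (detail) list(v = v, J = J, delta_g = dg, sat = satv, thermo = thv)
  else list(v = v, J = J)
}

# reduced derivative dy/dt (free species, then psi)
reduced_rhs <- function(cc, y) {
  y <- pmax(y, c(rep(0, length(cc$free)), -Inf))
  psi <- y[length(y)]
  conc <- full_conc(cc, y)
  ev <- eval_velocities(cc, conc, psi)
  dfull <- as.vector(cc$S %*% ev$v)
  if (!is.null(ev$J)) dfull[cc$dif$cyt] <- dfull[cc$dif$cyt] + ev$J
  dfull <- dfull / cc$vol
  dpsi <- cc$FoverCm * sum(cc$cC * ev$v)
  c(dfull[cc$free], dpsi)
}

#' Assemble the ODE system of a network model
#'
#' Builds the mass-balance derivative function `dC_j/dt = (J_j + sum_i
#' c_ji v_i) / V` for free metabolites, `dpsi/dt = (F/C_m) sum_i c_Ci v_i`
#' for the membrane potential, with clamped species held constant and one
#' member of each moiety pool eliminated algebraically through the
#' conservation law. The returned function has the `deSolve` signature
#' `function(t, y, parms)`.
#'
#' @param model an `mb_network`
#' @return list with `func` (derivative function), `y0` (initial reduced
#'   state), `ynames` (free species names + `"psi"`), and the internal
#'   compiled structure `cc`
#' @export
assemble_odes <- function(model) {
  cc <- compile_network(model)
  y0 <- c(cc$conc_init[cc$free], model$cell$psi_init %||% 0.12)
  ynames <- c(model$species$id[cc$free], "psi")
  list(func = function(t, y, parms) list(reduced_rhs(cc, y)),
       y0 = stats::setNames(y0, ynames), ynames = ynames, cc = cc)
}

#' Initial metabolic state of a model
#'
#' @param model an `mb_network`
#' @return list with `conc` (named vector, mol/L) and `psi` (V)
#' @export
initial_state <- function(model) {
  list(conc = stats::setNames(model$species$conc_init, model$species$id),
       psi = model$cell$psi_init %||% 0.12)
}

#' Integrate the network ODEs
#'
#' Stiff-capable forward integration with `deSolve::lsoda`. Negative
#' concentration excursions are clipped to zero inside the right-hand side;
#' if the reported trajectory contains negative values they are clipped with
#' a warning.
#'
#' @param model an `mb_network`
#' @param t_end end time, s
#' @param times optional explicit output times (overrides `t_end`)
#' @param init optional reduced-state vector to start from (defaults to the
#'   model's initial concentrations)
#' @param abs_tol,rel_tol integration tolerances
#' @return object of class `mb_trajectory`: a data.frame of times, free
#'   species and `psi`, with the ODE system in `attr(, "odes")`
#' @export
integrate_network <- function(model, t_end = 1e6, times = NULL, init = NULL,
                              abs_tol = 1e-12, rel_tol = 1e-8) {
  odes <- assemble_odes(model)
  y0 <- if (is.null(init)) odes$y0 else stats::setNames(init, odes$ynames)
  if (is.null(times)) {
    stopifnot(t_end >= 0)
    times <- if (t_end == 0) 0 else unique(c(0, 10^seq(-2, log10(t_end), length.out = 120)))
  }
  if (length(times) == 1) {
    out <- matrix(c(times, y0), 1, dimnames = list(NULL, c("time", odes$ynames)))
  } else {
    out <- deSolve::lsoda(y0, times, odes$func, parms = NULL,
                          atol = abs_tol, rtol = rel_tol, maxsteps = 50000)
  }
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  spcols <- setdiff(names(out), c("time", "psi"))
  neg <- out[spcols] < 0
  if (any(neg, na.rm = TRUE)) {
    warnf("negative concentration excursions clipped to 0 (%d values)",
          sum(neg, na.rm = TRUE))
    out[spcols][neg] <- 0
  }
  structure(out, class = c("mb_trajectory", "data.frame"), odes = odes)
}

# max relative derivative |dC/dt|/C (and |dpsi/dt|/psi), s^-1
steady_residual <- function(cc, y) {
  d <- reduced_rhs(cc, y)
  scale <- pmax(abs(y), 1e-12)
  max(abs(d) / scale)
}

# damped Newton polish on the reduced system; returns y (or NULL on failure)
newton_polish <- function(cc, y, tol = 1e-11, maxit = 40) {
  n <- length(y)
  f <- reduced_rhs(cc, y)
  for (it in seq_len(maxit)) {
    res <- max(abs(f) / pmax(abs(y), 1e-12))
    if (res < tol) return(y)
    Jm <- matrix(0, n, n)
    h <- pmax(abs(y), 1e-12) * 1e-7
    for (k in seq_len(n)) {
      yk <- y; yk[k] <- yk[k] + h[k]
      Jm[, k] <- (reduced_rhs(cc, yk) - f) / h[k]
    }
    step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      y2 <- y + lam * step
      y2[-n] <- pmax(y2[-n], 0)
      f2 <- reduced_rhs(cc, y2)
      if (max(abs(f2) / pmax(abs(y2), 1e-12)) < res || lam < 1e-4) break
      lam <- lam / 2
    }
    if (lam < 1e-4 && max(abs(f2) / pmax(abs(y2), 1e-12)) >= res) return(NULL)
    y <- y2; f <- f2
  }
  if (max(abs(f) / pmax(abs(y), 1e-12)) < tol) y else NULL
}

#' Solve for the steady state of a network model
#'
#' Integrates the system forward in stages (the default model relaxes within
#' about 1e3 s; integration continues to at most `t_end`) until the maximum
#' relative time derivative falls below `tol`. An optional Newton polish
#' drives the residual to near machine precision, which is required for
#' precise finite-difference control coefficients.
#'
#' @param model an `mb_network`
#' @param methanol optional external methanol concentration (mol/L) applied
#'   before solving
#' @param t_end maximum integration time, s
#' @param tol steady-state criterion on the maximum relative derivative, s-1
#' @param polish logical; apply the Newton polish after integration
#' @param init optional starting reduced state (warm start)
#' @param abs_tol,rel_tol integrator tolerances
#' @return object of class `mb_steady_state`: list with `state` (`conc`,
#'   `psi`, `time`), `velocities` (mol/s; biomass pseudo-reaction in g/s),
#'   `fluxes` (diffusion, mol/s, positive into the cell), `delta_g` (J/mol),
#'   `saturation`, `thermo`, `mu` and `mu_net` (s-1), `converged`,
#'   `residual`
#' @export
#' @examples
#' \donttest{
#' m <- build_network(fixture_barkeri())
#' ss <- steady_state(m, methanol = 0.1)
#' ss
#' }
steady_state <- function(model, methanol = NULL, t_end = 1e6, tol = 1e-8,
                         polish = FALSE, init = NULL,
                         abs_tol = 1e-12, rel_tol = 1e-8) {
  if (!is.null(methanol)) model <- set_methanol(model, methanol)
  odes <- assemble_odes(model)
  cc <- odes$cc
  y <- if (is.null(init)) odes$y0 else stats::setNames(init, odes$ynames)
  t_now <- 0
  stages <- c(1e2, 1e3, 1e4, 1e5, 1e6)
  stages <- stages[stages <= t_end]
  if (!length(stages)) stages <- t_end
  converged <- FALSE
  for (tn in stages) {
    out <- deSolve::lsoda(y, c(t_now, tn), odes$func, parms = NULL,
                          atol = abs_tol, rtol = rel_tol, maxsteps = 100000)
    y <- pmax(out[nrow(out), -1], c(rep(0, length(cc$free)), -Inf))
    names(y) <- odes$ynames
    t_now <- tn
    if (polish && steady_residual(cc, y) < 1e-4) {
      yp <- newton_polish(cc, y)
      if (!is.null(yp)) { y <- stats::setNames(yp, odes$ynames); converged <- TRUE; break }
    }
    if (steady_residual(cc, y) < tol) { converged <- TRUE; if (!polish) break }
  }
  if (polish && !converged) {
    yp <- newton_polish(cc, y)
    if (!is.null(yp)) { y <- stats::setNames(yp, odes$ynames); converged <- TRUE }
  }
  res <- steady_residual(cc, y)
  conc <- full_conc(cc, y)
  names(conc) <- model$species$id
  psi <- y[length(y)]
  ev <- eval_velocities(cc, conc, psi, detail = TRUE)
  vel <- stats::setNames(ev$v, cc$rids)
  mu <- mu_net <- NA_real_
  if (!is.na(cc$aha) && is.finite(cc$atp_per_g)) {
    mu <- vel[["AHA"]] / (cc$atp_per_g * model$cell$dry_mass)
    mu_net <- mu - cc$maint_v / (cc$atp_per_g * model$cell$dry_mass)
  }
  structure(list(
    state = list(conc = conc, psi = unname(psi), time = t_now),
    velocities = vel,
    fluxes = stats::setNames(if (is.null(ev$J)) numeric(0) else ev$J, cc$dif_ids),
    delta_g = stats::setNames(ev$delta_g, cc$rids),
    saturation = stats::setNames(ev$sat, cc$rids),
    thermo = stats::setNames(ev$thermo, cc$rids),
    mu = unname(mu), mu_net = unname(mu_net),
    converged = converged && res < max(tol, 1e-8),
    residual = unname(res), methanol = get_methanol(model),
    reduced = y, cc = cc), class = "mb_steady_state")
}

#' @export
print.mb_steady_state <- function(x, ...) {
  cat("<mb_steady_state>\n")
  cat(sprintf("  methanol: %g mM   converged: %s (max rel. dC/dt = %.2e s-1)\n",
              1e3 * x$methanol, x$converged, x$residual))
  cat(sprintf("  membrane potential: %.1f mV\n", 1e3 * x$state$psi))
  if (is.finite(x$mu))
    cat(sprintf("  mu = %.4g d-1   mu_net = %.4g d-1\n",
                per_day(x$mu), per_day(x$mu_net)))
  invisible(x)
}

#' Export a steady state as a tidy table
#'
#' @param ss an `mb_steady_state`
#' @return data.frame in long format: `kind` (species, psi, reaction,
#'   diffusion), `id`, `quantity`, `value`, `unit`
#' @export
steady_state_table <- function(ss) {
  rbind(
    data.frame(kind = "species", id = names(ss$state$conc),
               quantity = "concentration", value = unname(ss$state$conc),
               unit = "mol/L"),
    data.frame(kind = "psi", id = "psi", quantity = "membrane_potential",
               value = ss$state$psi, unit = "V"),
    data.frame(kind = "reaction", id = names(ss$velocities),
               quantity = "velocity", value = unname(ss$velocities),
               unit = "mol/s"),
    data.frame(kind = "reaction", id = names(ss$delta_g),
               quantity = "delta_g", value = unname(ss$delta_g), unit = "J/mol"),
    data.frame(kind = "diffusion", id = names(ss$fluxes),
               quantity = "flux", value = unname(ss$fluxes), unit = "mol/s"))
}
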