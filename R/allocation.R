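# Proteome allocation of the membrane enzymes: maximize the steady-state
# specific growth rate over the simplex of proteome fractions.

#' Optimize membrane-enzyme proteome fractions
#'
#' Searches the simplex `{phi_i >= 0, sum phi_i = phi_total}` of
#' membrane-enzyme proteome fractions for the allocation maximizing the
#' steady-state objective (the specific growth rate by default), using the
#' Nelder-Mead simplex method on `n - 1` free fractions with the last one
#' taken up by the budget; infeasible points (negative fractions) are
#' rejected with a penalty. The outer search wraps an inner steady-state
#' solve warm-started from the incumbent.
#'
#' @param model an `mb_network`
#' @param ids decision enzymes (default: all membrane enzymes)
#' @param phi_total proteome budget (default: the model's
#'   `phi_membrane_total`, falling back to the current sum)
#' @param objective function of an `mb_steady_state` returning the scalar
#'   to maximize; default the gross specific growth rate
#' @param start starting fractions (default: the model's current, rescaled
#'   to the budget); `start = "random"` draws a uniform random feasible
#'   point using `seed`
#' @param seed integer seed for the random start
#' @param maxit,reltol Nelder-Mead settings
#' @param ... passed to [steady_state()]
#' @return list with `phi` (optimal fractions, summing to `phi_total`),
#'   `value` (achieved objective), `start_value`, `counts`, `convergence`
#'   (0 = converged), and `model` (the network with optimized fractions)
#' @export
#' @examples
#' toy <- toy_serial_pair()
#' opt <- optimize_membrane_enzymes(toy,
#'   objective = function(ss) ss$velocities[["E2"]], maxit = 200)
#' opt$phi   # ~ equal split
optimize_membrane_enzymes <- function(model, ids = membrane_enzymes(model),
                                      phi_total = NULL, objective = NULL,
                                      start = NULL, seed = 1L,
                                      maxit = 1e4, reltol = 1e-10, ...) {
  stopifnot(length(ids) >= 2)
  cur <- vapply(ids, function(id) model$reactions[[id]]$phi, 0)
  phi_total <- phi_total %||% model$cell$phi_membrane_total %||% sum(cur)
  if (is.null(objective)) objective <- function(ss) ss$mu
  if (identical(start, "random")) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
    w <- stats::rexp(length(ids))
    start <- phi_total * w / sum(w)
  } else if (is.null(start)) {
    start <- phi_total * cur / sum(cur)
  }
  stopifnot(length(start) == length(ids), all(start >= 0))

  warm <- new.env()
  evaluate <- function(phi) {
    m2 <- model
    for (k in seq_along(ids)) m2$reactions[[ids[k]]]$phi <- phi[k]
    ss <- tryCatch(
      steady_state(m2, polish = TRUE, init = warm$state, ...),
      error = function(e) NULL)
    if (is.null(ss) || !ss$converged) return(NA_real_)
    warm$state <- ss$reduced
    objective(ss)
  }
  f0 <- evaluate(start)
  if (!is.finite(f0)) stopf("steady state at the starting allocation failed")

  n <- length(ids)
  scale <- abs(f0) + 1e-300          # objective normalization, O(1) values
  obj <- function(free) {
    phi <- c(free, phi_total - sum(free))
    if (any(phi < 0)) return(1e3 * (1 + sum(pmax(-phi, 0)) / phi_total))
    val <- evaluate(phi)
    if (!is.finite(val)) return(1e3)
    -val / scale
  }
  opt <- stats::optim(start[-n], obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = rep(phi_total / 10, n - 1)))
  phi <- c(opt$par, phi_total - sum(opt$par))
  phi <- pmax(phi, 0); phi <- phi * phi_total / sum(phi)
  names(phi) <- ids
  m2 <- model
  for (k in seq_along(ids)) m2$reactions[[ids[k]]]$phi <- phi[k]
  list(phi = phi, value = -opt$value * scale, start_value = f0,
       counts = opt$counts, convergence = opt$convergence, model = m2)
}
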