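## Flux balance analysis on a metabolic_model: maximise the objective flux
## subject to S v = 0 and bounds, and carry the equality duals (metabolite
## shadow prices) out of the optimal basis.
##
## Sign convention for shadow prices (gamma): gamma_i < 0 means a small
## external supply of metabolite i would increase growth (the metabolite is
## growth-limiting); gamma_i > 0 means it is in excess. With supply flux p
## entering row i of S v = 0, the right-hand side becomes b_i = -p, so
## gamma_i equals the raw equality dual dZ*/db_i of the maximisation.

SOLVER_CONFIG <- list(engine = "bounded simplex (Bland), dense refactorised",
                      feasibility_tol = 1e-9, optimality_tol = 1e-9,
                      threads = 1L, jitter = 1e-7, degenerate_tol = 1e-4)

#' Flux balance analysis
#'
#' Maximises the single nonzero objective flux (biomass) subject to
#' steady-state mass balance and flux bounds, returning fluxes, the objective
#' value and the metabolite shadow-price vector.
#'
#' @param model a \code{metabolic_model} with exactly one nonzero objective
#'   coefficient.
#' @param degeneracy if TRUE (default), re-solve once with a deterministic
#'   1e-7 bound jitter and flag metabolites whose dual moves by more than
#'   1e-4 as degenerate (their duals are non-unique; downstream
#'   classification falls back to finite-difference probing).
#' @return an object of class \code{fba_fit}: \code{status},
#'   \code{objective}, \code{fluxes}, \code{duals}, \code{reduced_costs},
#'   \code{degenerate}, \code{model}, \code{solver}.
#' @export
fba <- function(model, degeneracy = TRUE) {
  obj_id <- objective_reaction(model)
  r <- lp_solve_bounded(model$S, rep(0, nrow(model$S)), model$obj,
                        model$lb, model$ub, maximize = TRUE)
  if (r$status != "optimal") {
    fit <- list(status = if (r$status == "unbounded") "unbounded" else "infeasible",
                objective = NA_real_, fluxes = numeric(0), duals = numeric(0),
                reduced_costs = numeric(0), degenerate = logical(0),
                model = model, solver = SOLVER_CONFIG)
    class(fit) <- "fba_fit"
    return(fit)
  }
  fluxes <- stats::setNames(r$x, model$rxns$id)
  duals <- stats::setNames(r$y, model$mets$id)
  resid <- max(abs(model$S %*% r$x))
  if (resid > 1e-6)
    stop("steady-state violation ", format(resid), " at optimum")
  ## strong duality audit: dual objective = sum over bound multipliers;
  ## equivalently c'x - y'(Sx) - dj-weighted bound terms must close to zero.
  gap <- abs(r$obj - (sum(pmax(r$dj, 0) * model$ub) +
                      sum(pmin(r$dj, 0) * model$lb)))
  if (gap > 1e-5 * max(1, abs(r$obj)))
    stop("strong duality violated: gap ", format(gap))
  deg <- rep(FALSE, length(duals))
  if (degeneracy) {
    ## primal-side probe: deterministic 1e-7 bound jitter moves the vertex
    jig <- SOLVER_CONFIG$jitter * sin(seq_along(model$lb))
    r2 <- lp_solve_bounded(model$S, rep(0, nrow(model$S)), model$obj,
                           model$lb - abs(jig), model$ub + abs(jig),
                           maximize = TRUE)
    if (r2$status == "optimal")
      deg <- deg | abs(r2$y - r$y) > SOLVER_CONFIG$degenerate_tol
    ## dual-side probe: a tiny cost perturbation selects a different dual
    ## vertex wherever the dual solution is non-unique (e.g. metabolites all
    ## of whose incident reactions sit at their bounds)
    cjig <- SOLVER_CONFIG$jitter * cos(seq_along(model$obj))
    r3 <- lp_solve_bounded(model$S, rep(0, nrow(model$S)), model$obj + cjig,
                           model$lb, model$ub, maximize = TRUE)
    if (r3$status == "optimal")
      deg <- deg | abs(r3$y - r$y) > SOLVER_CONFIG$degenerate_tol
  }
  fit <- list(status = "optimal", objective = r$obj, fluxes = fluxes,
              duals = duals,
              reduced_costs = stats::setNames(r$dj, model$rxns$id),
              degenerate = stats::setNames(deg, model$mets$id),
              objective_id = obj_id, model = model, solver = SOLVER_CONFIG)
  class(fit) <- "fba_fit"
  fit
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA fit (", x$model$model_id, "): status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective, digits = 6), " h^-1", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$fluxes

#' @export
summary.fba_fit <- function(object, ...) {
  if (object$status != "optimal") {
    cat("Non-optimal FBA fit:", object$status, "\n")
    return(invisible(object))
  }
  cat("FBA on", object$model$model_id, "- objective",
      format(object$objective, digits = 6), "\n\nExchange fluxes:\n")
  ex <- object$fluxes[object$model$exchange]
  print(round(ex[abs(ex) > 1e-9], 6))
  cat("\nLimiting metabolites (shadow price < 0, non-degenerate):\n")
  lim <- object$duals[object$duals < -1e-6 & !object$degenerate]
  if (length(lim)) print(round(lim, 6)) else cat("  none\n")
  invisible(object)
}

#' Collapse stoichiometrically balanced cycles in an optimal flux vector
#'
#' Post-processes an optimal solution by minimising the total absolute
#' internal flux while holding every exchange flux and the objective value
#' fixed (a CycleFreeFlux-style L1 clean-up). Futile cycles carry no net
#' exchange, so this zeroes them without touching any reported quantity;
#' duals are carried over unchanged from the original LP, where they are
#' well-defined.
#'
#' @param model the \code{metabolic_model} the fit came from.
#' @param fit an optimal \code{fba_fit}.
#' @return an \code{fba_fit} with cycle-free fluxes.
#' @export
remove_loops <- function(model, fit) {
  if (!inherits(fit, "fba_fit") || fit$status != "optimal")
    stop("remove_loops requires an optimal FBA solution")
  n <- ncol(model$S)
  internal <- !model$exchange
  lb <- model$lb; ub <- model$ub
  ## fix exchanges and the objective at their solved values
  fixed <- model$exchange | model$obj != 0
  lb[fixed] <- ub[fixed] <- fit$fluxes[fixed]
  ## split internal reversibles v = p - q so |v| is linear
  splitj <- which(internal & lb < 0)
  Sx <- model$S
  if (length(splitj)) {
    Sx <- cbind(Sx, -model$S[, splitj, drop = FALSE])
    lbx <- c(pmax(lb, 0), rep(0, length(splitj)))
    ubx <- c(pmax(ub, 0), -lb[splitj])
    lbx[splitj] <- 0
  } else {
    lbx <- lb; ubx <- ub
  }
  w <- c(ifelse(internal, -1, 0), rep(-1, length(splitj)))
  r <- lp_solve_bounded(Sx, rep(0, nrow(Sx)), w, lbx, ubx, maximize = TRUE)
  if (r$status != "optimal")
    stop("loop-removal LP failed with status ", r$status)
  v <- r$x[seq_len(n)]
  if (length(splitj)) v[splitj] <- v[splitj] - r$x[n + seq_along(splitj)]
  out <- fit
  out$fluxes <- stats::setNames(v, model$rxns$id)
  out$loopless <- TRUE
  if (max(abs(model$S %*% v)) > 1e-6)
    stop("loop removal broke mass balance")
  if (abs(v[which(model$obj != 0)] - fit$objective) > 1e-6)
    stop("loop removal changed the objective value")
  out
}

## internal: optimise an arbitrary flux (min or max) under extra fixed bounds
optimize_flux <- function(model, rxn_id, maximize = TRUE,
                          fix = NULL) {
  j <- rxn_index(model, rxn_id)
  lb <- model$lb; ub <- model$ub
  if (!is.null(fix))
    for (id in names(fix)) {
      k <- rxn_index(model, id)
      lb[k] <- fix[[id]][1]; ub[k] <- fix[[id]][2]
    }
  obj <- numeric(ncol(model$S)); obj[j] <- 1
  lp_solve_bounded(model$S, rep(0, nrow(model$S)), obj, lb, ub,
                   maximize = maximize)
}
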