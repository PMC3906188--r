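## Shadow-price semantics and the composite reducing-capacity price.
##
## gamma_red = gamma_NADH - gamma_NAD for a chosen compartment: the growth
## sensitivity to the net supply of reducing equivalents (an external
## NAD -> NADH reduction). Negative gamma_red: reducing capacity is
## growth-limiting; positive: it is available in excess for biomass
## production. Degenerate duals (non-unique at a phase boundary) defer to a
## finite-difference probe.

GAMMA_EPS <- 1e-6

## Exact dual-multiplicity test. Given an optimal primal vertex x, the set
## of optimal dual vectors y is cut out by complementary slackness: reduced
## cost d = c - S'y must vanish on interior reactions, be <= 0 at lower
## bounds and >= 0 at upper bounds (maximisation). The range of w'y over
## that polytope is computed by two small LPs; a non-trivial width means the
## queried price is not unique at this optimum (the bound-jitter heuristic
## can miss such cases when the same degenerate basis survives the jitter).
dual_weight_range <- function(model, fit, weights, tol = 1e-7) {
  S <- model$S
  m <- nrow(S); n <- ncol(S)
  x <- fit$fluxes
  at_lb <- x <= model$lb + tol
  at_ub <- x >= model$ub - tol
  ## variables: y (free) then slack s with d = s, so S'y + s = c
  A <- cbind(t(S), diag(n))
  cvec <- model$obj
  big <- 1e6
  lb <- c(rep(-big, m), ifelse(at_lb & !at_ub, -big, 0))
  ub <- c(rep(big, m), ifelse(at_ub & !at_lb, big, 0))
  free <- at_lb & at_ub          # fixed reactions: sign unconstrained
  lb[m + which(free)] <- -big
  ub[m + which(free)] <- big
  ## maximisation convention: d_j <= 0 at lb, >= 0 at ub
  lb[m + which(at_lb & !at_ub)] <- -big
  ub[m + which(at_lb & !at_ub)] <- 0
  lb[m + which(at_ub & !at_lb)] <- 0
  ub[m + which(at_ub & !at_lb)] <- big
  obj <- c(weights, rep(0, n))
  hi <- lp_solve_bounded(A, cvec, obj, lb, ub, maximize = TRUE)
  lo <- lp_solve_bounded(A, cvec, obj, lb, ub, maximize = FALSE)
  if (hi$status != "optimal" || lo$status != "optimal") return(NULL)
  c(lo$obj, hi$obj)
}

dual_is_degenerate <- function(model, fit, weights,
                               tol = SOLVER_CONFIG$degenerate_tol) {
  rng <- dual_weight_range(model, fit, weights)
  if (is.null(rng)) return(TRUE)         # cannot certify uniqueness
  (rng[2] - rng[1]) > tol
}

#' Shadow price of a metabolite
#'
#' @param fit an optimal \code{fba_fit}.
#' @param metabolite_id metabolite id.
#' @return signed shadow price (attribute \code{degenerate} set when the dual
#'   is non-unique at the optimum).
#' @export
shadow_price <- function(fit, metabolite_id) {
  stopifnot(inherits(fit, "fba_fit"))
  if (fit$status != "optimal") stop("shadow prices require an optimal solve")
  i <- met_index(fit$model, metabolite_id)
  w <- numeric(length(fit$duals)); w[i] <- 1
  deg <- unname(fit$degenerate[i]) ||
    dual_is_degenerate(fit$model, fit, w)
  structure(unname(fit$duals[i]), degenerate = deg)
}

## find the NADH/NAD (or NADPH/NADP) pair in a compartment
cofactor_ids <- function(model, compartment, pair = c("nadh", "nad")) {
  ids <- model$mets$id[model$mets$compartment == compartment]
  out <- character(2)
  for (k in 1:2) {
    pat <- paste0("^", pair[k], "(_", compartment, ")?$")
    hit <- ids[grepl(pat, ids, ignore.case = TRUE)]
    if (!length(hit))
      stop("metabolite '", pair[k], "' not found in compartment '",
           compartment, "'")
    out[k] <- hit[1]
  }
  out
}

#' Reducing-capacity availability at an optimum
#'
#' Computes \code{gamma_red = gamma_NADH - gamma_NAD} for one compartment and
#' classifies the phenotype: \code{limiting} (gamma_red < -1e-6: more
#' reducing capacity would raise growth), \code{excess} (gamma_red > 1e-6) or
#' \code{neutral}. If either cofactor dual is degenerate, the value is
#' recomputed by a finite-difference probe (a small fixed-flux external
#' NAD -> NADH reduction) instead of the raw duals.
#'
#' @param fit an optimal \code{fba_fit}.
#' @param compartment compartment tag of the NADH/NAD pool (default "c",
#'   cytosol).
#' @param probe probe flux for the degenerate fallback (mmol gDW^-1 h^-1).
#' @return list with \code{gamma_red}, \code{classification},
#'   \code{compartment}, \code{degenerate}.
#' @export
gamma_red <- function(fit, compartment = "c", probe = 1e-3) {
  stopifnot(inherits(fit, "fba_fit"))
  if (fit$status != "optimal") stop("gamma_red requires an optimal solve")
  ids <- cofactor_ids(fit$model, compartment)
  g <- unname(fit$duals[ids[1]] - fit$duals[ids[2]])
  w <- numeric(length(fit$duals))
  w[met_index(fit$model, ids)] <- c(1, -1)
  deg <- any(fit$degenerate[ids]) ||
    dual_is_degenerate(fit$model, fit, w)
  if (deg)
    g <- fd_gamma_red(fit$model, compartment, probe = probe,
                      base_obj = fit$objective)
  list(gamma_red = g,
       classification = classify_gamma(g),
       compartment = compartment,
       degenerate = deg)
}

classify_gamma <- function(g) {
  if (g > GAMMA_EPS) "excess" else if (g < -GAMMA_EPS) "limiting" else "neutral"
}

## finite-difference estimate of gamma_red: add a fixed-flux NAD -> NADH
## reduction and difference the optima
fd_gamma_red <- function(model, compartment = "c", probe = 1e-3,
                         base_obj = NULL) {
  ids <- cofactor_ids(model, compartment)
  if (is.null(base_obj)) {
    f0 <- fba(model, degeneracy = FALSE)
    if (f0$status != "optimal") stop("base model not optimal")
    base_obj <- f0$objective
  }
  m2 <- add_supply_reaction(model, ids[1], probe, consume = ids[2])
  f1 <- fba(m2, degeneracy = FALSE)
  if (f1$status != "optimal") {
    ## reduction probe infeasible: try the opposite (oxidation) direction
    m3 <- add_supply_reaction(model, ids[2], probe, consume = ids[1])
    f2 <- fba(m3, degeneracy = FALSE)
    if (f2$status != "optimal") return(0)
    return((f2$objective - base_obj) / probe)
  }
  -(f1$objective - base_obj) / probe
}

## append an irreversible supply reaction "(consume ->) metabolite" with
## fixed flux `probe`
add_supply_reaction <- function(model, metabolite_id, probe,
                                consume = NULL) {
  i <- met_index(model, metabolite_id)
  col <- numeric(nrow(model$S)); col[i] <- 1
  if (!is.null(consume)) col[met_index(model, consume)] <- -1
  model$S <- cbind(model$S, col)
  rid <- make.unique(c(model$rxns$id, "SUPPLY_probe"))[nrow(model$rxns) + 1]
  colnames(model$S) <- c(model$rxns$id, rid)
  model$rxns <- rbind(model$rxns,
                      data.frame(id = rid, name = "supply probe",
                                 reversible = FALSE, subsystem = "probe",
                                 stringsAsFactors = FALSE))
  model$lb <- c(model$lb, stats::setNames(probe, rid))
  model$ub <- c(model$ub, stats::setNames(probe, rid))
  model$obj <- c(model$obj, stats::setNames(0, rid))
  model$exchange <- c(model$exchange, stats::setNames(FALSE, rid))
  model
}

#' Verify a shadow price by finite differences
#'
#' Adds a temporary irreversible supply reaction for the metabolite with flux
#' fixed to \code{probe}, re-solves, and returns
#' \code{fd_estimate = -(Z(probe) - Z(0)) / probe}. For a non-degenerate dual
#' the estimate must agree with the LP shadow price within
#' \code{max(1e-6, 1\% |gamma|)}.
#'
#' @param model a \code{metabolic_model} whose FBA is optimal.
#' @param metabolite_id metabolite id.
#' @param probe supply rate, default 1e-3 mmol gDW^-1 h^-1 (small enough to
#'   stay within one LP basis, large enough to rise above solver noise).
#' @return list with \code{fd_estimate}, \code{gamma} (LP dual),
#'   \code{agrees}, \code{degenerate}.
#' @export
verify_fd <- function(model, metabolite_id, probe = 1e-3) {
  if (!is.numeric(probe) || probe <= 0) stop("probe must be > 0")
  f0 <- fba(model)
  if (f0$status != "optimal") stop("base model FBA is not optimal")
  g <- shadow_price(f0, metabolite_id)   # exact dual-range degeneracy check
  m2 <- add_supply_reaction(model, metabolite_id, probe)
  f1 <- fba(m2, degeneracy = FALSE)
  if (f1$status != "optimal")
    stop("perturbed model is ", f1$status, " at probe ", probe)
  fd <- -(f1$objective - f0$objective) / probe
  deg <- isTRUE(attr(g, "degenerate"))
  list(fd_estimate = fd, gamma = as.numeric(g),
       agrees = !deg && abs(fd - as.numeric(g)) <= max(1e-6, 0.01 * abs(g)),
       degenerate = deg)
}

#' Per-compartment reducing-capacity table
#'
#' @param fit an optimal \code{fba_fit}.
#' @return data.frame with one row per compartment holding an NADH/NAD pair.
#' @export
gamma_red_table <- function(fit) {
  comps <- unique(fit$model$mets$compartment)
  rows <- list()
  for (cc in comps) {
    ok <- tryCatch({ g <- gamma_red(fit, cc); TRUE }, error = function(e) FALSE)
    if (ok)
      rows[[cc]] <- data.frame(compartment = cc, gamma_red = g$gamma_red,
                               classification = g$classification,
                               degenerate = g$degenerate,
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
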