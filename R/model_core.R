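## Metabolic model container: stoichiometry, bounds, objective.
##
## A `metabolic_model` is a plain list holding the stoichiometric matrix S
## (metabolites x reactions, dimnames set), per-reaction bounds in
## mmol gDW^-1 h^-1 (the biomass column in h^-1), objective coefficients and
## exchange flags. The exchange convention is the BiGG one throughout:
## negative exchange flux = uptake, positive = secretion.

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param mets data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (one row per metabolite).
#' @param rxns data.frame with columns \code{id}, \code{name},
#'   \code{reversible}, \code{subsystem} (one row per reaction).
#' @param S stoichiometric matrix, metabolites in rows, reactions in columns.
#' @param lb,ub per-reaction flux bounds (mmol gDW^-1 h^-1; biomass h^-1).
#' @param obj per-reaction objective coefficients (one nonzero for growth
#'   analyses).
#' @param exchange optional logical vector of exchange flags; auto-detected
#'   when NULL (single-metabolite columns on extracellular species or ids
#'   starting with \code{EX_}).
#' @return an object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(id, mets, rxns, S, lb, ub, obj, exchange = NULL) {
  S <- as.matrix(S)
  dimnames(S) <- list(mets$id, rxns$id)
  m <- list(model_id = id,
            mets = as.data.frame(mets, stringsAsFactors = FALSE),
            rxns = as.data.frame(rxns, stringsAsFactors = FALSE),
            S = S,
            lb = as.numeric(lb), ub = as.numeric(ub),
            obj = as.numeric(obj))
  names(m$lb) <- names(m$ub) <- names(m$obj) <- rxns$id
  m$exchange <- if (is.null(exchange)) detect_exchanges(m) else as.logical(exchange)
  names(m$exchange) <- rxns$id
  class(m) <- "metabolic_model"
  validate_model(m)
  m
}

## exchange = boundary column: exactly one nonzero entry, on an extracellular
## metabolite ("e" compartment) or with the conventional EX_/DM_/SK_ prefix
detect_exchanges <- function(m) {
  nz <- colSums(m$S != 0)
  single <- nz == 1
  out <- logical(ncol(m$S))
  for (j in which(single)) {
    i <- which(m$S[, j] != 0)
    out[j] <- m$mets$compartment[i] %in% c("e", "extracellular") ||
      grepl("^(EX_|DM_|SK_)", m$rxns$id[j])
  }
  out
}

#' Validate model invariants
#'
#' Checks matrix shape, unique ids, bound ordering, irreversibility
#' consistency and non-empty reaction columns; stops on violation.
#' @param m a \code{metabolic_model}.
#' @return the model, invisibly.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (nrow(m$S) != nrow(m$mets) || ncol(m$S) != nrow(m$rxns))
    stop("S has shape ", nrow(m$S), "x", ncol(m$S),
         " but model lists ", nrow(m$mets), " metabolites and ",
         nrow(m$rxns), " reactions")
  if (anyDuplicated(m$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(m$rxns$id)) stop("duplicate reaction ids")
  if (ncol(m$S) == 0) stop("model has zero reactions")
  empty <- colSums(m$S != 0) == 0
  if (any(empty))
    stop("reaction column(s) with no metabolites: ",
         paste(m$rxns$id[empty], collapse = ", "))
  if (any(m$lb > m$ub))
    stop("lower_bound > upper_bound for: ",
         paste(m$rxns$id[m$lb > m$ub], collapse = ", "))
  bad <- !m$rxns$reversible & m$lb < 0
  if (any(bad))
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(m$rxns$id[bad], collapse = ", "))
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$model_id, "\n")
  cat("  metabolites:", nrow(x$mets),
      " reactions:", nrow(x$rxns),
      " exchanges:", sum(x$exchange), "\n")
  ob <- which(x$obj != 0)
  cat("  objective:",
      if (length(ob)) paste(x$rxns$id[ob], collapse = ", ") else "<none>", "\n")
  invisible(x)
}

rxn_index <- function(m, id) {
  i <- match(id, m$rxns$id)
  if (anyNA(i))
    stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

met_index <- function(m, id) {
  i <- match(id, m$mets$id)
  if (anyNA(i))
    stop("unknown metabolite id(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Objective (biomass) reaction id
#' @param m a \code{metabolic_model}.
#' @return reaction id carrying the nonzero objective coefficient.
#' @export
objective_reaction <- function(m) {
  ob <- which(m$obj != 0)
  if (length(ob) == 0)
    stop("model '", m$model_id, "' has no objective reaction; ",
         "growth analyses refuse to run")
  if (length(ob) > 1)
    stop("model has ", length(ob), " nonzero objective coefficients; expected 1")
  m$rxns$id[ob]
}

#' Set the maximal uptake rate of an exchange reaction
#'
#' Uptake is represented as a negative lower bound on the exchange column
#' (negative flux = uptake). The input model is never modified.
#'
#' @param m a \code{metabolic_model}.
#' @param exchange_id id of an exchange reaction.
#' @param max_uptake non-negative uptake magnitude (mmol gDW^-1 h^-1) or the
#'   string \code{"unbounded"} (lower bound -1000).
#' @return a modified copy of the model.
#' @export
set_uptake <- function(m, exchange_id, max_uptake) {
  j <- rxn_index(m, exchange_id)
  if (!m$exchange[j])
    stop("'", exchange_id, "' is not an exchange reaction")
  if (identical(max_uptake, "unbounded")) max_uptake <- DEFAULT_BOUND
  if (!is.numeric(max_uptake) || length(max_uptake) != 1 || max_uptake < 0)
    stop("max_uptake must be a single non-negative rate or \"unbounded\"")
  m$lb[j] <- -max_uptake
  if (m$ub[j] < m$lb[j]) m$ub[j] <- m$lb[j]
  m
}

#' Pin reactions to zero flux (in-silico deletions)
#'
#' @param m a \code{metabolic_model}.
#' @param reaction_ids character vector of reaction ids (may be empty).
#' @return a modified copy with \code{lb = ub = 0} for each named reaction.
#' @export
apply_deletions <- function(m, reaction_ids) {
  if (length(reaction_ids) == 0) return(m)
  j <- rxn_index(m, reaction_ids)
  m$lb[j] <- 0
  m$ub[j] <- 0
  m
}

#' Exchange reaction ids of a model
#' @param m a \code{metabolic_model}.
#' @return character vector of exchange reaction ids.
#' @export
exchanges <- function(m) m$rxns$id[m$exchange]

## locate the exchange for a substrate by conventional id fragments
find_exchange <- function(m, what = c("glucose", "oxygen", "ethanol")) {
  what <- match.arg(what)
  pat <- switch(what,
                glucose = "glc", oxygen = "o2", ethanol = "etoh|eth")
  hits <- which(m$exchange & grepl(pat, m$rxns$id, ignore.case = TRUE))
  if (!length(hits)) stop("model has no ", what, " exchange reaction")
  m$rxns$id[hits[1]]
}

#' Convert a hexose uptake rate to carbon-mmol
#'
#' Expresses an uptake rate in carbon-moles, as customarily printed alongside
#' glucose rates (6 carbons per glucose), rounded to three significant digits.
#'
#' @param rate uptake rate in mmol gDW^-1 h^-1.
#' @param n_carbon carbon atoms per substrate molecule (default 6, glucose).
#' @return rate in C-mmol gDW^-1 h^-1, 3 significant digits.
#' @examples
#' c_mmol(4.45)   # 26.7
#' c_mmol(14.08)  # 84.5
#' @export
c_mmol <- function(rate, n_carbon = 6) signif(rate * n_carbon, 3)

## connectivity sanity check: metabolites feeding the objective should be
## reachable from some exchange through the bipartite reaction graph
check_connectivity <- function(m) {
  ob <- which(m$obj != 0)
  if (!length(ob)) return(character(0))
  reach <- rep(FALSE, nrow(m$mets))
  front <- unique(unlist(lapply(which(m$exchange), function(j) which(m$S[, j] != 0))))
  reach[front] <- TRUE
  repeat {
    rx <- which(colSums(m$S[reach, , drop = FALSE] != 0) > 0)
    newm <- unique(unlist(lapply(rx, function(j) which(m$S[, j] != 0))))
    if (all(reach[newm])) break
    reach[newm] <- TRUE
  }
  need <- which(m$S[, ob[1]] != 0)
  m$mets$id[need[!reach[need]]]
}
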