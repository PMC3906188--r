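# Independent oracles and small fixtures shared across the suite.
#
# vertex_lp() solves max c'x s.t. A x = b, lb <= x <= ub by brute-force
# enumeration of basic solutions (every m-column basis x every lb/ub
# assignment of the nonbasic columns). It shares no code with the simplex
# engine and is the reference optimum for toy-sized problems.

vertex_lp <- function(A, b, obj, lb, ub) {
  A <- as.matrix(A)
  ## drop linearly dependent rows (cofactor pool closure makes stoichiometric
  ## rows dependent); with b = 0 the dropped constraints are implied
  qrA <- qr(t(A))
  keep <- qrA$pivot[seq_len(qrA$rank)]
  stopifnot(all(b == 0) || qrA$rank == nrow(A))
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); n <- ncol(A)
  best <- -Inf; best_x <- NULL
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), basis)
    for (mask in seq_len(2^length(nb)) - 1L) {
      xN <- lb[nb]
      if (length(nb)) {
        up <- as.logical(bitwAnd(mask, 2^(seq_along(nb) - 1L)))
        xN[up] <- ub[nb][up]
      }
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      if (any(xB < lb[basis] - 1e-7) || any(xB > ub[basis] + 1e-7)) next
      x <- numeric(n); x[basis] <- xB; x[nb] <- xN
      val <- sum(obj * x)
      if (val > best + 1e-10) { best <- val; best_x <- x }
    }
  }
  list(obj = best, x = best_x)
}

# oracle FBA objective for a metabolic_model via vertex enumeration
vertex_fba <- function(model) {
  vertex_lp(model$S, rep(0, nrow(model$S)), model$obj, model$lb, model$ub)$obj
}

# scipy.optimize.linprog (HiGHS) as an external cross-check
scipy_lp_obj <- function(A, b, obj, lb, ub) {
  inp <- tempfile(fileext = ".json"); outp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = A, b = b, c = obj, lb = lb, ub = ub),
                       inp, digits = NA, matrix = "rowmajor")
  code <- sprintf(paste0(
    "import json, numpy as np\n",
    "from scipy.optimize import linprog\n",
    "d = json.load(open('%s'))\n",
    "res = linprog(-np.array(d['c'], float), A_eq=np.array(d['A'], float),\n",
    "              b_eq=np.array(d['b'], float),\n",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs')\n",
    "json.dump({'status': int(res.status),\n",
    "           'obj': (-res.fun if res.status == 0 else None)},\n",
    "          open('%s', 'w'))\n"), inp, outp)
  script <- tempfile(fileext = ".py"); writeLines(code, script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  jsonlite::fromJSON(outp)
}

# minimal linear chain model with a plantable 3-reaction futile cycle:
# substrate -> a, biomass drains a; a -> b -> c -> a carries no net exchange
cycle_model <- function() {
  mets <- data.frame(id = c("s_e", "a_c", "b_c", "c_c"),
                     name = c("substrate", "a", "b", "c"),
                     compartment = c("e", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_s", "T1", "BIOMASS", "C1", "C2", "C3"),
    name = c("substrate exchange", "uptake", "biomass drain",
             "cycle 1", "cycle 2", "cycle 3"),
    reversible = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    subsystem = "", stringsAsFactors = FALSE)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rxns$id))
  S["s_e", "EX_s"] <- -1
  S["s_e", "T1"] <- -1; S["a_c", "T1"] <- 1
  S["a_c", "BIOMASS"] <- -1
  S["a_c", "C1"] <- -1; S["b_c", "C1"] <- 1
  S["b_c", "C2"] <- -1; S["c_c", "C2"] <- 1
  S["c_c", "C3"] <- -1; S["a_c", "C3"] <- 1
  metabolic_model("cycle-toy", mets, rxns, S,
                  lb = c(-5, 0, 0, 0, 0, 0),
                  ub = c(1000, 1000, 1000, 1000, 1000, 1000),
                  obj = c(0, 0, 1, 0, 0, 0))
}

# legacy SBML Level 2 text with kinetic-law bounds and objective flag
sbml_l2_text <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '<model id="legacy_toy">\n',
    '<listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species id="s_e" name="substrate" compartment="e" boundaryCondition="false"/>\n',
    '<species id="a_c" name="a" compartment="c" boundaryCondition="false"/>\n',
    '</listOfSpecies>\n',
    '<listOfReactions>\n',
    '<reaction id="EX_s" reversible="true">\n',
    '<listOfReactants><speciesReference species="s_e" stoichiometry="1"/></listOfReactants>\n',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>\n',
    '<listOfParameters>\n',
    '<parameter id="LOWER_BOUND" value="-7.25"/>\n',
    '<parameter id="UPPER_BOUND" value="1000"/>\n',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="0"/>\n',
    '</listOfParameters></kineticLaw>\n',
    '</reaction>\n',
    '<reaction id="T1" reversible="false">\n',
    '<listOfReactants><speciesReference species="s_e" stoichiometry="1"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="a_c" stoichiometry="1"/></listOfProducts>\n',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>\n',
    '<listOfParameters>\n',
    '<parameter id="LOWER_BOUND" value="0"/>\n',
    '<parameter id="UPPER_BOUND" value="900"/>\n',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="0"/>\n',
    '</listOfParameters></kineticLaw>\n',
    '</reaction>\n',
    '<reaction id="GROW" reversible="false">\n',
    '<listOfReactants><speciesReference species="a_c" stoichiometry="1"/></listOfReactants>\n',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>\n',
    '<listOfParameters>\n',
    '<parameter id="LOWER_BOUND" value="0"/>\n',
    '<parameter id="UPPER_BOUND" value="1000"/>\n',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>\n',
    '</listOfParameters></kineticLaw>\n',
    '</reaction>\n',
    '</listOfReactions>\n',
    '</model>\n</sbml>\n')
}

# uptake settings used by the shadow-price agreement sweeps
random_uptakes <- function(n = 5, seed = 421L) {
  set.seed(seed)
  data.frame(glc = round(runif(n, 2, 10), 2),
             o2 = round(runif(n, 0.5, 12), 2))
}

toy_with_uptakes <- function(model, glc, o2) {
  m <- set_uptake(model, "EX_glc", glc)
  set_uptake(m, "EX_o2", o2)
}
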