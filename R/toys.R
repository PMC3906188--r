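## Deterministic toy yeast models with explicit NAD(H) bookkeeping.
##
## Two small stoichiometric networks emulate the qualitative redox contrast
## between a Crabtree-positive yeast (TOY-SC) and a Crabtree-negative,
## redox-recycling yeast (TOY-SS):
##
##   TOY-SC  lumped glycolysis / TCA / respiratory chain / fermentation,
##           biomass drawing pyruvate + ATP + NADH. Two fermentative isozymes
##           (one minor, capacity-capped) provide the alternate-optima
##           redundancy that appears only when overflow is active, so the
##           flux span grows under oxygen limitation.
##   TOY-SS  the same backbone plus the NADH-recycling routes the organism is
##           known for: an alternative oxidase (AOX, no ATP), an
##           NADH -> NADPH transhydrogenase-like bypass (THD), a low-capacity
##           polyol sink, and an oxidative PPP-like NADPH source; biomass
##           draws NADPH instead of NADH.
##
## All coefficients are frozen calibration constants: they were tuned once
## against the finite-difference shadow-price oracle until the four headline
## qualitative contrasts (ethanol coupling yes/no, all-excess vs
## subset-excess availability, span increase vs invariance, deletion-induced
## pattern flip) held, and are not meant to be fitted to data.

#' Toy model specification
#'
#' @param po_ratio ATP per NADH oxidised by the respiratory chain (default
#'   1.5, the classical upper-end yeast P/O).
#' @param biomass_stoich named numeric: pyruvate, ATP and NAD(P)H demand per
#'   unit growth (mmol per gDW, so growth carries h^-1).
#' @param redox_options logical flags \code{aox}, \code{thd_bypass},
#'   \code{polyol_sink} — all FALSE for TOY-SC, all TRUE for TOY-SS.
#' @param maintenance_atp non-growth ATP demand (mmol gDW^-1 h^-1).
#' @return list of class \code{toy_spec}.
#' @export
toy_spec <- function(po_ratio = 1.5,
                     biomass_stoich = c(pyr = 12, atp = 40, redox = 4),
                     redox_options = c(aox = FALSE, thd_bypass = FALSE,
                                       polyol_sink = FALSE),
                     maintenance_atp = 1) {
  if (po_ratio <= 0) stop("po_ratio must be > 0")
  if (any(biomass_stoich <= 0)) stop("all biomass coefficients must be > 0")
  if (maintenance_atp < 0) stop("maintenance_atp must be >= 0")
  structure(list(po_ratio = po_ratio, biomass_stoich = biomass_stoich,
                 redox_options = redox_options,
                 maintenance_atp = maintenance_atp),
            class = "toy_spec")
}

toy_build <- function(id, spec, stipitis) {
  po <- spec$po_ratio
  bs <- spec$biomass_stoich
  ## calibration constant: net substrate-level ATP of the lumped TCA turn.
  ## 1 for TOY-SC; 0 for TOY-SS, whose lumped turn books the GTP into the
  ## maintenance side (this is what lets its TCA flux serve the
  ## transhydrogenase bypass rather than energy production under oxygen
  ## limitation, reproducing the carbon-valuable redox economy).
  tca_atp <- if (stipitis) 0 else 1
  mets <- data.frame(
    id = c("glc_e", "o2_e", "etoh_e", "co2_e",
           if (stipitis) "polyol_e",
           "pyr_c", "atp_c", "nadh_c", "nad_c",
           if (stipitis) c("nadph_c", "nadp_c")),
    stringsAsFactors = FALSE)
  mets$name <- mets$id
  mets$compartment <- ifelse(grepl("_e$", mets$id), "e", "c")

  rxn <- function(id, name, stoich, lb, ub, sub = "") {
    list(id = id, name = name, stoich = stoich, lb = lb, ub = ub, sub = sub)
  }
  B <- DEFAULT_BOUND
  rl <- list(
    rxn("EX_glc", "glucose exchange", c(glc_e = -1), -10, B, "exchange"),
    rxn("EX_o2", "oxygen exchange", c(o2_e = -1), -B, B, "exchange"),
    rxn("EX_etoh", "ethanol exchange", c(etoh_e = -1), 0, B, "exchange"),
    rxn("EX_co2", "co2 exchange", c(co2_e = -1), 0, B, "exchange"),
    rxn("GLYC", "lumped glycolysis",
        c(glc_e = -1, nad_c = -2, pyr_c = 2, nadh_c = 2, atp_c = 2),
        0, B, "glycolysis"),
    rxn("TCA", "lumped TCA cycle",
        c(pyr_c = -1, nad_c = -4, nadh_c = 4, atp_c = tca_atp, co2_e = 3),
        0, B, "tca"),
    rxn("RESP", "respiratory chain (complex-I linked)",
        c(nadh_c = -1, o2_e = -0.5, nad_c = 1, atp_c = po),
        0, B, "oxidative phosphorylation"),
    rxn("ATPM", "ATP maintenance", c(atp_c = -1),
        spec$maintenance_atp, spec$maintenance_atp, "maintenance"))
  if (stipitis) {
    rl <- c(rl, list(
      rxn("EX_polyol", "polyol exchange", c(polyol_e = -1), 0, B, "exchange"),
      rxn("PPP", "oxidative pentose phosphate, cyclic (lumped)",
          c(glc_e = -1, nadp_c = -12, nadph_c = 12, co2_e = 6),
          0, B, "ppp"),
      rxn("FERM", "pyruvate fermentation to ethanol",
          c(pyr_c = -1, nadh_c = -1, etoh_e = 1, co2_e = 1, nad_c = 1),
          0, B, "fermentation"),
      rxn("AOX", "alternative oxidase (capacity-capped)",
          c(nadh_c = -1, o2_e = -0.5, nad_c = 1),
          0, 0.5, "oxidative phosphorylation"),
      rxn("THD", "NADH->NADPH bypass (transhydrogenase-like)",
          c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
          0, B, "redox balancing"),
      rxn("POLYOL", "polyol synthesis (NADH sink, capacity-capped)",
          c(pyr_c = -1, nadh_c = -2, nad_c = 2, polyol_e = 1),
          0, 0.3, "redox balancing"),
      rxn("BIOMASS", "biomass (NADPH-drawing)",
          c(pyr_c = -bs[["pyr"]], atp_c = -bs[["atp"]],
            nadph_c = -bs[["redox"]], nadp_c = bs[["redox"]]),
          0, B, "biomass")))
  } else {
    rl <- c(rl, list(
      rxn("FERM", "pyruvate fermentation to ethanol (major isozyme)",
          c(pyr_c = -1, nadh_c = -1, etoh_e = 1, co2_e = 1, nad_c = 1),
          0, B, "fermentation"),
      rxn("FERM2", "pyruvate fermentation to ethanol (minor isozyme 1)",
          c(pyr_c = -1, nadh_c = -1, etoh_e = 1, co2_e = 1, nad_c = 1),
          0, 0.5, "fermentation"),
      rxn("FERM3", "pyruvate fermentation to ethanol (minor isozyme 2)",
          c(pyr_c = -1, nadh_c = -1, etoh_e = 1, co2_e = 1, nad_c = 1),
          0, 2, "fermentation"),
      rxn("FERM4", "pyruvate fermentation to ethanol (inducible isozyme)",
          c(pyr_c = -1, nadh_c = -1, etoh_e = 1, co2_e = 1, nad_c = 1),
          0, 12, "fermentation"),
      rxn("BIOMASS", "biomass (NADH-drawing)",
          c(pyr_c = -bs[["pyr"]], atp_c = -bs[["atp"]],
            nadh_c = -bs[["redox"]], nad_c = bs[["redox"]]),
          0, B, "biomass")))
  }
  n <- length(rl)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, NULL))
  for (j in seq_len(n)) S[names(rl[[j]]$stoich), j] <- rl[[j]]$stoich
  rxns <- data.frame(
    id = vapply(rl, `[[`, "", "id"),
    name = vapply(rl, `[[`, "", "name"),
    reversible = vapply(rl, function(r) r$lb < 0, TRUE),
    subsystem = vapply(rl, `[[`, "", "sub"),
    stringsAsFactors = FALSE)
  lb <- vapply(rl, `[[`, 0, "lb"); ub <- vapply(rl, `[[`, 0, "ub")
  obj <- ifelse(rxns$id == "BIOMASS", 1, 0)
  metabolic_model(id = id, mets = mets, rxns = rxns, S = S,
                  lb = lb, ub = ub, obj = obj)
}

#' Crabtree-positive toy yeast model (TOY-SC)
#'
#' @param spec a \code{toy_spec}; all \code{redox_options} must be FALSE.
#' @return a \code{metabolic_model} with 12 reactions.
#' @export
toy_cerevisiae <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  if (any(spec$redox_options))
    stop("TOY-SC requires all redox_options FALSE")
  toy_build("TOY-SC", spec, stipitis = FALSE)
}

#' Crabtree-negative, redox-recycling toy yeast model (TOY-SS)
#'
#' @param spec a \code{toy_spec}; all \code{redox_options} must be TRUE.
#' @return a \code{metabolic_model} with 15 reactions.
#' @export
toy_stipitis <- function(spec = toy_spec(
                           biomass_stoich = c(pyr = 16, atp = 35, redox = 5),
                           redox_options = c(aox = TRUE, thd_bypass = TRUE,
                                             polyol_sink = TRUE))) {
  stopifnot(inherits(spec, "toy_spec"))
  if (!all(spec$redox_options))
    stop("TOY-SS requires all redox_options TRUE")
  toy_build("TOY-SS", spec, stipitis = TRUE)
}

## logical preset names -> toy reaction ids (the lumped chain stands in for
## both the complex-I entry and the cytochrome oxidase exit)
toy_id_map <- function(model) {
  if (model$model_id == "TOY-SS")
    c(NDH1 = "RESP", AOX = "AOX", COX = "RESP")
  else c(NDH1 = "RESP", COX = "RESP")
}
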