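## Reaction-deletion analyses: a priori respiratory-chain presets, the
## exhaustive pattern-replication screen, a bounded local search for
## growth-coupled designs (enumeration-first stand-in for bilevel MILP
## strain design), and the NADH-sink modified-model procedure.

MIN_GROWTH_EPS <- 1e-8

deletion_result <- function(deletion_set, max_growth, coupling = NA_character_,
                            pattern = NULL, provenance) {
  structure(list(deletion_set = sort(deletion_set), max_growth = max_growth,
                 coupling = coupling, pattern = pattern,
                 provenance = provenance),
            class = "deletion_result")
}

#' @export
print.deletion_result <- function(x, ...) {
  cat("Deletion {", paste(x$deletion_set, collapse = ", "), "} [",
      x$provenance, "]: max growth ", format(x$max_growth, digits = 5),
      sep = "")
  if (!is.na(x$coupling)) cat(", ", x$coupling, sep = "")
  if (!is.null(x$pattern))
    cat(", excess fraction ", format(x$pattern$fraction_excess, digits = 3),
        sep = "")
  cat("\n")
  invisible(x)
}

eval_deletant <- function(model, dels, provenance, grid_steps = 20,
                          glc_range = c(0, 10), o2_range = c(0, 14),
                          compartment = "c", envelope_product = NULL) {
  md <- apply_deletions(model, dels)
  f <- fba(md, degeneracy = FALSE)
  zx <- if (f$status == "optimal") f$objective else 0
  pat <- NULL
  cp <- NA_character_
  if (zx > MIN_GROWTH_EPS) {
    grid <- phpp_scan(md, glc_range, o2_range, steps = grid_steps,
                      compartment = compartment)
    pat <- tryCatch(availability_pattern(grid), error = function(e) NULL)
    if (!is.null(envelope_product))
      cp <- production_envelope(md, envelope_product)$coupling
  }
  deletion_result(dels, zx, cp, pat, provenance)
}

#' A priori respiratory-chain deletion presets
#'
#' Evaluates (i) the complex-I / alternative-oxidase double deletion and
#' (ii) the cytochrome-oxidase single deletion, each with a phase-plane
#' grid, availability pattern and ethanol envelope. Logical preset names
#' are resolved to model reaction ids through \code{id_map}; unresolvable
#' presets are skipped with a warning.
#'
#' @param model a \code{metabolic_model}.
#' @param id_map named character vector mapping \code{NDH1}, \code{AOX},
#'   \code{COX} to reaction ids; defaults to the toy mapping for the bundled
#'   synthetic models.
#' @param ... grid options passed to the internal evaluator.
#' @return list of \code{deletion_result}.
#' @export
a_priori_presets <- function(model, id_map = toy_id_map(model), ...) {
  presets <- list(ndh1_aox = c("NDH1", "AOX"), cox = "COX")
  out <- list()
  for (nm in names(presets)) {
    ids <- id_map[presets[[nm]]]
    if (anyNA(ids)) {
      warning("preset '", nm, "' unresolvable in ", model$model_id,
              " (missing: ", paste(presets[[nm]][is.na(ids)], collapse = ", "),
              "); skipped", call. = FALSE)
      next
    }
    ids <- unique(unname(ids))
    out[[nm]] <- eval_deletant(model, ids, "a_priori", ...,
                               envelope_product = find_exchange(model, "ethanol"))
  }
  out
}

#' Exhaustive single-deletion pattern screen
#'
#' For each candidate single deletion (optionally pairs/triples up to
#' \code{max_size}), computes the deletant's phase plane on a coarse
#' screening grid and keeps those whose oxygen-limited region is entirely in
#' excess (\code{all_excess_o2_limited}) with maximal growth at least
#' \code{min_growth}; survivors are re-verified on the full grid.
#'
#' @param model a \code{metabolic_model}.
#' @param candidates reaction ids eligible for deletion.
#' @param min_growth minimal acceptable maximal growth rate (h^-1).
#' @param max_size largest deletion-set size screened (default 1).
#' @param coarse_steps,fine_steps screening and confirmation grid
#'   resolutions (defaults 8 and 20).
#' @param glc_range,o2_range grid ranges.
#' @param compartment NADH/NAD compartment.
#' @return list of confirmed \code{deletion_result} (survivors only).
#' @export
pattern_screen <- function(model, candidates, min_growth = 0,
                           max_size = 1, coarse_steps = 8, fine_steps = 20,
                           glc_range = c(0, 10), o2_range = c(0, 14),
                           compartment = "c") {
  if (!length(candidates)) stop("candidates must be non-empty")
  if (min_growth < 0) stop("min_growth must be >= 0")
  rxn_index(model, candidates)   # existence check
  sets <- list()
  for (k in seq_len(max_size))
    sets <- c(sets, utils::combn(sort(candidates), k, simplify = FALSE))
  survivors <- list()
  for (dels in sets) {
    res <- tryCatch(
      eval_deletant(model, dels, "exhaustive_single",
                    grid_steps = coarse_steps, glc_range = glc_range,
                    o2_range = o2_range, compartment = compartment),
      error = function(e) NULL)
    if (is.null(res) || res$max_growth < max(min_growth, MIN_GROWTH_EPS)) next
    if (is.null(res$pattern) || !res$pattern$all_excess_o2_limited) next
    ## confirmation pass at full resolution
    conf <- eval_deletant(model, dels, "exhaustive_single",
                          grid_steps = fine_steps, glc_range = glc_range,
                          o2_range = o2_range, compartment = compartment)
    if (!is.null(conf$pattern) && conf$pattern$all_excess_o2_limited)
      survivors[[paste(dels, collapse = "+")]] <- conf
  }
  survivors
}

## coupling strength of a deletion set: minimal product flux at maximal
## growth, with a growth floor; NA when infeasible or below the floor
coupling_strength <- function(model, dels, product_id, min_growth) {
  md <- apply_deletions(model, dels)
  obj_id <- objective_reaction(md)
  f <- fba(md, degeneracy = FALSE)
  if (f$status != "optimal" || f$objective < min_growth) return(NA_real_)
  r <- optimize_flux(md, product_id, maximize = FALSE,
                     fix = stats::setNames(list(f$objective + c(-1e-9, 1e-9)),
                                           obj_id))
  if (r$status != "optimal") return(NA_real_)
  r$obj
}

#' Bounded local search for growth-coupled deletion designs
#'
#' Enumeration-first stand-in for bilevel MILP strain design: all single
#' deletions are scored by coupling strength (minimal product flux at
#' maximal growth), then a deterministic beam search (add/swap one deletion,
#' lexicographic tie-breaks) grows sets up to \code{max_deletions}. The
#' whole procedure is repeated over a ladder of minimal-growth constraints
#' (default 0.1 to 0.7 h^-1 in steps of 0.1), and the unique coupled
#' solutions found at any rung are returned.
#'
#' @param model a \code{metabolic_model}.
#' @param product_id product (exchange) reaction id.
#' @param max_deletions 1, 2 or 3.
#' @param min_growth_ladder increasing minimal growth rates (h^-1).
#' @param candidates deletion candidates; defaults to all non-exchange,
#'   non-objective reactions.
#' @param beam_width beam size of the local search (default 5).
#' @return list of \code{deletion_result} with provenance
#'   \code{"local_search"}, sorted by decreasing coupling strength.
#' @export
growth_coupled_search <- function(model, product_id, max_deletions = 3,
                                  min_growth_ladder = seq(0.1, 0.7, by = 0.1),
                                  candidates = NULL, beam_width = 5) {
  if (!max_deletions %in% 1:3)
    stop("max_deletions must be 1, 2 or 3")
  if (is.null(candidates))
    candidates <- model$rxns$id[!model$exchange & model$obj == 0]
  candidates <- sort(candidates)
  found <- list()
  note <- function(dels, strength, g) {
    key <- paste(sort(dels), collapse = "+")
    if (is.null(found[[key]]) || found[[key]]$strength < strength)
      found[[key]] <<- list(dels = sort(dels), strength = strength,
                            min_growth = g)
  }
  for (g in min_growth_ladder) {
    scores <- vapply(candidates, function(id)
      coupling_strength(model, id, product_id, g), numeric(1))
    ok <- !is.na(scores)
    if (!any(ok)) next
    for (id in candidates[ok & scores > 1e-6]) note(id, scores[id], g)
    ord <- order(-scores[ok], candidates[ok])       # deterministic
    beam <- lapply(utils::head(which(ok)[ord], beam_width),
                   function(i) candidates[i])
    for (size in seq_len(max_deletions - 1)) {
      nxt <- list()
      for (set in beam) {
        for (add in setdiff(candidates, set)) {
          cand <- sort(c(set, add))
          key <- paste(cand, collapse = "+")
          if (!is.null(nxt[[key]])) next
          s <- coupling_strength(model, cand, product_id, g)
          if (is.na(s)) next
          nxt[[key]] <- list(dels = cand, strength = s)
          if (s > 1e-6) note(cand, s, g)
        }
      }
      if (!length(nxt)) break
      ord <- order(-vapply(nxt, `[[`, 0, "strength"), names(nxt))
      beam <- lapply(nxt[utils::head(ord, beam_width)], `[[`, "dels")
    }
  }
  out <- lapply(found, function(fd) {
    md <- apply_deletions(model, fd$dels)
    f <- fba(md, degeneracy = FALSE)
    env <- production_envelope(md, product_id)
    deletion_result(fd$dels, f$objective, env$coupling,
                    provenance = "local_search")
  })
  keep <- vapply(out, function(r) identical(r$coupling, "coupled"), TRUE)
  out <- out[keep]
  strengths <- vapply(found[keep], `[[`, 0, "strength")
  out[order(-strengths, names(out))]
}

#' Exhaustive growth-coupled enumeration (small models)
#'
#' Scores every deletion subset up to \code{max_deletions} by coupling
#' strength. Intended as the independent oracle for
#' \code{\link{growth_coupled_search}} on toy-sized models.
#'
#' @inheritParams growth_coupled_search
#' @param min_growth single minimal growth rate.
#' @return data.frame of coupled sets with their strengths, sorted.
#' @export
enumerate_coupled_sets <- function(model, product_id, max_deletions = 3,
                                   min_growth = 0.1, candidates = NULL) {
  if (is.null(candidates))
    candidates <- model$rxns$id[!model$exchange & model$obj == 0]
  candidates <- sort(candidates)
  rows <- list()
  for (k in seq_len(max_deletions)) {
    for (dels in utils::combn(candidates, k, simplify = FALSE)) {
      s <- coupling_strength(model, dels, product_id, min_growth)
      if (!is.na(s) && s > 1e-6)
        rows[[paste(dels, collapse = "+")]] <-
          data.frame(deletion_set = paste(dels, collapse = "+"),
                     size = k, strength = s, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(deletion_set = character(0), size = integer(0),
                      strength = numeric(0)))
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df[order(-df$strength, df$deletion_set), , drop = FALSE]
}

#' NADH-sink modified model
#'
#' Adds an artificial irreversible sink that consumes NADH without
#' regenerating NAD (a pure drain, not an oxidase), forcing the metabolism
#' to operate under low NADH availability, and imposes a minimal growth
#' rate. Deletion searches on the variant surface modifications that
#' compensate for the drained reducing equivalents; re-applied to the
#' original model they raise available reducing capacity.
#'
#' @param model a \code{metabolic_model}.
#' @param sink_range \code{c(lb, ub)} sink flux bounds, default
#'   \code{c(0.1, 0.6)} mmol gDW^-1 h^-1.
#' @param min_growth growth lower bound, default 0.20 h^-1.
#' @param compartment compartment of the drained NADH pool (default "c").
#' @return a modified \code{metabolic_model} with reaction
#'   \code{NADH_SINK}.
#' @export
nadh_sink_variant <- function(model, sink_range = c(0.1, 0.6),
                              min_growth = 0.20, compartment = "c") {
  if (sink_range[1] > sink_range[2]) stop("sink_range must satisfy lb <= ub")
  ids <- cofactor_ids(model, compartment)
  i <- met_index(model, ids[1])
  col <- numeric(nrow(model$S)); col[i] <- -1
  m2 <- model
  m2$S <- cbind(m2$S, col)
  rid <- "NADH_SINK"
  colnames(m2$S) <- c(model$rxns$id, rid)
  m2$rxns <- rbind(m2$rxns,
                   data.frame(id = rid, name = "artificial NADH sink",
                              reversible = FALSE, subsystem = "artificial",
                              stringsAsFactors = FALSE))
  m2$lb <- c(m2$lb, stats::setNames(sink_range[1], rid))
  m2$ub <- c(m2$ub, stats::setNames(sink_range[2], rid))
  m2$obj <- c(m2$obj, stats::setNames(0, rid))
  m2$exchange <- c(m2$exchange, stats::setNames(FALSE, rid))
  ## a pure drain is infeasible when the NAD(H) pool is strictly closed
  ## (every other reaction conserves NADH + NAD, as in the bundled toys);
  ## genome-scale models keep the pool open through biosynthesis. For closed
  ## pools an explicit NAD-salvage reaction is added so the variant stays
  ## feasible while the drain still removes reducing equivalents.
  pool_rows <- met_index(model, ids)
  if (all(abs(colSums(model$S[pool_rows, , drop = FALSE])) < 1e-12)) {
    col2 <- numeric(nrow(m2$S)); col2[met_index(model, ids[2])] <- 1
    m2$S <- cbind(m2$S, col2)
    colnames(m2$S) <- c(colnames(m2$S)[-ncol(m2$S)], "NAD_SALVAGE")
    m2$rxns <- rbind(m2$rxns,
                     data.frame(id = "NAD_SALVAGE", name = "NAD salvage",
                                reversible = FALSE, subsystem = "artificial",
                                stringsAsFactors = FALSE))
    m2$lb <- c(m2$lb, stats::setNames(0, "NAD_SALVAGE"))
    m2$ub <- c(m2$ub, stats::setNames(DEFAULT_BOUND, "NAD_SALVAGE"))
    m2$obj <- c(m2$obj, stats::setNames(0, "NAD_SALVAGE"))
    m2$exchange <- c(m2$exchange, stats::setNames(FALSE, "NAD_SALVAGE"))
  }
  ob <- which(m2$obj != 0)
  m2$lb[ob] <- max(m2$lb[ob], min_growth)
  f <- fba(m2, degeneracy = FALSE)
  if (f$status != "optimal") {
    ## report the largest feasible sink at this growth floor
    m3 <- m2; m3$lb[ncol(m3$S)] <- 0
    r <- optimize_flux(m3, rid, maximize = TRUE)
    stop("NADH sink of ", sink_range[1], " infeasible at growth >= ",
         min_growth, "; maximal feasible sink is ",
         if (r$status == "optimal") format(r$obj, digits = 4) else "0")
  }
  m2
}
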