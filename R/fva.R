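## Flux variability analysis at fixed optimal growth, flux spans
## (span = v_max - v_min), and the span-vs-oxygen profile used to compare
## network flexibility between phenotypes.
##
## Span bins follow the convention: S1 spans > 10, S2 spans in (1, 10],
## S3 spans in [0.01, 1]; spans below 0.01 are excluded from the counts
## (only substantial flexibility is tallied). Boundary assignment
## (closed/open edges) is this package's stated choice.

span_bins <- function(span) {
  list(S1 = sum(span > 10),
       S2 = sum(span > 1 & span <= 10),
       S3 = sum(span >= 0.01 & span <= 1),
       excluded = sum(span < 0.01))
}

#' Flux variability analysis
#'
#' Fixes growth at 100\% of the FBA optimum and minimises / maximises every
#' reaction flux in turn.
#'
#' @param model a \code{metabolic_model} with optimal FBA and Z* > 0.
#' @param fraction_of_optimum growth fraction at which variability is
#'   evaluated (default 1, the reported setting).
#' @param loopless if TRUE, each min/max solve is post-processed with
#'   \code{\link{remove_loops}} before reading the flux (never widens a
#'   span; default FALSE).
#' @return an object of class \code{flux_span}: per-reaction \code{v_min},
#'   \code{v_max}, \code{span}, bin counts and the uptake context.
#' @export
fva <- function(model, fraction_of_optimum = 1, loopless = FALSE) {
  f <- fba(model, degeneracy = FALSE)
  if (f$status != "optimal") stop("model FBA is ", f$status)
  if (f$objective <= 1e-9) stop("FVA requires Z* > 0")
  obj_id <- objective_reaction(model)
  ztgt <- f$objective * fraction_of_optimum
  fx <- stats::setNames(list(ztgt + c(-1e-9, 1e-9)), obj_id)
  n <- ncol(model$S)
  vmin <- vmax <- numeric(n)
  for (j in seq_len(n)) {
    rlo <- optimize_flux(model, model$rxns$id[j], maximize = FALSE, fix = fx)
    rhi <- optimize_flux(model, model$rxns$id[j], maximize = TRUE, fix = fx)
    if (rlo$status != "optimal" || rhi$status != "optimal")
      stop("FVA solve failed for ", model$rxns$id[j])
    if (loopless) {
      rlo <- loopless_extreme(model, rlo, fx, j)
      rhi <- loopless_extreme(model, rhi, fx, j)
    }
    vmin[j] <- rlo$obj; vmax[j] <- rhi$obj
  }
  span <- pmax(vmax - vmin, 0)
  structure(list(reaction = model$rxns$id, v_min = vmin, v_max = vmax,
                 span = span, bins = span_bins(span),
                 fba_fluxes = f$fluxes, growth = f$objective,
                 context = list(lb = model$lb, ub = model$ub,
                                fraction_of_optimum = fraction_of_optimum,
                                loopless = loopless),
                 model_id = model$model_id),
            class = "flux_span")
}

## re-read one FVA extreme after an L1 cycle clean-up constrained to keep
## the probed flux at its extreme (never widens the span)
loopless_extreme <- function(model, r, fx, j) {
  v <- stats::setNames(r$x, model$rxns$id)
  fit <- structure(list(status = "optimal", fluxes = v,
                        objective = v[[objective_reaction(model)]]),
                   class = "fba_fit")
  m2 <- model
  for (id in names(fx)) {
    k <- rxn_index(m2, id); m2$lb[k] <- fx[[id]][1]; m2$ub[k] <- fx[[id]][2]
  }
  m2$lb[j] <- m2$ub[j] <- r$obj     # hold the probed extreme
  out <- tryCatch(remove_loops(m2, fit), error = function(e) NULL)
  if (is.null(out)) return(r)
  r$x <- unname(out$fluxes)
  r$obj <- out$fluxes[[j]]
  r
}

#' @export
print.flux_span <- function(x, ...) {
  cat("Flux span report (", x$model_id, ") at growth ",
      format(x$growth, digits = 6), " h^-1\n", sep = "")
  cat("  S1 (>10): ", x$bins$S1, "   S2 (1,10]: ", x$bins$S2,
      "   S3 [0.01,1]: ", x$bins$S3, "   excluded (<0.01): ",
      x$bins$excluded, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.flux_span <- function(x, ...) {
  data.frame(reaction = x$reaction, v_min = x$v_min, v_max = x$v_max,
             span = x$span, stringsAsFactors = FALSE)
}

#' Flux-span profile across oxygen uptake levels
#'
#' One FVA report per oxygen bound at a fixed glucose uptake, plus an
#' invariance metric: the maximum over bins of the relative change in count
#' across the strictly oxygen-limited entries of the profile (0 = perfectly
#' invariant flexibility). Entries at or beyond the line of optimality are
#' reported but excluded from the metric, because flexibility trivially
#' collapses on the line in small networks.
#'
#' @param model a \code{metabolic_model}.
#' @param glc_uptake glucose uptake magnitude (default 10).
#' @param o2_values positive, sorted oxygen uptake magnitudes; default 8
#'   evenly spaced values from 0.5 to the line-of-optimality oxygen.
#' @param loopless passed to \code{\link{fva}}.
#' @return an object of class \code{span_profile}: \code{reports} (one per
#'   oxygen value, NULL where infeasible), \code{bin_table},
#'   \code{invariance_metric}, \code{loo_o2}.
#' @export
span_profile <- function(model, glc_uptake = 10, o2_values = NULL,
                         loopless = FALSE) {
  ex_glc <- find_exchange(model, "glucose")
  ex_o2 <- find_exchange(model, "oxygen")
  loo <- line_of_optimality(model, glc_uptake)$o2[1]
  if (is.null(o2_values)) {
    if (is.na(loo)) stop("line of optimality undefined at glc = ", glc_uptake)
    o2_values <- seq(0.5, loo, length.out = 8)
  }
  if (any(diff(o2_values) < 0) || any(o2_values <= 0))
    stop("o2_values must be positive and sorted")
  reports <- vector("list", length(o2_values))
  for (k in seq_along(o2_values)) {
    mm <- set_uptake(model, ex_glc, glc_uptake)
    mm <- set_uptake(mm, ex_o2, o2_values[k])
    reports[[k]] <- tryCatch(fva(mm, loopless = loopless),
                             error = function(e) NULL)
  }
  ok <- !vapply(reports, is.null, TRUE)
  bt <- t(vapply(reports[ok],
                 function(r) unlist(r$bins[c("S1", "S2", "S3")]),
                 numeric(3)))
  bt <- as.data.frame(bt)
  bt$o2 <- o2_values[ok]
  bt$o2_limited <- !is.na(loo) & bt$o2 < loo - 1e-6
  lim <- bt[bt$o2_limited, , drop = FALSE]
  inv <- if (nrow(lim) > 1)
    max(apply(lim[, c("S1", "S2", "S3")], 2,
              function(cnt) (max(cnt) - min(cnt)) / max(1, max(cnt))))
  else 0
  structure(list(reports = reports, o2_values = o2_values,
                 glc_uptake = glc_uptake, bin_table = bt,
                 invariance_metric = inv, loo_o2 = loo,
                 model_id = model$model_id),
            class = "span_profile")
}

#' @export
print.span_profile <- function(x, ...) {
  cat("Flux-span profile (", x$model_id, ") at glucose ", x$glc_uptake,
      " mmol gDW^-1 h^-1\n", sep = "")
  print(x$bin_table, row.names = FALSE)
  cat("  invariance metric:", format(x$invariance_metric, digits = 4),
      "  (line of optimality at O2 =", format(x$loo_o2, digits = 4), ")\n")
  invisible(x)
}
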