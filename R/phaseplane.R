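## Phenotypic phase planes: optimal growth, ethanol secretion and the
## reducing-capacity availability map over a glucose x oxygen uptake grid,
## plus the line of optimality (the uptake ratio of maximal biomass yield,
## i.e. fully respiratory metabolism; left of it growth is oxygen-limited).

#' Line of optimality
#'
#' For each glucose uptake, solves FBA with oxygen unbounded and returns the
#' minimal oxygen uptake that still attains the optimum (alternate optima can
#' waste oxygen, so the maximal-yield ratio is the minimal-oxygen one; fluxes
#' at these points are loop-removed before reading the oxygen exchange).
#' Ethanol secretion on the line is zero for wild-type models.
#'
#' @param model a \code{metabolic_model} with glucose and oxygen exchanges.
#' @param glc_values positive glucose uptake magnitudes.
#' @return data.frame with \code{glc}, \code{o2} (NA where infeasible) and
#'   \code{growth}.
#' @export
line_of_optimality <- function(model, glc_values) {
  if (any(glc_values < 0)) stop("glc_values must be non-negative")
  ex_glc <- find_exchange(model, "glucose")
  ex_o2 <- find_exchange(model, "oxygen")
  obj_id <- objective_reaction(model)
  out <- data.frame(glc = glc_values, o2 = NA_real_, growth = NA_real_)
  for (i in seq_along(glc_values)) {
    mm <- set_uptake(model, ex_glc, glc_values[i])
    mm <- set_uptake(mm, ex_o2, "unbounded")
    f <- fba(mm, degeneracy = FALSE)
    if (f$status != "optimal" || f$objective < 1e-8) {
      if (f$status == "optimal") out$o2[i] <- 0
      out$growth[i] <- if (f$status == "optimal") f$objective else NA_real_
      next
    }
    r <- optimize_flux(mm, ex_o2, maximize = TRUE,
                       fix = stats::setNames(list(rep(f$objective, 2)), obj_id))
    if (r$status == "optimal") {
      out$o2[i] <- -r$x[rxn_index(mm, ex_o2)]
      out$growth[i] <- f$objective
    }
  }
  out
}

#' Phenotypic phase plane scan
#'
#' At every point of a glucose x oxygen uptake grid, sets both maximal
#' uptakes, runs FBA and classifies the reducing-capacity availability
#' (\code{\link{gamma_red}}). Zero-growth points are treated as infeasible
#' for pattern purposes (gamma_red is not a growth sensitivity when growth
#' is zero). Oxygen-limited means strictly left of the line of optimality;
#' points within one grid step of the line are excluded from pattern
#' statistics, since the line is the degenerate locus.
#'
#' @param model a \code{metabolic_model}.
#' @param glc_range,o2_range numeric \code{c(min, max)} uptake magnitudes.
#' @param steps grid resolution per axis (default 20), at least 2.
#' @param compartment compartment of the NADH/NAD pair (default "c").
#' @return an object of class \code{phpp_grid}.
#' @export
phpp_scan <- function(model, glc_range = c(0, 10), o2_range = c(0, 14),
                      steps = 20, compartment = "c") {
  if (steps < 2) stop("steps must be >= 2 (degenerate grid)")
  if (diff(glc_range) <= 0 || diff(o2_range) <= 0)
    stop("uptake ranges must be non-degenerate")
  ex_glc <- find_exchange(model, "glucose")
  ex_o2 <- find_exchange(model, "oxygen")
  ex_eth <- find_exchange(model, "ethanol")
  glc_axis <- seq(glc_range[1], glc_range[2], length.out = steps)
  o2_axis <- seq(o2_range[1], o2_range[2], length.out = steps)
  dims <- c(steps, steps)
  growth <- eth <- gmap <- matrix(NA_real_, steps, steps)
  feas <- matrix(FALSE, steps, steps)
  cls <- matrix(NA_character_, steps, steps)
  deg <- matrix(FALSE, steps, steps)
  for (i in seq_len(steps)) {
    mg <- set_uptake(model, ex_glc, glc_axis[i])
    for (j in seq_len(steps)) {
      mm <- set_uptake(mg, ex_o2, o2_axis[j])
      f <- fba(mm)
      if (f$status != "optimal" || f$objective < 1e-8) next
      feas[i, j] <- TRUE
      growth[i, j] <- f$objective
      eth[i, j] <- f$fluxes[[ex_eth]]
      g <- gamma_red(f, compartment)
      gmap[i, j] <- g$gamma_red
      cls[i, j] <- g$classification
      deg[i, j] <- g$degenerate
    }
  }
  loo <- line_of_optimality(model, glc_axis)
  o2_step <- diff(o2_axis[1:2])
  o2lim <- matrix(FALSE, steps, steps)
  for (i in seq_len(steps))
    if (!is.na(loo$o2[i]))
      o2lim[i, ] <- o2_axis < loo$o2[i] - o2_step   # one-step exclusion zone
  structure(list(glc_axis = glc_axis, o2_axis = o2_axis, growth = growth,
                 ethanol = eth, gamma_red = gmap, classification = cls,
                 degenerate = deg, feasible = feas, loo = loo,
                 o2_limited = o2lim, compartment = compartment,
                 model_id = model$model_id),
            class = "phpp_grid")
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat("Phenotypic phase plane grid (", x$model_id, "): ",
      length(x$glc_axis), "x", length(x$o2_axis), " points\n", sep = "")
  cat("  glucose ", min(x$glc_axis), "-", max(x$glc_axis),
      ", oxygen ", min(x$o2_axis), "-", max(x$o2_axis),
      " mmol gDW^-1 h^-1\n", sep = "")
  cat("  feasible:", sum(x$feasible),
      " oxygen-limited (off-line):", sum(x$o2_limited & x$feasible), "\n")
  tab <- table(x$classification[x$feasible & x$o2_limited])
  if (length(tab)) {
    cat("  availability in the oxygen-limited region:\n")
    print(tab)
  }
  invisible(x)
}

#' @export
as.data.frame.phpp_grid <- function(x, ...) {
  n <- length(x$glc_axis)
  data.frame(glc = rep(x$glc_axis, times = n),
             o2 = rep(x$o2_axis, each = n),
             growth = as.vector(x$growth),
             ethanol = as.vector(x$ethanol),
             gamma_red = as.vector(x$gamma_red),
             classification = as.vector(x$classification),
             feasible = as.vector(x$feasible),
             o2_limited = as.vector(x$o2_limited),
             stringsAsFactors = FALSE)
}

#' @export
plot.phpp_grid <- function(x, what = c("growth", "gamma_red"), ...) {
  what <- match.arg(what)
  z <- if (what == "growth") x$growth else x$gamma_red
  graphics::image(x$glc_axis, x$o2_axis, z,
                  xlab = "glucose uptake (mmol/gDW/h)",
                  ylab = "oxygen uptake (mmol/gDW/h)",
                  main = paste(x$model_id, "-", what),
                  col = grDevices::hcl.colors(24,
                    if (what == "growth") "viridis" else "Blue-Red 2"), ...)
  ok <- !is.na(x$loo$o2)
  graphics::lines(x$loo$glc[ok], x$loo$o2[ok], lty = 2, lwd = 2)
  invisible(x)
}

#' Availability pattern of a phase-plane grid
#'
#' Summarises the reducing-capacity classification over the feasible,
#' strictly oxygen-limited grid points. \code{all_excess_o2_limited} (every
#' such point in excess) is the operational definition of the
#' Crabtree-positive pattern; \code{subset_excess} (a proper, non-empty
#' subset in excess) is the Crabtree-negative one.
#'
#' @param grid a \code{phpp_grid}.
#' @return list with \code{fraction_excess}, \code{n_o2_limited},
#'   \code{all_excess_o2_limited}, \code{subset_excess}.
#' @export
availability_pattern <- function(grid) {
  sel <- grid$feasible & grid$o2_limited
  if (!any(sel))
    stop("grid has no feasible oxygen-limited points")
  cl <- grid$classification[sel]
  frac <- mean(cl == "excess")
  list(fraction_excess = frac,
       n_o2_limited = sum(sel),
       all_excess_o2_limited = frac == 1,
       subset_excess = frac > 0 && frac < 1)
}

#' Export a phase-plane grid as CSV (long format)
#'
#' @param grid a \code{phpp_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phpp_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
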