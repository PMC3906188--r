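## Production envelopes: min/max product secretion as a function of growth
## rate, and the growth-coupling verdict (is production forced at maximal
## growth?).

#' Ethanol-biomass production envelope
#'
#' Computes maximal growth Z*, then at \code{n_points} evenly spaced growth
#' values in [0, Z*] fixes growth (two-sided band of 1e-9) and minimises /
#' maximises the product flux.
#'
#' @param model a \code{metabolic_model} (FBA must be feasible).
#' @param product_id reaction id of the product (exchange) flux.
#' @param n_points number of growth points, >= 2 (default 20).
#' @return an object of class \code{production_envelope}.
#' @export
production_envelope <- function(model, product_id, n_points = 20) {
  if (n_points < 2) stop("n_points must be >= 2")
  j <- rxn_index(model, product_id)
  obj_id <- objective_reaction(model)
  f <- fba(model, degeneracy = FALSE)
  if (f$status != "optimal")
    stop("base model FBA is ", f$status, "; envelope undefined")
  zmax <- f$objective
  if (model$lb[j] == 0 && model$ub[j] == 0)
    warning("product '", product_id, "' has zero bounds; envelope is all zero",
            call. = FALSE)
  growth_points <- seq(0, zmax, length.out = n_points)
  lo <- hi <- rep(NA_real_, n_points)
  for (k in seq_len(n_points)) {
    fx <- stats::setNames(list(growth_points[k] + c(-1e-9, 1e-9)), obj_id)
    rlo <- optimize_flux(model, product_id, maximize = FALSE, fix = fx)
    rhi <- optimize_flux(model, product_id, maximize = TRUE, fix = fx)
    if (rlo$status == "optimal") lo[k] <- rlo$obj
    if (rhi$status == "optimal") hi[k] <- rhi$obj
  }
  env <- structure(list(growth_points = growth_points, min_product = lo,
                        max_product = hi, product_id = product_id,
                        max_growth = zmax, model_id = model$model_id),
                   class = "production_envelope")
  env$coupling <- coupling(env)
  env
}

#' Growth-coupling verdict of an envelope
#'
#' \code{coupled} iff the minimal product flux at the maximal-growth point
#' exceeds 1e-6 (growth forces production); \code{non_coupled} otherwise.
#'
#' @param envelope a \code{production_envelope} computed up to the model's
#'   maximal growth.
#' @return \code{"coupled"} or \code{"non_coupled"}.
#' @export
coupling <- function(envelope) {
  stopifnot(inherits(envelope, "production_envelope"))
  mn <- envelope$min_product[length(envelope$min_product)]
  if (!is.na(mn) && mn > 1e-6) "coupled" else "non_coupled"
}

#' @export
print.production_envelope <- function(x, ...) {
  cat("Production envelope (", x$model_id, "): ", x$product_id,
      " vs growth\n", sep = "")
  cat("  max growth ", format(x$max_growth, digits = 6), " h^-1; product at ",
      "max growth in [", format(x$min_product[length(x$min_product)], digits = 4),
      ", ", format(x$max_product[length(x$max_product)], digits = 4),
      "] mmol gDW^-1 h^-1\n", sep = "")
  cat("  verdict:", x$coupling, "\n")
  invisible(x)
}

#' @export
as.data.frame.production_envelope <- function(x, ...) {
  data.frame(growth = x$growth_points, min_product = x$min_product,
             max_product = x$max_product)
}

#' @export
plot.production_envelope <- function(x, anchors = NULL, ...) {
  graphics::plot(x$growth_points, x$max_product, type = "l", lwd = 2,
                 xlab = "growth rate (1/h)",
                 ylab = paste(x$product_id, "(mmol/gDW/h)"),
                 main = paste("Production envelope -", x$model_id),
                 ylim = range(c(0, x$max_product, x$min_product), na.rm = TRUE),
                 ...)
  graphics::lines(x$growth_points, x$min_product, lwd = 2, lty = 2)
  if (!is.null(anchors))
    graphics::points(anchors$growth, anchors$product, pch = 8, cex = 1.4)
  invisible(x)
}
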