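## Pipeline entry point tying the stages together: resolves a run
## configuration, executes one named stage and writes CSV/JSON artifacts
## plus a run log with the solver settings and model checksum. A thin
## command-line front-end lives in inst/scripts/redoxplane.

#' Run configuration
#'
#' @param model model source: a file path or \code{"toy:sc"} /
#'   \code{"toy:ss"}.
#' @param glc,o2 uptake magnitudes; \code{o2} may be \code{"unbounded"}.
#' @param glc_range,o2_range,steps phase-plane grid settings.
#' @param compartment NADH/NAD compartment for gamma_red.
#' @param min_growth,max_deletions,sink_range screen settings.
#' @param out_dir output directory (created if missing).
#' @param seed recorded in the log (the pipeline itself is deterministic).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(model = "toy:sc", glc = 10, o2 = "unbounded",
                       glc_range = c(0, 10), o2_range = c(0, 14),
                       steps = 20, compartment = "c", min_growth = 0.1,
                       max_deletions = 3, sink_range = c(0.1, 0.6),
                       out_dir = ".", seed = 1L) {
  cfg <- list(model = model, glc = glc, o2 = o2, glc_range = glc_range,
              o2_range = o2_range, steps = steps, compartment = compartment,
              min_growth = min_growth, max_deletions = max_deletions,
              sink_range = sink_range, out_dir = out_dir, seed = seed)
  if (!is.character(model) || length(model) != 1)
    stop("config field 'model' must be a single path or toy:sc / toy:ss")
  if (!model %in% c("toy:sc", "toy:ss") && !file.exists(model))
    stop("config field 'model': file not found: ", model)
  if (!identical(o2, "unbounded") && (!is.numeric(o2) || o2 < 0))
    stop("config field 'o2' must be non-negative or \"unbounded\"")
  if (!is.numeric(glc) || glc < 0) stop("config field 'glc' must be >= 0")
  structure(cfg, class = "run_config")
}

resolve_model <- function(cfg) {
  switch(cfg$model,
         "toy:sc" = toy_cerevisiae(),
         "toy:ss" = toy_stipitis(),
         read_model(cfg$model))
}

apply_uptakes <- function(m, cfg) {
  m <- set_uptake(m, find_exchange(m, "glucose"), cfg$glc)
  set_uptake(m, find_exchange(m, "oxygen"), cfg$o2)
}

write_run_log <- function(cfg, path) {
  chk <- if (file.exists(cfg$model)) unname(tools::md5sum(cfg$model))
         else cfg$model
  jsonlite::write_json(list(config = unclass(cfg), model_checksum = chk,
                            solver = SOLVER_CONFIG,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Execute a pipeline stage
#'
#' @param command one of \code{"fba"}, \code{"envelope"}, \code{"phpp"},
#'   \code{"fva"}, \code{"screen"}, \code{"reproduce-toy"}.
#' @param config a \code{\link{run_config}}.
#' @return invisible list of the stage's result objects; artifact files are
#'   written under \code{config$out_dir}.
#' @export
run_stage <- function(command = c("fba", "envelope", "phpp", "fva",
                                  "screen", "reproduce-toy"),
                      config = run_config()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_log(config, file.path(config$out_dir, "run_log.json"))
  if (command == "reproduce-toy") return(invisible(reproduce_toy(config)))
  m <- apply_uptakes(resolve_model(config), config)
  out <- switch(command,
    fba = {
      f <- fba(m)
      utils::write.csv(data.frame(reaction = names(f$fluxes),
                                  flux = unname(f$fluxes)),
                       file.path(config$out_dir, "fluxes.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(metabolite = names(f$duals),
                                  shadow_price = unname(f$duals),
                                  degenerate = unname(f$degenerate)),
                       file.path(config$out_dir, "shadow_prices.csv"),
                       row.names = FALSE)
      f
    },
    envelope = {
      env <- production_envelope(m, find_exchange(m, "ethanol"))
      utils::write.csv(as.data.frame(env),
                       file.path(config$out_dir, "envelope.csv"),
                       row.names = FALSE)
      env
    },
    phpp = {
      mb <- resolve_model(config)   # grid sets its own uptakes
      grid <- phpp_scan(mb, config$glc_range, config$o2_range,
                        steps = config$steps,
                        compartment = config$compartment)
      write_phpp_csv(grid, file.path(config$out_dir, "phpp.csv"))
      pat <- availability_pattern(grid)
      jsonlite::write_json(pat, file.path(config$out_dir, "pattern.json"),
                           auto_unbox = TRUE, digits = NA)
      list(grid = grid, pattern = pat)
    },
    fva = {
      rep <- fva(m)
      utils::write.csv(as.data.frame(rep),
                       file.path(config$out_dir, "fva.csv"),
                       row.names = FALSE)
      jsonlite::write_json(rep$bins, file.path(config$out_dir, "bins.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    },
    screen = {
      mb <- resolve_model(config)
      cands <- screen_candidates(mb)
      sur <- pattern_screen(mb, cands, min_growth = config$min_growth,
                            glc_range = config$glc_range,
                            o2_range = config$o2_range,
                            compartment = config$compartment)
      df <- data.frame(
        deletion_set = vapply(sur, function(r)
          paste(r$deletion_set, collapse = "+"), ""),
        max_growth = vapply(sur, `[[`, 0, "max_growth"),
        fraction_excess = vapply(sur, function(r)
          r$pattern$fraction_excess, 0),
        stringsAsFactors = FALSE)
      utils::write.csv(df, file.path(config$out_dir, "screen.csv"),
                       row.names = FALSE)
      sur
    })
  invisible(out)
}

## candidate pruning for screens: drop exchanges, the objective and
## zero-span reactions at the reference state (cannot change the pattern)
screen_candidates <- function(model) {
  cands <- model$rxns$id[!model$exchange & model$obj == 0]
  ref <- tryCatch(fva(model), error = function(e) NULL)
  if (!is.null(ref)) {
    alive <- abs(ref$v_min) > 1e-9 | abs(ref$v_max) > 1e-9
    names(alive) <- ref$reaction
    cands <- cands[alive[cands]]
  }
  cands
}

#' Four-contrast toy reproduction suite
#'
#' Re-runs the qualitative contrasts the two bundled toy models are
#' calibrated to show (ethanol-growth coupling under oxygen limitation vs
#' none; all-excess vs subset-excess availability; span increase vs
#' invariance; deletion-induced pattern flip) and prints a pass/fail table.
#'
#' @param config a \code{\link{run_config}} (grid settings are honoured).
#' @return data.frame with columns \code{contrast}, \code{pass}.
#' @export
reproduce_toy <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- toy_cerevisiae(); ss <- toy_stipitis()
  loo_sc <- line_of_optimality(sc, 10)$o2[1]
  env_sc <- production_envelope(
    apply_uptakes(sc, run_config(glc = 10, o2 = loo_sc / 2)), "EX_etoh")
  env_ss <- production_envelope(
    apply_uptakes(ss, run_config(glc = 10, o2 = "unbounded")), "EX_etoh")
  grid_sc <- phpp_scan(sc, config$glc_range, config$o2_range, config$steps)
  grid_ss <- phpp_scan(ss, config$glc_range, config$o2_range, config$steps)
  pat_sc <- availability_pattern(grid_sc)
  pat_ss <- availability_pattern(grid_ss)
  prof_sc <- span_profile(sc)
  prof_ss <- span_profile(ss)
  grid_del <- phpp_scan(apply_deletions(ss, c("AOX", "THD", "POLYOL")),
                        config$glc_range, config$o2_range, config$steps)
  pat_del <- availability_pattern(grid_del)
  res <- data.frame(
    contrast = c("coupling: TOY-SC coupled under O2 limit, TOY-SS aerobic not",
                 "availability: TOY-SC all-excess, TOY-SS subset-excess",
                 "flux span: TOY-SS profile more invariant than TOY-SC",
                 "deletion flip: TOY-SS minus {AOX,THD,POLYOL} all-excess"),
    pass = c(env_sc$coupling == "coupled" && env_ss$coupling == "non_coupled",
             pat_sc$all_excess_o2_limited && pat_ss$subset_excess,
             prof_ss$invariance_metric < prof_sc$invariance_metric,
             pat_del$all_excess_o2_limited),
    stringsAsFactors = FALSE)
  print(res, row.names = FALSE)
  jsonlite::write_json(res, file.path(config$out_dir, "reproduce_toy.json"),
                       digits = NA)
  res
}
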