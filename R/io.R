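## Model I/O: BiGG-style JSON (read + write) and SBML (L3+FBC read/write,
## with the legacy L2 kinetic-law bound fallback). Written against the two
## dialects genome-scale yeast models are commonly distributed in.

#' Read a metabolic model from file
#'
#' @param path file path.
#' @param format \code{"sbml"}, \code{"bigg_json"} or \code{"auto"} (by file
#'   extension: .xml/.sbml vs .json).
#' @return a \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("auto", "sbml", "bigg_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "bigg_json"
  }
  m <- switch(format,
              sbml = read_sbml(path),
              bigg_json = read_bigg_json(path))
  if (all(m$obj == 0))
    warning("model '", m$model_id, "' has no objective reaction; ",
            "growth analyses will refuse to run", call. = FALSE)
  unreach <- check_connectivity(m)
  if (length(unreach))
    warning("objective precursors not reachable from any exchange: ",
            paste(unreach, collapse = ", "), call. = FALSE)
  m
}

read_bigg_json <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(d$reactions) || length(d$reactions) == 0)
    stop("parse error in '", path, "': model has zero reactions")
  if (is.null(d$metabolites) || length(d$metabolites) == 0)
    stop("parse error in '", path, "': model has zero metabolites")
  mets <- data.frame(
    id = vapply(d$metabolites, function(x) as.character(x$id), ""),
    name = vapply(d$metabolites, function(x) as.character(x$name %||% x$id), ""),
    compartment = vapply(d$metabolites, function(x)
      as.character(x$compartment %||% sub(".*_", "", x$id)), ""),
    stringsAsFactors = FALSE)
  nr <- length(d$reactions)
  lb <- ub <- obj <- numeric(nr)
  S <- matrix(0, nrow(mets), nr)
  rid <- rname <- rsub <- character(nr)
  for (j in seq_len(nr)) {
    r <- d$reactions[[j]]
    rid[j] <- as.character(r$id)
    rname[j] <- as.character(r$name %||% r$id)
    rsub[j] <- as.character(r$subsystem %||% "")
    lb[j] <- as.numeric(r$lower_bound %||% -DEFAULT_BOUND)
    ub[j] <- as.numeric(r$upper_bound %||% DEFAULT_BOUND)
    obj[j] <- as.numeric(r$objective_coefficient %||% 0)
    for (mid in names(r$metabolites)) {
      i <- match(mid, mets$id)
      if (is.na(i)) stop("parse error in '", path, "': reaction '", rid[j],
                         "' references unknown metabolite '", mid, "'")
      S[i, j] <- as.numeric(r$metabolites[[mid]])
    }
  }
  rxns <- data.frame(id = rid, name = rname, reversible = lb < 0,
                     subsystem = rsub, stringsAsFactors = FALSE)
  metabolic_model(id = as.character(d$id %||% basename(path)),
                  mets = mets, rxns = rxns, S = S,
                  lb = lb, ub = ub, obj = obj)
}

#' Write a model as BiGG-style JSON
#'
#' Canonical dump of the internal representation; \code{read_model} on the
#' written file reproduces S, bounds and objective exactly.
#'
#' @param m a \code{metabolic_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(m, path) {
  mets <- lapply(seq_len(nrow(m$mets)), function(i)
    list(id = m$mets$id[i], name = m$mets$name[i],
         compartment = m$mets$compartment[i]))
  rxns <- lapply(seq_len(nrow(m$rxns)), function(j) {
    nz <- which(m$S[, j] != 0)
    stoich <- as.list(m$S[nz, j])
    names(stoich) <- m$mets$id[nz]
    list(id = m$rxns$id[j], name = m$rxns$name[j],
         metabolites = stoich,
         lower_bound = m$lb[[j]], upper_bound = m$ub[[j]],
         subsystem = m$rxns$subsystem[j],
         objective_coefficient = m$obj[[j]])
  })
  jsonlite::write_json(list(id = m$model_id, metabolites = mets,
                            reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML ------------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing"))
    stop("parse error in '", path, "': no <model> element")
  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("parse error in '", path, "': model has zero species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets <- mets[!boundary, , drop = FALSE]   # boundary species are sinks

  ## fbc global parameters (bound values)
  pars <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("parse error in '", path, "': model has zero reactions")
  nr <- length(rx)
  S <- matrix(0, nrow(mets), nr)
  lb <- rep(NA_real_, nr); ub <- rep(NA_real_, nr); obj <- numeric(nr)
  rid <- xml2::xml_attr(rx, "id")
  rname <- ifelse(is.na(xml2::xml_attr(rx, "name")), rid,
                  xml2::xml_attr(rx, "name"))
  rev <- !(xml2::xml_attr(rx, "reversible") %in% c("false", "0"))
  for (j in seq_len(nr)) {
    r <- rx[[j]]
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(r, paste0("./s:", tag, "/s:speciesReference"), ns)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        i <- match(sid, mets$id)
        if (!is.na(i)) S[i, j] <- S[i, j] + side * st
      }
    }
    ## fbc v2 bounds reference global parameters
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(parval)) lb[j] <- parval[[lbp]]
    if (!is.na(ubp) && ubp %in% names(parval)) ub[j] <- parval[[ubp]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      ## legacy L2 dialect: kinetic-law local parameters
      kl <- xml2::xml_find_all(
        r, ".//s:kineticLaw//s:parameter | .//s:kineticLaw//s:localParameter", ns)
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kv <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lb[j]) && "LOWER_BOUND" %in% kid)
          lb[j] <- kv[match("LOWER_BOUND", kid)]
        if (is.na(ub[j]) && "UPPER_BOUND" %in% kid)
          ub[j] <- kv[match("UPPER_BOUND", kid)]
        if ("OBJECTIVE_COEFFICIENT" %in% kid)
          obj[j] <- kv[match("OBJECTIVE_COEFFICIENT", kid)]
      }
    }
    if (is.na(lb[j])) lb[j] <- if (rev[j]) -DEFAULT_BOUND else 0
    if (is.na(ub[j])) ub[j] <- DEFAULT_BOUND
  }

  ## fbc objective
  fo <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (length(fo)) {
    fr <- xml2::xml_attr(fo, "reaction")
    fc <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    for (k in seq_along(fr)) {
      j <- match(fr[k], rid)
      if (!is.na(j)) obj[j] <- fc[k]
    }
  }
  empty <- colSums(S != 0) == 0
  if (any(empty)) {   # pure boundary-species reactions become exchanges on 'e'
    S <- S[, !empty, drop = FALSE]
    warn_ids <- rid[empty]
    rid <- rid[!empty]; rname <- rname[!empty]; rev <- rev[!empty]
    lb <- lb[!empty]; ub <- ub[!empty]; obj <- obj[!empty]
    warning("dropped reaction(s) with only boundary species: ",
            paste(warn_ids, collapse = ", "), call. = FALSE)
  }
  rxns <- data.frame(id = rid, name = rname,
                     reversible = rev | lb < 0, subsystem = "",
                     stringsAsFactors = FALSE)
  mid <- xml2::xml_attr(model, "id")
  metabolic_model(id = if (is.na(mid)) basename(path) else mid,
                  mets = mets, rxns = rxns, S = S, lb = lb, ub = ub, obj = obj)
}

#' Write a model as SBML Level 3 with flux constraints
#'
#' @param m a \code{metabolic_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_sbml <- function(m, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- textConnection("sbml_out", "w", local = TRUE)
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(m$model_id), '" fbc:strict="true">')
  comps <- unique(m$mets$compartment)
  w('    <listOfCompartments>')
  for (cc in comps)
    w('      <compartment id="', cc, '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(m$mets)))
    w('      <species id="', esc(m$mets$id[i]), '" name="', esc(m$mets$name[i]),
      '" compartment="', m$mets$compartment[i],
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  w('    </listOfSpecies>')
  ## one shared parameter per distinct bound value
  vals <- sort(unique(c(m$lb, m$ub)))
  pid <- sprintf("fb_%d", seq_along(vals))
  pfor <- function(v) pid[match(v, vals)]
  w('    <listOfParameters>')
  for (k in seq_along(vals))
    w('      <parameter id="', pid[k], '" value="',
      format(vals[k], digits = 17), '" constant="true"/>')
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (j in seq_len(nrow(m$rxns))) {
    w('      <reaction id="', esc(m$rxns$id[j]), '" name="', esc(m$rxns$name[j]),
      '" reversible="', tolower(as.character(m$rxns$reversible[j])),
      '" fast="false" fbc:lowerFluxBound="', pfor(m$lb[[j]]),
      '" fbc:upperFluxBound="', pfor(m$ub[[j]]), '">')
    nz <- which(m$S[, j] != 0)
    rs <- nz[m$S[nz, j] < 0]; ps <- nz[m$S[nz, j] > 0]
    if (length(rs)) {
      w('        <listOfReactants>')
      for (i in rs)
        w('          <speciesReference species="', esc(m$mets$id[i]),
          '" stoichiometry="', format(-m$S[i, j], digits = 17),
          '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(ps)) {
      w('        <listOfProducts>')
      for (i in ps)
        w('          <speciesReference species="', esc(m$mets$id[i]),
          '" stoichiometry="', format(m$S[i, j], digits = 17),
          '" constant="true"/>')
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  ob <- which(m$obj != 0)
  if (length(ob)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (j in ob)
      w('          <fbc:fluxObjective fbc:reaction="', esc(m$rxns$id[j]),
        '" fbc:coefficient="', format(m$obj[[j]], digits = 17), '"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  close(con)
  writeLines(sbml_out, path)
  invisible(path)
}
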