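#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attr xml_attrs
#'   xml_name xml_ns
NULL

# Namespace URIs of the SBML subset we read and write.
SBML_NS_CORE   <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_NS_FBC    <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_NS_GROUPS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

# Attribute lookup tolerant to the namespace prefix actually used in the
# document (BiGG exports use "fbc:"/"groups:", but the prefix is free).
attr_any <- function(node, names) {
  at <- xml2::xml_attrs(node)
  for (nm in names) if (nm %in% names(at)) return(unname(at[[nm]]))
  hit <- which(sub("^.*:", "", names(at)) %in% sub("^.*:", "", names))
  if (length(hit)) unname(at[[hit[1L]]]) else NA_character_
}

#' Parse an SBML metabolic model
#'
#' Reads SBML Level 3 with the flux-balance-constraints (fbc) package:
#' species with compartments, reactions with stoichiometry and per-reaction
#' flux bounds, and the active maximisation/minimisation objective.
#' Reaction subsystems are taken from the SBML groups package when present.
#' Documents without fbc bounds on every reaction, or without an active
#' objective, are rejected rather than repaired.
#'
#' @param sbml raw vector, single string, or path to an SBML file.
#' @return a `model_record`: list with `model_id`, `source_db`, `species`
#'   (data.frame id/name/compartment), `reactions` (data.frame id/name/
#'   lower_bound/upper_bound/subsystem), `stoichiometry` (named list:
#'   reaction id -> named numeric of signed species coefficients; negative
#'   = consumed), `objective` (named numeric, reaction id -> coefficient)
#'   and `objective_sense` ("maximize" or "minimize").
#' @export
read_sbml_model <- function(sbml) {
  doc <- tryCatch(read_sbml_doc(sbml), error = function(e)
    ft_abort(paste0("not parseable as XML: ", conditionMessage(e)), "format_error"))
  model <- xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    ft_abort("no <model> element in SBML document", "format_error")

  params <- xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(
    as.numeric(vapply(params, function(p) attr_any(p, "value"), "")),
    vapply(params, function(p) attr_any(p, "id"), ""))

  sp_nodes <- xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  species <- data.frame(
    species_id  = vapply(sp_nodes, function(s) attr_any(s, "id"), ""),
    name        = vapply(sp_nodes, function(s) attr_any(s, "name") %||% NA_character_, ""),
    compartment = vapply(sp_nodes, function(s) attr_any(s, "compartment"), ""),
    stringsAsFactors = FALSE)
  species$name[is.na(species$name)] <- species$species_id[is.na(species$name)]
  boundary <- vapply(sp_nodes, function(s)
    identical(attr_any(s, "boundaryCondition"), "true"), logical(1))

  rx_nodes <- xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  bound_value <- function(node, which) {
    ref <- attr_any(node, c(paste0("fbc:", which), which))
    if (is.na(ref)) return(NA_real_)
    num <- suppressWarnings(as.numeric(ref))
    if (!is.na(num)) return(num)           # inline numeric (non-strict dialects)
    if (!ref %in% names(pval)) return(NA_real_)
    pval[[ref]]
  }
  stoich_of <- function(node) {
    out <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml_find_all(node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (r in refs) {
        sp <- attr_any(r, "species")
        coef <- suppressWarnings(as.numeric(attr_any(r, "stoichiometry")))
        if (is.na(coef)) coef <- 1
        cur <- if (sp %in% names(out)) out[[sp]] else 0
        out[sp] <- cur + sgn * coef
      }
    }
    # drop boundary-condition species (unconstrained sinks/sources) and
    # coefficients that cancelled to zero
    out <- out[!names(out) %in% species$species_id[boundary]]
    out[out != 0]
  }

  rx_id <- vapply(rx_nodes, function(r) attr_any(r, "id"), "")
  lbv <- vapply(rx_nodes, bound_value, numeric(1), which = "lowerFluxBound")
  ubv <- vapply(rx_nodes, bound_value, numeric(1), which = "upperFluxBound")
  if (any(is.na(lbv)) || any(is.na(ubv)))
    ft_abort(sprintf("reaction(s) without resolvable fbc flux bounds: %s",
                     paste(rx_id[is.na(lbv) | is.na(ubv)], collapse = ", ")),
             "format_error")
  if (any(lbv > ubv))
    ft_abort("reaction with lower_bound > upper_bound", "format_error")

  stoich <- lapply(rx_nodes, stoich_of)
  names(stoich) <- rx_id
  bad_sp <- setdiff(unique(unlist(lapply(stoich, names))), species$species_id)
  if (length(bad_sp))
    ft_abort(sprintf("stoichiometry references unknown species: %s",
                     paste(bad_sp, collapse = ", ")), "format_error")

  # subsystems from the groups package
  subsystem <- stats::setNames(rep(NA_character_, length(rx_id)), rx_id)
  for (g in xml_find_all(doc, "//*[local-name()='group']")) {
    gname <- attr_any(g, c("groups:name", "name"))
    if (is.na(gname)) gname <- attr_any(g, c("groups:id", "id"))
    for (mb in xml_find_all(g, ".//*[local-name()='member']")) {
      ref <- attr_any(mb, c("groups:idRef", "idRef"))
      if (!is.na(ref) && ref %in% rx_id) subsystem[[ref]] <- gname
    }
  }

  # active objective
  objectives <- xml_find_all(doc, "//*[local-name()='listOfObjectives']")
  if (!length(objectives))
    ft_abort("SBML document carries no fbc objective", "format_error")
  active <- attr_any(objectives[[1L]], c("fbc:activeObjective", "activeObjective"))
  obj_nodes <- xml_find_all(doc, "//*[local-name()='objective']")
  pick <- NULL
  for (o in obj_nodes) {
    oid <- attr_any(o, c("fbc:id", "id"))
    if (is.na(active) || identical(oid, active)) { pick <- o; break }
  }
  if (is.null(pick))
    ft_abort("active fbc objective not found", "format_error")
  sense <- attr_any(pick, c("fbc:type", "type")) %||% "maximize"
  fo <- xml_find_all(pick, ".//*[local-name()='fluxObjective']")
  if (!length(fo))
    ft_abort("fbc objective lists no flux objectives", "format_error")
  objective <- stats::setNames(
    vapply(fo, function(x) as.numeric(attr_any(x, c("fbc:coefficient", "coefficient"))), numeric(1)),
    vapply(fo, function(x) attr_any(x, c("fbc:reaction", "reaction")), ""))
  bad_obj <- setdiff(names(objective), rx_id)
  if (length(bad_obj))
    ft_abort(sprintf("objective references unknown reaction(s): %s",
                     paste(bad_obj, collapse = ", ")), "format_error")

  reactions <- data.frame(
    reaction_id = rx_id,
    name = vapply(rx_nodes, function(r) {
      nm <- attr_any(r, "name"); if (is.na(nm)) attr_any(r, "id") else nm
    }, ""),
    lower_bound = lbv, upper_bound = ubv,
    subsystem = unname(subsystem),
    stringsAsFactors = FALSE)

  structure(list(
    model_id = attr_any(model, "id") %||% "model",
    source_db = NA_character_,
    species = species[, c("species_id", "name", "compartment")],
    reactions = reactions,
    stoichiometry = stoich,
    objective = objective,
    objective_sense = if (identical(sense, "minimize")) "minimize" else "maximize"
  ), class = "model_record")
}

read_sbml_doc <- function(sbml) {
  if (is.raw(sbml)) return(read_xml(sbml))
  if (is.character(sbml) && length(sbml) == 1L && !grepl("<", sbml, fixed = TRUE))
    return(read_xml(sbml))              # a path
  read_xml(paste(sbml, collapse = "\n"))
}

#' @export
print.model_record <- function(x, ...) {
  cat(sprintf("<model_record> %s  (%d species, %d reactions)\n",
              x$model_id, nrow(x$species), nrow(x$reactions)))
  cat(sprintf("  objective (%s): %s\n", x$objective_sense,
              paste(sprintf("%g*%s", x$objective, names(x$objective)), collapse = " + ")))
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialise a model record to SBML
#'
#' Writes SBML L3V1 with fbc-v2 bounds/objective (strict dialect: every
#' reaction's bounds are parameter references) and, when any reaction carries
#' a subsystem, a groups-v1 partonomy. The output is deterministic: the same
#' record always yields byte-identical SBML, which is what makes model-file
#' integrity checks meaningful.
#'
#' @param model a `model_record`.
#' @return single string containing the SBML document.
#' @export
write_sbml_model <- function(model) {
  stopifnot(inherits(model, "model_record"))
  sp <- model$species
  rx <- model$reactions
  num <- function(x) formatC(x, format = "g", digits = 15)

  # bound parameters, deduplicated by value
  vals <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals) - 1L), num(vals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:groups="%s" ',
                   'level="3" version="1" fbc:required="false" groups:required="false">'),
            SBML_NS_CORE, SBML_NS_FBC, SBML_NS_GROUPS),
    sprintf('  <model id="%s" fbc:strict="true">', xml_escape(model$model_id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            xml_escape(sort(unique(sp$compartment)))),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'),
            xml_escape(sp$species_id), xml_escape(sp$name), xml_escape(sp$compartment)),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>', pid, names(pid)),
    '    </listOfParameters>',
    '    <listOfReactions>')

  for (i in seq_len(nrow(rx))) {
    rid <- rx$reaction_id[i]
    st <- model$stoichiometry[[rid]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(rid), xml_escape(rx$name[i]),
      if (rx$lower_bound[i] < 0) "true" else "false",
      pid[[num(rx$lower_bound[i])]], pid[[num(rx$upper_bound[i])]]))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) lines <- c(lines,
      '        <listOfReactants>',
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              xml_escape(names(reac)), num(-unname(reac))),
      '        </listOfReactants>')
    if (length(prod)) lines <- c(lines,
      '        <listOfProducts>',
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              xml_escape(names(prod)), num(unname(prod))),
      '        </listOfProducts>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    sprintf('    <fbc:listOfObjectives fbc:activeObjective="obj">'),
    sprintf('      <fbc:objective fbc:id="obj" fbc:type="%s">', model$objective_sense),
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
            xml_escape(names(model$objective)), num(unname(model$objective))),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>')

  subs <- rx$subsystem[!is.na(rx$subsystem)]
  if (length(subs)) {
    lines <- c(lines, '    <groups:listOfGroups>')
    for (s in sort(unique(subs))) {
      members <- rx$reaction_id[!is.na(rx$subsystem) & rx$subsystem == s]
      lines <- c(lines,
        sprintf('      <groups:group groups:id="g_%s" groups:kind="partonomy" groups:name="%s">',
                gsub("[^A-Za-z0-9_]", "_", s), xml_escape(s)),
        '        <groups:listOfMembers>',
        sprintf('          <groups:member groups:idRef="%s"/>', xml_escape(members)),
        '        </groups:listOfMembers>',
        '      </groups:group>')
    }
    lines <- c(lines, '    </groups:listOfGroups>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  paste0(paste(lines, collapse = "\n"), "\n")
}
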