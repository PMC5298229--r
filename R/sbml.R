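# SBML Level 3 Version 1 export of an expanded reaction network.

.sbmlSanitize <- function(x) {
  id <- gsub("[^A-Za-z0-9_]", "_", x)
  id <- gsub("_+", "_", id)
  id <- sub("^([0-9])", "x\\1", id)
  make.unique(id, sep = "_")
}

.mathTimes <- function(doc, parent, cis) {
  math <- xml2::xml_add_child(parent, "math",
                              xmlns = "http://www.w3.org/1998/Math/MathML")
  if (length(cis) == 1L) {
    xml2::xml_add_child(math, "ci", cis)
  } else {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    for (ci in cis) xml2::xml_add_child(ap, "ci", ci)
  }
}

#' Export a reaction network to SBML Level 3
#'
#' Writes the expanded network as a flat SBML L3V1 model: one compartment per
#' location in use, one species per network species (canonical label kept as
#' the species \code{name}; ids are sanitized \code{S1..Sn}), one global
#' parameter per resolved rate constant and one reaction per network reaction
#' with an explicit mass-action kinetic law.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @param params ParameterSet (or named vector) resolving every rate symbol.
#' @param path output file.
#' @param modelId SBML model id.
#' @param initial optional named initial concentrations (by canonical label).
#' @return invisibly, a data.frame mapping SBML species ids to canonical
#'   labels.
#' @export
exportSBML <- function(network, params, path, modelId = "vegferk",
                       initial = NULL) {
  if (is(params, "ParameterSet")) params <- params@values
  rx <- network@reactions
  miss <- setdiff(unique(rx$rateName), names(params))
  if (length(miss))
    stop("missing parameter symbol(s): ", paste(miss, collapse = ", "))
  n <- length(network@labels)
  sid <- paste0("S", seq_len(n))
  locs <- unique(vapply(network@species, function(s) s@location, ""))
  cid <- stats::setNames(.sbmlSanitize(locs), locs)

  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = modelId)

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (l in locs)
    xml2::xml_add_child(lc, "compartment", id = cid[[l]], name = l,
                        constant = "true", spatialDimensions = "3", size = "1")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(n)) {
    init <- if (!is.null(initial) && network@labels[i] %in% names(initial))
      initial[[network@labels[i]]] else 0
    xml2::xml_add_child(ls, "species", id = sid[i], name = network@labels[i],
      compartment = cid[[network@species[[i]]@location]],
      initialConcentration = format(init, digits = 15),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  kv <- unname(params[rx$rateName]) * rx$factor
  kid <- paste0("k", seq_len(nrow(rx)))
  for (j in seq_len(nrow(rx)))
    xml2::xml_add_child(lp, "parameter", id = kid[j],
      name = paste0(rx$rateName[j], " x ", format(rx$factor[j])),
      value = format(kv[j], digits = 15), constant = "true")

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(rx))) {
    re <- rx$reactants[[j]]; pr <- rx$products[[j]]
    rn <- xml2::xml_add_child(lr, "reaction", id = paste0("R", j),
                              name = rx$rule[j], reversible = "false")
    if (length(re)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in re)
        xml2::xml_add_child(lre, "speciesReference", species = sid[i],
                            stoichiometry = "1", constant = "true")
    }
    if (length(pr)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in pr)
        xml2::xml_add_child(lpr, "speciesReference", species = sid[i],
                            stoichiometry = "1", constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    .mathTimes(doc, kl, c(kid[j], sid[re]))
  }
  xml2::write_xml(doc, path)
  invisible(data.frame(id = sid, label = network@labels,
                       stringsAsFactors = FALSE))
}

#' Count species and reactions in an SBML file
#'
#' Light-weight round-trip check for \code{\link{exportSBML}}.
#'
#' @param path SBML file.
#' @return named integer vector \code{c(species, reactions, compartments,
#'   parameters)}.
#' @export
sbmlCounts <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  cnt <- function(xp) length(xml2::xml_find_all(doc, xp, ns))
  c(species = cnt("//s:listOfSpecies/s:species"),
    reactions = cnt("//s:listOfReactions/s:reaction"),
    compartments = cnt("//s:listOfCompartments/s:compartment"),
    parameters = cnt("//s:listOfParameters/s:parameter"))
}
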