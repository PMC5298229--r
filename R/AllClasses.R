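#' @import methods
#' @importFrom stats approx cor optimize rnorm runif setNames uniroot median quantile
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib vegferk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.locations <- c("surface", "endosome", "solution", "cytosol", "ER", "membrane", "sink")

#' Molecule type declaration
#'
#' A molecule type declares a named protein (or ligand) together with its
#' binding/modification sites and, for each site, the set of allowed internal
#' states.  Sites with a single allowed state are pure binding sites; sites
#' with several states (e.g. a phosphotyrosine with states \code{U}/\code{P})
#' can additionally be modified by rules.
#'
#' @slot name molecule type identifier.
#' @slot sites named list; one character vector of allowed states per site
#'   (first element is the default state).
#' @slot isMembrane logical; membrane-anchored molecules keep complexes at the
#'   plasma membrane or endosome, soluble molecules released from a membrane
#'   complex return to solution.
#' @export
setClass("MoleculeType",
  representation(name = "character", sites = "list", isMembrane = "logical"))

setValidity("MoleculeType", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("molecule type needs a single non-empty name")
  nm <- names(object@sites)
  if (length(object@sites) && (is.null(nm) || anyDuplicated(nm)))
    return("site names must be unique within a molecule type")
  if (any(!vapply(object@sites, length, 1L)))
    return("every site needs a non-empty state set")
  TRUE
})

#' Create a molecule type
#'
#' @param name identifier, e.g. \code{"VEGFR2"}.
#' @param sites named list mapping each site name to its allowed states; a
#'   site given as an unnamed character element (or a state vector of length
#'   one) is a pure binding site.  The first state listed is the default.
#' @param isMembrane logical flag for membrane anchoring.
#' @return A \linkS4class{MoleculeType}.
#' @examples
#' moleculeType("VEGFR2", list(L = "0", C = "0", Y = c("U", "P")), isMembrane = TRUE)
#' @export
moleculeType <- function(name, sites = list(), isMembrane = FALSE) {
  sites <- lapply(sites, as.character)
  new("MoleculeType", name = name, sites = sites, isMembrane = isMembrane)
}

setMethod("show", "MoleculeType", function(object) {
  toks <- vapply(names(object@sites), function(s) {
    st <- object@sites[[s]]
    if (length(st) > 1L) paste0(s, "~", paste(st, collapse = "~")) else s
  }, "")
  cat(sprintf("%s(%s)%s\n", object@name, paste(toks, collapse = ","),
              if (object@isMembrane) " [membrane]" else ""))
})

#' A complex species: a connected graph of molecule instances
#'
#' Molecules are referenced by integer index; \code{bonds} is an integer/character
#' edge list connecting (molecule, site) pairs; \code{states} carries the
#' internal state of every state-site.  The canonical \code{label} is invariant
#' under relabelling of molecule instances and is the identity of the species
#' inside a reaction network.
#'
#' @slot molecules character vector of molecule type names.
#' @slot states list (one named character vector per molecule: site -> state).
#' @slot bonds list of bonds, each \code{list(m1, s1, m2, s2)}.
#' @slot location compartment tag.
#' @slot label canonical label (filled by \code{\link{canonicalLabel}}).
#' @export
setClass("ComplexSpecies",
  representation(molecules = "character", states = "list", bonds = "list",
                 location = "character", label = "character"))

setValidity("ComplexSpecies", function(object) {
  n <- length(object@molecules)
  if (length(object@states) != n) return("one state vector per molecule required")
  if (!object@location %in% .locations)
    return(sprintf("unknown location '%s'", object@location))
  used <- character(0)
  for (b in object@bonds) {
    for (end in list(c(b$m1, b$s1), c(b$m2, b$s2))) {
      key <- paste(end, collapse = ".")
      if (key %in% used) return("each site may carry at most one bond")
      used <- c(used, key)
    }
    if (b$m1 < 1 || b$m1 > n || b$m2 < 1 || b$m2 > n)
      return("bond references molecule outside complex")
  }
  if (n > 1L && !.isConnected(n, object@bonds))
    return("bond graph must be connected")
  TRUE
})

.isConnected <- function(n, bonds) {
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b$m1]] <- c(adj[[b$m1]], b$m2)
    adj[[b$m2]] <- c(adj[[b$m2]], b$m1)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

setMethod("show", "ComplexSpecies", function(object) {
  cat(object@label, "\n")
})

#' A pattern over complex species
#'
#' Patterns are partial species: unmentioned sites are unconstrained, a site
#' may require a specific state (\code{states}), and each mentioned site has a
#' bond constraint (\code{"free"}, \code{"any"}, or a shared bond tag that must
#' connect to the correspondingly tagged site).  \code{location} of \code{NA}
#' matches any compartment.
#'
#' @slot molecules character vector of molecule type names.
#' @slot states list of named character vectors (site -> required state).
#' @slot bondSpec list of named character vectors (site -> "free"/"any"/tag).
#' @slot location compartment tag or NA.
#' @export
setClass("ComplexPattern",
  representation(molecules = "character", states = "list", bondSpec = "list",
                 location = "character"))

setMethod("show", "ComplexPattern", function(object) {
  cat("<pattern> ", patternToText(object), "\n", sep = "")
})

#' A reaction rule
#'
#' The generative unit of the network: one or two reactant patterns, a rate
#' constant symbol, and an action (bind, unbind, set a site state, transport
#' the complex, degrade it into per-molecule sink counters, or synthesise a
#' seed species).  Optional per-reactant constraints restrict matches to
#' complexes that contain / do not contain given molecule types or patterns.
#'
#' @slot name rule identifier.
#' @slot reactants list of \linkS4class{ComplexPattern} (length 0, 1 or 2).
#' @slot rateName parameter symbol resolved at ODE-emission time.
#' @slot kind rate-law kind ("mass-action" or "transport").
#' @slot action list describing the rewrite.
#' @slot constraints list (one per reactant) of
#'   \code{list(require=, exclude=, excludePattern=, maxSize=)}.
#' @export
setClass("ReactionRule",
  representation(name = "character", reactants = "list", rateName = "character",
                 kind = "character", action = "list", constraints = "list"))

setMethod("show", "ReactionRule", function(object) {
  cat(sprintf("rule %-22s [%s, k = %s] %s\n", object@name, object@kind,
              object@rateName, object@action$type))
})

#' A closed reaction network
#'
#' @slot species list of \linkS4class{ComplexSpecies}.
#' @slot labels canonical labels (same order as species).
#' @slot reactions data.frame with columns \code{rule}, \code{rateName},
#'   \code{factor} (statistical/symmetry factor), and list-columns
#'   \code{reactants}, \code{products} of species indices.
#' @slot observables named list of \code{list(pattern, weights)} where
#'   \code{weights} is a numeric vector over species (embedding counts).
#' @slot rejected number of rule applications rejected by the aggregate cap.
#' @export
setClass("ReactionNetwork",
  representation(species = "list", labels = "character", reactions = "data.frame",
                 observables = "list", rejected = "numeric"))

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions, %d observables\n",
              length(object@species), nrow(object@reactions),
              length(object@observables)))
})

#' Number of species in a network
#' @param network a \linkS4class{ReactionNetwork}
#' @return integer count
#' @export
numSpecies <- function(network) length(network@species)

#' Number of reactions in a network
#' @param network a \linkS4class{ReactionNetwork}
#' @return integer count
#' @export
numReactions <- function(network) nrow(network@reactions)

#' Model parameter set
#'
#' A flat named numeric vector of rate constants, Michaelis constants,
#' dissociation constants, total concentrations and geometry constants, with a
#' parallel unit annotation.  Values are accessed with \code{params["name"]}
#' via \code{[} or \code{\link{getParam}}.
#'
#' @slot values named numeric vector.
#' @slot units named character vector (same names).
#' @export
setClass("ParameterSet",
  representation(values = "numeric", units = "character"))

setValidity("ParameterSet", function(object) {
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("parameter values must have unique names")
  if (any(!is.finite(object@values))) return("parameter values must be finite")
  TRUE
})

#' @describeIn ParameterSet extract parameter values by name
#' @param x ParameterSet
#' @param i parameter name(s)
#' @export
setMethod("[", "ParameterSet", function(x, i) {
  out <- x@values[i]
  if (anyNA(out)) stop("unknown parameter(s): ", paste(i[is.na(out)], collapse = ", "))
  out
})

#' Replace parameter values
#' @param x ParameterSet
#' @param i parameter name(s)
#' @param value replacement numeric values
#' @export
setMethod("[<-", "ParameterSet", function(x, i, value) {
  if (!all(i %in% names(x@values)))
    stop("unknown parameter(s): ", paste(setdiff(i, names(x@values)), collapse = ", "))
  x@values[i] <- value
  x
})

#' Get one parameter value
#' @param params ParameterSet
#' @param name parameter name
#' @return numeric scalar
#' @export
getParam <- function(params, name) unname(params[name])

#' Set parameters, returning the modified set
#' @param params ParameterSet
#' @param ... name = value pairs
#' @return modified ParameterSet
#' @export
setParams <- function(params, ...) {
  v <- c(...)
  params[names(v)] <- v
  params
}

#' All parameter names
#' @param x ParameterSet
#' @export
setMethod("names", "ParameterSet", function(x) names(x@values))

setMethod("show", "ParameterSet", function(object) {
  cat(sprintf("ParameterSet with %d parameters\n", length(object@values)))
  df <- data.frame(value = object@values, unit = object@units[names(object@values)])
  print(head(df, 12))
  if (length(object@values) > 12) cat("...\n")
})

#' Convert a ParameterSet to a data.frame
#' @param x ParameterSet
#' @param ... ignored
#' @export
setMethod("as.data.frame", "ParameterSet", function(x, ...) {
  data.frame(parameter = names(x@values), value = unname(x@values),
             unit = unname(x@units[names(x@values)]), stringsAsFactors = FALSE)
})

#' Simulated time course of named observables
#'
#' @slot time time grid in seconds.
#' @slot observables numeric matrix, one column per named observable.
#' @slot dose applied VEGF dose (pM).
#' @export
setClass("TimeCourse",
  representation(time = "numeric", observables = "matrix", dose = "numeric"))

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse: %d time points over %.1f min, VEGF = %.3g pM\n",
              length(object@time), max(object@time) / 60, object@dose))
  cat("observables:", paste(colnames(object@observables), collapse = ", "), "\n")
})

#' @describeIn TimeCourse tidy data.frame (time in seconds plus one column per
#'   observable)
#' @param x TimeCourse
#' @param ... ignored
#' @export
setMethod("as.data.frame", "TimeCourse", function(x, ...) {
  data.frame(time = x@time, x@observables, check.names = FALSE)
})

#' Extract one observable trajectory
#' @param tc TimeCourse
#' @param name observable name
#' @return numeric vector along the time grid
#' @export
observable <- function(tc, name) {
  if (!name %in% colnames(tc@observables))
    stop("unknown observable: ", name)
  tc@observables[, name]
}

#' Time grid accessor
#' @param tc TimeCourse
#' @export
timeGrid <- function(tc) tc@time

#' Dose-response curve: per-dose peak of one observable
#'
#' @slot dose dose grid (pM), strictly increasing.
#' @slot response peak (max over time) of the observable at each dose.
#' @slot observable observable name.
#' @export
setClass("DoseResponse",
  representation(dose = "numeric", response = "numeric", observable = "character"))

setValidity("DoseResponse", function(object) {
  if (length(object@dose) != length(object@response))
    return("dose and response must have equal length")
  if (is.unsorted(object@dose, strictly = TRUE))
    return("doses must be strictly increasing")
  if (any(object@response < 0)) return("responses must be non-negative")
  TRUE
})

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse (%s): %d doses, %.3g - %.3g pM\n", object@observable,
              length(object@dose), min(object@dose), max(object@dose)))
})

#' @describeIn DoseResponse tidy data.frame
#' @param x DoseResponse
#' @param ... ignored
#' @export
setMethod("as.data.frame", "DoseResponse", function(x, ...) {
  data.frame(dose_pM = x@dose, response = x@response, observable = x@observable)
})

#' SignalModel: assembled whole-cell model
#'
#' Couples the expanded receptor \linkS4class{ReactionNetwork} to the
#' signalling-cascade and calcium layer, holding everything the compiled
#' right-hand side needs.  Build with \code{\link{buildModel}}.
#'
#' @slot network the receptor \linkS4class{ReactionNetwork}.
#' @slot params the \linkS4class{ParameterSet} the model was resolved with.
#' @slot cmodel list consumed by the compiled right-hand side (resolved rate
#'   constants, stoichiometry triplets, observable weights, cascade parameter
#'   vector).
#' @slot stateNames names of all state variables (network labels then cascade
#'   states).
#' @export
setClass("SignalModel",
  representation(network = "ReactionNetwork", params = "ParameterSet",
                 cmodel = "list", stateNames = "character"))

#' @describeIn SignalModel compact display
#' @param object SignalModel
#' @export
setMethod("show", "SignalModel", function(object) {
  cat("SignalModel:", numSpecies(object@network), "network species +",
      length(object@stateNames) - numSpecies(object@network),
      "cascade states,", numReactions(object@network), "reactions\n")
})
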