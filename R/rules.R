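# Reaction rules: constructors and the graph-rewrite that applies a rule to
# concrete species.

#' Create a reaction rule
#'
#' Low-level constructor; most users will go through the convenience wrappers
#' \code{\link{bindRule}}, \code{\link{unbindRule}}, \code{\link{stateRule}},
#' \code{\link{transportRule}}, \code{\link{degradeRule}} and
#' \code{\link{synthRule}}.
#'
#' @param name rule identifier.
#' @param reactants character vector of pattern texts (length 0, 1 or 2).
#' @param rateName parameter symbol for the rate constant.
#' @param action list with element \code{type} plus action arguments.
#' @param types named list of \linkS4class{MoleculeType}.
#' @param constraints list of per-reactant constraint lists
#'   (\code{require}, \code{exclude}, \code{excludePattern} (pattern text),
#'   \code{maxSize}); use \code{NULL} entries for unconstrained reactants.
#' @param kind "mass-action" or "transport".
#' @return a \linkS4class{ReactionRule}.
#' @export
reactionRule <- function(name, reactants, rateName, action, types,
                         constraints = NULL, kind = "mass-action") {
  pats <- lapply(reactants, parsePattern, types = types)
  if (is.null(constraints)) constraints <- vector("list", length(pats))
  constraints <- lapply(constraints, function(cs) {
    if (!is.null(cs$excludePattern) && is.character(cs$excludePattern))
      cs$excludePattern <- parsePattern(cs$excludePattern, types)
    cs
  })
  length(constraints) <- max(length(pats), 1L)
  symmetric <- length(reactants) == 2L && identical(reactants[1], reactants[2]) &&
    identical(constraints[[1]], constraints[[2]])
  action$symmetric <- symmetric
  new("ReactionRule", name = name, reactants = pats, rateName = rateName,
      kind = kind, action = action, constraints = constraints)
}

#' @rdname reactionRule
#' @param r1,r2 pattern texts for the two reactants (or one, for an
#'   intramolecular bond).
#' @param site1,site2 \code{c(patternMoleculeIndex, siteName)} giving the two
#'   sites to join; for two-reactant rules the indices refer to each reactant's
#'   own pattern.
#' @param location location of the bound product, or \code{NA} to inherit the
#'   non-solution reactant location.
#' @export
bindRule <- function(name, r1, r2 = NULL, site1, site2, rateName, types,
                     constraints = NULL, location = NA_character_) {
  reactionRule(name, c(r1, r2), rateName,
               list(type = "bind",
                    end1 = list(m = as.integer(site1[[1]]), s = site1[[2]]),
                    end2 = list(m = as.integer(site2[[1]]), s = site2[[2]]),
                    intra = is.null(r2), location = location),
               types, constraints)
}

#' @rdname reactionRule
#' @param pattern pattern text containing the tagged bond to break.
#' @param bondEnd \code{c(patternMoleculeIndex, siteName)}: one end of the bond
#'   that the rule breaks.
#' @export
unbindRule <- function(name, pattern, bondEnd, rateName, types, constraints = NULL) {
  reactionRule(name, pattern, rateName,
               list(type = "unbind",
                    end = list(m = as.integer(bondEnd[[1]]), s = bondEnd[[2]])),
               types, constraints)
}

#' @rdname reactionRule
#' @param molecule pattern molecule index whose site changes state.
#' @param site site name.
#' @param state new state.
#' @export
stateRule <- function(name, pattern, molecule, site, state, rateName, types,
                      constraints = NULL) {
  reactionRule(name, pattern, rateName,
               list(type = "setState", m = as.integer(molecule), s = site,
                    state = state),
               types, constraints)
}

#' @rdname reactionRule
#' @param to destination compartment.
#' @export
transportRule <- function(name, pattern, to, rateName, types, constraints = NULL) {
  reactionRule(name, pattern, rateName, list(type = "transport", to = to),
               types, constraints, kind = "transport")
}

#' @rdname reactionRule
#' @param counters named character vector mapping molecule type names to sink
#'   counter type names; molecules of unlisted types are dropped without a
#'   counter.
#' @export
degradeRule <- function(name, pattern, counters, rateName, types, constraints = NULL) {
  reactionRule(name, pattern, rateName,
               list(type = "degrade", counters = counters),
               types, constraints, kind = "transport")
}

#' @rdname reactionRule
#' @param species species text created by the synthesis rule (zeroth order).
#' @export
synthRule <- function(name, species, rateName, types) {
  rule <- reactionRule(name, character(0), rateName,
                       list(type = "synth", species = species), types)
  rule
}

# --- application -----------------------------------------------------------

.mergeReactants <- function(spList) {
  mols <- character(0); states <- list(); bonds <- list(); offs <- integer(0)
  for (sp in spList) {
    off <- length(mols)
    offs <- c(offs, off)
    mols <- c(mols, sp@molecules)
    states <- c(states, sp@states)
    bonds <- c(bonds, lapply(sp@bonds, function(b)
      list(m1 = b$m1 + off, s1 = b$s1, m2 = b$m2 + off, s2 = b$s2)))
  }
  locs <- vapply(spList, function(s) s@location, "")
  nonSol <- setdiff(unique(locs), "solution")
  if (length(nonSol) > 1L) return(NULL)     # cross-compartment: rule not applicable
  loc <- if (length(nonSol)) nonSol else "solution"
  list(molecules = mols, states = states, bonds = bonds, offsets = offs, location = loc)
}

.splitComponents <- function(mols, states, bonds, parentLoc, types) {
  n <- length(mols)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in bonds) {
      m <- min(comp[b$m1], comp[b$m2])
      if (comp[b$m1] != m || comp[b$m2] != m) {
        comp[comp == comp[b$m1]] <- m; comp[comp == comp[b$m2]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(ci) {
    idx <- which(comp == ci)
    remap <- integer(n); remap[idx] <- seq_along(idx)
    bsub <- Filter(function(b) b$m1 %in% idx, bonds)
    bsub <- lapply(bsub, function(b)
      list(m1 = remap[b$m1], s1 = b$s1, m2 = remap[b$m2], s2 = b$s2))
    mem <- any(vapply(mols[idx], function(t) types[[t]]@isMembrane, TRUE))
    loc <- if (mem) parentLoc else if (parentLoc == "surface") "solution" else parentLoc
    sp <- new("ComplexSpecies", molecules = mols[idx], states = states[idx],
              bonds = bsub, location = loc, label = "")
    canonicalize(sp, types)
  })
}

# Apply one rule instance; returns list of product species or NULL when the
# instance is rejected (e.g. both ends already bound, aggregate too large).
.applyRuleInstance <- function(rule, spList, embList, types, maxAgg) {
  act <- rule@action
  if (act$type == "synth")
    return(list(parseSpecies(act$species, types)))
  mg <- .mergeReactants(spList)
  if (is.null(mg)) return(NULL)
  # map (reactantIdx, patternMolIdx) -> merged molecule index
  mapMol <- function(ri, pm) mg$offsets[ri] + embList[[ri]][pm]
  loc <- mg$location
  mols <- mg$molecules; states <- mg$states; bonds <- mg$bonds
  if (act$type == "bind") {
    i1 <- mapMol(1L, act$end1$m)
    i2 <- if (act$intra) mapMol(1L, act$end2$m) else mapMol(2L, act$end2$m)
    for (b in bonds)
      if ((b$m1 == i1 && b$s1 == act$end1$s) || (b$m2 == i1 && b$s2 == act$end1$s) ||
          (b$m1 == i2 && b$s1 == act$end2$s) || (b$m2 == i2 && b$s2 == act$end2$s))
        return(NULL)
    if (act$intra && i1 == i2) return(NULL)
    bonds <- c(bonds, list(list(m1 = i1, s1 = act$end1$s, m2 = i2, s2 = act$end2$s)))
    if (!is.na(act$location)) loc <- act$location
  } else if (act$type == "unbind") {
    i <- mapMol(1L, act$end$m); s <- act$end$s
    hit <- which(vapply(bonds, function(b)
      (b$m1 == i && b$s1 == s) || (b$m2 == i && b$s2 == s), TRUE))
    if (!length(hit)) return(NULL)
    bonds <- bonds[-hit[1L]]
  } else if (act$type == "setState") {
    i <- mapMol(1L, act$m)
    states[[i]][act$s] <- act$state
  } else if (act$type == "transport") {
    loc <- act$to
  } else if (act$type == "degrade") {
    out <- list()
    for (t in mols) {
      ct <- act$counters[t]
      if (!is.na(ct))
        out <- c(out, list(parseSpecies(paste0(ct, "@sink"), types)))
    }
    return(out)
  } else stop("unknown rule action: ", act$type)
  if (act$type == "bind" && length(mols) > maxAgg) return("capped")
  .splitComponents(mols, states, bonds, loc, types)
}
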