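# Network expansion: iterate rule application over seed species to the closed
# set of species and reactions, with BioNetGen-convention statistical factors.

.embFor <- function(cache, rule, ri, spIdx, sp, types) {
  key <- paste(rule@name, ri, spIdx, sep = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  emb <- if (.satisfiesConstraints(rule@constraints[[ri]], sp, types))
    matchPattern(rule@reactants[[ri]], sp, types) else list()
  cache[[key]] <- emb
  emb
}

#' Expand a rule set over seed species to a closed reaction network
#'
#' Applies every rule to every species (and species pair) repeatedly until no
#' new species appear.  Species are deduplicated by canonical label.  Reaction
#' rate constants carry the BioNetGen statistical convention: one reaction per
#' distinct embedding (lumped by summing when several embeddings give the same
#' products), with a factor 1/2 when the two reactants of a rule with identical
#' patterns are the same species.  The output is deterministic and independent
#' of rule and seed ordering (species are sorted by canonical label, reactions
#' by content).
#'
#' @param rules list of \linkS4class{ReactionRule}.
#' @param seeds list of \linkS4class{ComplexSpecies} (canonical), or character
#'   vector of species texts.
#' @param types named list of \linkS4class{MoleculeType}.
#' @param maxIter iteration bound; exceeding it raises a "network not closed"
#'   error.
#' @param maxAgg largest complex (molecule count) a binding rule may create;
#'   rule applications beyond the cap are rejected and counted in the
#'   \code{rejected} slot.
#' @return a \linkS4class{ReactionNetwork}.
#' @examples
#' types <- vegfMoleculeTypes()
#' seeds <- c("V(r1,r2,n)@solution", "VEGFR2(L,C,Y~U)@surface")
#' rules <- list(
#'   bindRule("bindV", "V(r1,r2)@solution", "VEGFR2(L)", c(1, "r1"), c(1, "L"),
#'            "konV", types),
#'   unbindRule("unbindV", "V(r1!1,r2).VEGFR2(L!1)@surface", c(1, "r1"),
#'              "koffV", types))
#' net <- expandNetwork(rules, seeds, types)
#' numSpecies(net)    # 3
#' numReactions(net)  # 2
#' @export
expandNetwork <- function(rules, seeds, types, maxIter = 60L, maxAgg = 6L) {
  if (is.character(seeds)) seeds <- lapply(seeds, parseSpecies, types = types)
  seeds <- lapply(seeds, canonicalize, types = types)
  labels <- character(0)
  species <- list()
  idxOf <- new.env(parent = emptyenv())
  addSpecies <- function(sp) {
    lab <- sp@label
    i <- idxOf[[lab]]
    if (!is.null(i)) return(i)
    species[[length(species) + 1L]] <<- sp
    labels[length(species)] <<- lab
    idxOf[[lab]] <- length(species)
    length(species)
  }
  for (sp in seeds) addSpecies(sp)

  cache <- new.env(parent = emptyenv())
  rxn <- new.env(parent = emptyenv())
  rejected <- 0L
  addReaction <- function(rule, reactants, products, factor) {
    key <- paste(rule@name, paste(sort(reactants), collapse = ","),
                 paste(sort(products), collapse = ","), sep = "|")
    cur <- rxn[[key]]
    if (is.null(cur)) {
      rxn[[key]] <- list(rule = rule@name, rateName = rule@rateName,
                         reactants = sort(reactants), products = sort(products),
                         factor = factor)
    } else {
      cur$factor <- cur$factor + factor
      rxn[[key]] <- cur
    }
  }
  tryInstance <- function(rule, spList, embList, factor) {
    prods <- .applyRuleInstance(rule, spList, embList, types, maxAgg)
    if (is.null(prods)) return(invisible())
    if (identical(prods, "capped")) { rejected <<- rejected + 1L; return(invisible()) }
    pidx <- vapply(prods, addSpecies, 1L)
    ridx <- vapply(spList, function(s) idxOf[[s@label]], 1L)
    addReaction(rule, ridx, pidx, factor)
  }

  synthRules <- Filter(function(r) r@action$type == "synth", rules)
  for (r in synthRules) {
    prod <- addSpecies(parseSpecies(r@action$species, types))
    addReaction(r, integer(0), prod, 1)
  }
  rules <- Filter(function(r) r@action$type != "synth", rules)
  unary <- Filter(function(r) length(r@reactants) == 1L, rules)
  binary <- Filter(function(r) length(r@reactants) == 2L, rules)

  processed <- 0L   # species 1..processed have been fully cross-combined
  iter <- 0L
  while (processed < length(species)) {
    iter <- iter + 1L
    if (iter > maxIter)
      stop("network not closed after ", maxIter, " iterations (",
           length(species), " species so far)")
    newFrom <- processed + 1L
    nNow <- length(species)
    for (rule in unary) {
      perComplex <- rule@action$type %in% c("transport", "degrade")
      for (i in newFrom:nNow) {
        emb <- .embFor(cache, rule, 1L, i, species[[i]], types)
        if (!length(emb)) next
        if (perComplex) {
          tryInstance(rule, species[i], list(emb[[1L]]), 1)
        } else {
          for (e in emb) tryInstance(rule, species[i], list(e), 1)
        }
      }
    }
    for (rule in binary) {
      sym <- isTRUE(rule@action$symmetric)
      for (i in newFrom:nNow) {
        emb1 <- .embFor(cache, rule, 1L, i, species[[i]], types)
        for (j in seq_len(nNow)) {
          # pair coverage: every pair with at least one new member is handled
          # exactly once per role assignment.  For symmetric rules pairs are
          # unordered (take i = max); for distinct patterns both orders run,
          # the swapped role only when j is old (new-new swaps arise when the
          # outer loop reaches j).
          if (sym && j > i) next
          emb2i <- .embFor(cache, rule, 2L, j, species[[j]], types)
          if (length(emb1) && length(emb2i)) {
            for (e1 in emb1) for (e2 in emb2i) {
              f <- 1
              if (sym && i == j) {
                if (identical(e1, e2)) f <- 0.5
                else if (paste(e1, collapse = ",") > paste(e2, collapse = ",")) next
              }
              tryInstance(rule, species[c(i, j)], list(e1, e2), f)
            }
          }
          if (!sym && j < newFrom) {
            emb1j <- .embFor(cache, rule, 1L, j, species[[j]], types)
            emb2  <- .embFor(cache, rule, 2L, i, species[[i]], types)
            if (length(emb1j) && length(emb2))
              for (e1 in emb1j) for (e2 in emb2)
                tryInstance(rule, species[c(j, i)], list(e1, e2), 1)
          }
        }
      }
    }
    processed <- nNow
  }

  keys <- ls(rxn)
  rx <- lapply(keys, function(k) rxn[[k]])
  # canonical ordering: sort species by label, remap, sort reactions
  ord <- order(labels)
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  species <- species[ord]; labels <- labels[ord]
  rx <- lapply(rx, function(r) {
    r$reactants <- sort(remap[r$reactants]); r$products <- sort(remap[r$products]); r
  })
  rkey <- vapply(rx, function(r) paste(r$rule, paste(r$reactants, collapse = ","),
                                       paste(r$products, collapse = ","), sep = "|"), "")
  rx <- rx[order(rkey)]
  reactions <- data.frame(
    rule = vapply(rx, `[[`, "", "rule"),
    rateName = vapply(rx, `[[`, "", "rateName"),
    factor = vapply(rx, `[[`, 1, "factor"),
    stringsAsFactors = FALSE)
  reactions$reactants <- lapply(rx, `[[`, "reactants")
  reactions$products <- lapply(rx, `[[`, "products")
  new("ReactionNetwork", species = species, labels = labels,
      reactions = reactions, observables = list(), rejected = rejected)
}

#' Verify network closure under a rule set
#'
#' Re-applies every rule to every species (and pair) of an expanded network and
#' checks that no product falls outside the network's species list (under the
#' same aggregate cap).
#'
#' @inheritParams expandNetwork
#' @param network a \linkS4class{ReactionNetwork}.
#' @return TRUE invisibly; error describing the escaping species otherwise.
#' @export
checkClosure <- function(network, rules, types, maxAgg = 6L) {
  net2 <- expandNetwork(rules, network@species, types, maxAgg = maxAgg)
  extra <- setdiff(net2@labels, network@labels)
  if (length(extra))
    stop("network not closed; new species reachable: ",
         paste(head(extra, 5), collapse = " ; "))
  invisible(TRUE)
}

#' Attach a named observable to a network
#'
#' An observable is the weighted sum over species concentrations with weights
#' equal to the number of embeddings of a pattern in each species (BNGL
#' "Molecules" semantics: a species containing two phosphorylated receptors
#' contributes twice its concentration).
#'
#' @param network ReactionNetwork.
#' @param name observable name.
#' @param pattern pattern text or \linkS4class{ComplexPattern}.
#' @param types molecule type list.
#' @return the network with the observable added.
#' @export
addObservable <- function(network, name, pattern, types) {
  if (is.character(pattern)) pattern <- parsePattern(pattern, types)
  w <- vapply(network@species, function(sp) countEmbeddings(pattern, sp, types), 1L)
  network@observables[[name]] <- list(pattern = pattern, weights = as.numeric(w))
  network
}

#' Evaluate observables at a state vector
#' @param network ReactionNetwork with observables attached.
#' @param y numeric state vector over network species.
#' @return named numeric vector.
#' @export
evalObservables <- function(network, y) {
  vapply(network@observables, function(o) sum(o$weights * y), 1)
}

#' Emit the mass-action ODE right-hand side of a network
#'
#' Builds d(species)/dt from the network's reactions.  Every rate symbol is
#' resolved in \code{params} (a missing symbol raises an error naming it); the
#' resolved constant is multiplied by the reaction's statistical factor.
#' Additional (e.g. Michaelis-Menten aggregate) terms may be layered on top via
#' \code{extraRhs}.
#'
#' @param network ReactionNetwork.
#' @param params \linkS4class{ParameterSet} or named numeric vector.
#' @param extraRhs optional \code{function(t, y)} returning a derivative
#'   increment over the same species indexing.
#' @return list with \code{rhs = function(t, y)}, the species \code{labels}
#'   (index map), the resolved per-reaction constants \code{k}, and the dense
#'   stoichiometry matrix \code{stoich} (species x reactions).
#' @export
emitODEs <- function(network, params, extraRhs = NULL) {
  if (is(params, "ParameterSet")) params <- params@values
  rx <- network@reactions
  miss <- setdiff(unique(rx$rateName), names(params))
  if (length(miss))
    stop("missing parameter symbol(s): ", paste(miss, collapse = ", "))
  k <- unname(params[rx$rateName]) * rx$factor
  n <- length(network@species)
  m <- nrow(rx)
  S <- matrix(0, n, m)
  r1 <- integer(m); r2 <- integer(m)
  for (j in seq_len(m)) {
    re <- rx$reactants[[j]]; pr <- rx$products[[j]]
    if (length(re) > 2L) stop("at most bimolecular reactions supported")
    r1[j] <- if (length(re) >= 1L) re[1L] else 0L
    r2[j] <- if (length(re) == 2L) re[2L] else 0L
    for (i in re) S[i, j] <- S[i, j] - 1
    for (i in pr) S[i, j] <- S[i, j] + 1
  }
  rhs <- function(t, y) {
    f <- k
    has1 <- r1 > 0L
    f[has1] <- f[has1] * y[r1[has1]]
    has2 <- r2 > 0L
    f[has2] <- f[has2] * y[r2[has2]]
    dy <- as.numeric(S %*% f)
    if (!is.null(extraRhs)) dy <- dy + extraRhs(t, y)
    dy
  }
  list(rhs = rhs, labels = network@labels, k = k, stoich = S, r1 = r1, r2 = r2)
}

#' Per-species molecule counts of one molecule type
#'
#' Used for moiety conservation checks: the inner product of the returned
#' vector with a concentration vector is the total concentration of that
#' molecule type (sink counters included when they are declared as types).
#'
#' @param network ReactionNetwork.
#' @param typeName molecule type (counters count via \code{countedAs}).
#' @param countedAs additional type names (e.g. the degradation counter) whose
#'   molecules count towards the same total.
#' @return numeric vector over species.
#' @export
moietyCounts <- function(network, typeName, countedAs = character(0)) {
  all <- c(typeName, countedAs)
  vapply(network@species, function(sp) sum(sp@molecules %in% all), 1) * 1.0
}

#' Species table (canonical label, index, size, location)
#' @param network ReactionNetwork
#' @return data.frame
#' @export
speciesTable <- function(network) {
  data.frame(index = seq_along(network@species),
             label = network@labels,
             size = vapply(network@species, function(s) length(s@molecules), 1L),
             location = vapply(network@species, function(s) s@location, ""),
             stringsAsFactors = FALSE)
}

#' Reaction table (rule, rate symbol, factor, reactant/product labels)
#' @param network ReactionNetwork
#' @return data.frame
#' @export
reactionTable <- function(network) {
  rx <- network@reactions
  data.frame(index = seq_len(nrow(rx)),
             rule = rx$rule, rateName = rx$rateName, factor = rx$factor,
             reactants = vapply(rx$reactants, function(i)
               paste(network@labels[i], collapse = " + "), ""),
             products = vapply(rx$products, function(i)
               paste(network@labels[i], collapse = " + "), ""),
             stringsAsFactors = FALSE)
}
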