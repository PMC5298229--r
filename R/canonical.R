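# Canonical labelling of complex species.
#
# Molecules are vertices coloured by (type, internal site states); bonds are
# edges labelled by the site pair they join.  The canonical label is the
# lexicographically smallest BNGL-style string over all orderings of the
# molecule instances, restricted to orderings compatible with a
# Weisfeiler-Lehman colour refinement (which keeps the permutation search
# trivial for the complex sizes that receptor-scale rules generate).

.siteOrder <- function(type) names(type@sites)

.stateToken <- function(type, states, site) {
  if (length(type@sites[[site]]) > 1L) paste0("~", states[[site]]) else ""
}

.molBaseColor <- function(sp, i, types) {
  ty <- types[[sp@molecules[i]]]
  toks <- vapply(.siteOrder(ty), function(s) .stateToken(ty, sp@states[[i]], s), "")
  paste0(ty@name, "{", paste(toks, collapse = ","), "}")
}

.bondEnds <- function(sp) {
  # adjacency: for molecule i, named list site -> c(partner molecule, partner site)
  n <- length(sp@molecules)
  adj <- rep(list(list()), n)
  for (b in sp@bonds) {
    adj[[b$m1]][[b$s1]] <- list(m = b$m2, s = b$s2)
    adj[[b$m2]][[b$s2]] <- list(m = b$m1, s = b$s1)
  }
  adj
}

.refineColors <- function(sp, types, rounds = 3L) {
  n <- length(sp@molecules)
  col <- vapply(seq_len(n), function(i) .molBaseColor(sp, i, types), "")
  if (n == 1L) return(col)
  adj <- .bondEnds(sp)
  for (r in seq_len(rounds)) {
    sig <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (!length(nb)) return(col[i])
      ns <- sort(vapply(names(nb), function(s)
        paste0(s, ">", nb[[s]]$s, ":", col[[nb[[s]]$m]]), ""))
      paste0(col[i], "|", paste(ns, collapse = ";"))
    }, "")
    if (identical(sig, col)) break
    col <- sig
  }
  col
}

.labelForOrder <- function(sp, types, ord) {
  # ord[k] = original index of the molecule placed at position k
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  adj <- .bondEnds(sp)
  bondNum <- new.env(parent = emptyenv())
  cnt <- 0L
  # first pass: assign bond numbers in traversal order
  for (k in seq_along(ord)) {
    i <- ord[k]
    ty <- types[[sp@molecules[i]]]
    for (s in .siteOrder(ty)) {
      nb <- adj[[i]][[s]]
      if (!is.null(nb)) {
        key <- paste(min(i, nb$m), max(i, nb$m),
                     if (i < nb$m || (i == nb$m && s < nb$s)) paste(s, nb$s) else paste(nb$s, s))
        if (is.null(bondNum[[key]])) { cnt <- cnt + 1L; bondNum[[key]] <- cnt }
      }
    }
  }
  toks <- vapply(seq_along(ord), function(k) {
    i <- ord[k]
    ty <- types[[sp@molecules[i]]]
    st <- vapply(.siteOrder(ty), function(s) {
      nb <- adj[[i]][[s]]
      bt <- if (is.null(nb)) "" else {
        key <- paste(min(i, nb$m), max(i, nb$m),
                     if (i < nb$m || (i == nb$m && s < nb$s)) paste(s, nb$s) else paste(nb$s, s))
        paste0("!", bondNum[[key]])
      }
      paste0(s, .stateToken(ty, sp@states[[i]], s), bt)
    }, "")
    paste0(ty@name, "(", paste(st, collapse = ","), ")")
  }, "")
  paste0(paste(toks, collapse = "."), "@", sp@location)
}

.permsWithin <- function(groups) {
  # all orderings: concatenation of per-group permutations (groups already ordered)
  out <- list(integer(0))
  for (g in groups) {
    pg <- .allPerms(g)
    out <- unlist(lapply(out, function(prefix)
      lapply(pg, function(p) c(prefix, p))), recursive = FALSE)
  }
  out
}

.allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    out <- c(out, lapply(.allPerms(v[-k]), function(p) c(v[k], p)))
  out
}

#' Canonical label of a complex species
#'
#' The label is invariant under any permutation of the molecule instances
#' (graph isomorphism over type/state-coloured molecules and site-labelled
#' bonds) and therefore serves as the species identity during network
#' expansion.
#'
#' @param sp a \linkS4class{ComplexSpecies} (its \code{label} slot is ignored).
#' @param types named list of \linkS4class{MoleculeType}.
#' @return character label, e.g. \code{"V(r1!1,r2,n).VEGFR2(L!1,C,Y~U)@surface"}.
#' @export
canonicalLabel <- function(sp, types) {
  n <- length(sp@molecules)
  if (n == 1L) return(.labelForOrder(sp, types, 1L))
  col <- .refineColors(sp, types)
  ord0 <- order(col, sp@molecules)
  groups <- split(ord0, col[ord0])
  groups <- groups[order(names(groups))]
  nPerm <- prod(vapply(groups, function(g) factorial(length(g)), 1))
  if (nPerm > 20000)
    stop("complex too symmetric for exhaustive canonicalization (", nPerm, " orderings)")
  labs <- vapply(.permsWithin(groups), function(ord) .labelForOrder(sp, types, ord), "")
  min(labs)
}

#' Finalize a species: canonicalize and stamp its label
#' @param sp ComplexSpecies
#' @param types molecule type list
#' @return the species with its \code{label} slot set
#' @export
canonicalize <- function(sp, types) {
  sp@label <- canonicalLabel(sp, types)
  sp
}
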