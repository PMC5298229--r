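# Subgraph embedding of patterns into species.

.patternBonds <- function(p) {
  tags <- list()
  for (i in seq_along(p@molecules)) {
    bs <- p@bondSpec[[i]]
    for (s in names(bs)) {
      b <- bs[[s]]
      if (!b %in% c("free", "any"))
        tags[[b]] <- c(tags[[b]], list(list(m = i, s = s)))
    }
  }
  lapply(tags, function(e) list(m1 = e[[1]]$m, s1 = e[[1]]$s,
                                m2 = e[[2]]$m, s2 = e[[2]]$s))
}

.molCandidates <- function(p, i, sp, types) {
  # species molecule indices that can host pattern molecule i
  out <- integer(0)
  adj <- attr(sp, "adjCache")
  for (j in seq_along(sp@molecules)) {
    if (sp@molecules[j] != p@molecules[i]) next
    ok <- TRUE
    stp <- p@states[[i]]
    for (s in names(stp)) if (sp@states[[j]][[s]] != stp[[s]]) { ok <- FALSE; break }
    if (ok) {
      bs <- p@bondSpec[[i]]
      for (s in names(bs)) {
        bound <- !is.null(adj[[j]][[s]])
        if (bs[[s]] == "free" && bound) { ok <- FALSE; break }
        if (bs[[s]] != "free" && !bound) { ok <- FALSE; break }
      }
    }
    if (ok) out <- c(out, j)
  }
  out
}

.patternAutomorphisms <- function(p) {
  np <- length(p@molecules)
  if (np == 1L) return(list(1L))
  sig <- vapply(seq_len(np), function(i) {
    bs <- p@bondSpec[[i]]
    cls <- vapply(names(bs), function(s)
      paste0(s, ":", if (bs[[s]] %in% c("free", "any")) bs[[s]] else "tag"), "")
    paste(p@molecules[i],
          paste(sort(paste0(names(p@states[[i]]), "=", unlist(p@states[[i]]))), collapse = ","),
          paste(sort(cls), collapse = ","))
  }, "")
  bonds <- .patternBonds(p)
  bondKey <- function(m1, s1, m2, s2)
    paste(min(m1, m2), max(m1, m2), if (m1 <= m2) paste(s1, s2) else paste(s2, s1))
  bondSet <- vapply(bonds, function(b) bondKey(b$m1, b$s1, b$m2, b$s2), "")
  keep <- list()
  for (perm in .allPerms(seq_len(np))) {
    if (!all(sig == sig[perm])) next
    ok <- all(vapply(bonds, function(b)
      bondKey(perm[b$m1], b$s1, perm[b$m2], b$s2) %in% bondSet, TRUE))
    if (ok) keep <- c(keep, list(perm))
  }
  keep
}

#' Find all embeddings of a pattern in a species
#'
#' Returns every injective map from pattern molecules to species molecules that
#' respects molecule types, required site states, bond status (\code{free} /
#' \code{any}) and tagged bonds, and the pattern's location (if given).
#' Embeddings related by an automorphism of the pattern are reported once.
#'
#' @param pattern a \linkS4class{ComplexPattern}.
#' @param species a \linkS4class{ComplexSpecies}.
#' @param types named list of \linkS4class{MoleculeType}.
#' @return list of integer vectors (pattern index -> species molecule index);
#'   empty list if the pattern does not match.
#' @examples
#' types <- vegfMoleculeTypes()
#' dimer <- parseSpecies("VEGFR2(L,C!1,Y~U).VEGFR2(L,C!1,Y~U)@surface", types)
#' length(matchPattern(parsePattern("VEGFR2(C!+)", types), dimer, types))  # 2
#' @export
matchPattern <- function(pattern, species, types) {
  bad <- setdiff(pattern@molecules, names(types))
  if (length(bad)) stop("undeclared molecule type(s): ", paste(bad, collapse = ", "))
  if (!is.na(pattern@location) && pattern@location != species@location)
    return(list())
  np <- length(pattern@molecules)
  attr(species, "adjCache") <- .bondEnds(species)
  cand <- lapply(seq_len(np), function(i) .molCandidates(pattern, i, species, types))
  if (any(!vapply(cand, length, 1L))) return(list())
  pbonds <- .patternBonds(pattern)
  adj <- attr(species, "adjCache")
  res <- list()
  assign <- integer(np)
  used <- logical(length(species@molecules))
  recurse <- function(k) {
    if (k > np) {
      for (b in pbonds) {
        nb <- adj[[assign[b$m1]]][[b$s1]]
        if (is.null(nb) || nb$m != assign[b$m2] || nb$s != b$s2) return(invisible())
      }
      res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (j in cand[[k]]) {
      if (used[j]) next
      used[j] <<- TRUE; assign[k] <<- j
      recurse(k + 1L)
      used[j] <<- FALSE
    }
  }
  recurse(1L)
  if (length(res) <= 1L || np == 1L) return(res)
  auts <- .patternAutomorphisms(pattern)
  if (length(auts) == 1L) return(res)
  keys <- vapply(res, function(e)
    min(vapply(auts, function(p) paste(e[p], collapse = ","), "")), "")
  res[!duplicated(keys)]
}

#' Count embeddings of a pattern in a species
#' @inheritParams matchPattern
#' @return integer
#' @export
countEmbeddings <- function(pattern, species, types)
  length(matchPattern(pattern, species, types))

# rule-level reactant constraints ------------------------------------------

.satisfiesConstraints <- function(cons, sp, types) {
  if (is.null(cons)) return(TRUE)
  # [[ ]] indexing: "$" would partial-match "exclude" to "excludePattern"
  if (!is.null(cons[["maxSize"]]) && length(sp@molecules) > cons[["maxSize"]])
    return(FALSE)
  if (!is.null(cons[["require"]]) && !all(cons[["require"]] %in% sp@molecules))
    return(FALSE)
  if (!is.null(cons[["exclude"]]) && any(cons[["exclude"]] %in% sp@molecules))
    return(FALSE)
  if (!is.null(cons[["excludePattern"]]) &&
      countEmbeddings(cons[["excludePattern"]], sp, types) > 0L) return(FALSE)
  TRUE
}
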