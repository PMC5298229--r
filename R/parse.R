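# A plain-text dialect mirroring BNGL seed-species / pattern syntax.
#
# Species:  "V(r1!1,r2,n).VEGFR2(L!1,C,Y~U)@surface"
#   - every molecule lists any subset of its sites; unmentioned sites are
#     unbound and take their default state
#   - "!n" tags pair up bonds; "~s" sets a state
#   - "@loc" sets the compartment (default "surface")
# Pattern:  same syntax, but unmentioned sites are unconstrained, a mentioned
#   site without "!" must be free, "!+" means bound to anything, and "@loc"
#   may be omitted to match any compartment.

.splitMolecules <- function(text) {
  # split on "." at depth 0 (no parentheses nesting in this dialect)
  parts <- character(0); depth <- 0L; cur <- ""
  for (ch in strsplit(text, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "." && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

.parseMol <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z0-9_]+)\\((.*)\\)$", tok))[[1]]
  if (!length(m)) {
    m2 <- regmatches(tok, regexec("^([A-Za-z0-9_]+)$", tok))[[1]]
    if (!length(m2)) stop("cannot parse molecule token: ", tok)
    return(list(type = m2[2], sites = character(0)))
  }
  sites <- if (nzchar(m[3])) strsplit(m[3], ",")[[1]] else character(0)
  list(type = m[2], sites = trimws(sites))
}

.parseSiteTok <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z0-9_]+)(~([A-Za-z0-9_?]+))?(!([0-9]+|\\+))?$", tok))[[1]]
  if (!length(m)) stop("cannot parse site token: ", tok)
  list(site = m[2], state = if (nzchar(m[4])) m[4] else NA_character_,
       bond = if (nzchar(m[6])) m[6] else NA_character_)
}

.parseText <- function(text, types, asPattern) {
  text <- gsub("[[:space:]]", "", text)
  loc <- NA_character_
  if (grepl("@", text, fixed = TRUE)) {
    bits <- strsplit(text, "@", fixed = TRUE)[[1]]
    text <- bits[1]; loc <- bits[2]
    if (!loc %in% .locations) stop("unknown location: ", loc)
  }
  mols <- lapply(.splitMolecules(text), .parseMol)
  molTypes <- vapply(mols, `[[`, "", "type")
  bad <- setdiff(molTypes, names(types))
  if (length(bad)) stop("undeclared molecule type(s): ", paste(bad, collapse = ", "))
  states <- list(); bondSpec <- list(); tagEnds <- list()
  for (i in seq_along(mols)) {
    ty <- types[[molTypes[i]]]
    st <- character(0); bs <- character(0)
    for (tok in mols[[i]]$sites) {
      p <- .parseSiteTok(tok)
      if (!p$site %in% names(ty@sites))
        stop("undeclared site '", p$site, "' on ", ty@name)
      if (!is.na(p$state)) {
        if (!p$state %in% ty@sites[[p$site]])
          stop("undeclared state '", p$state, "' for site ", ty@name, ".", p$site)
        st[p$site] <- p$state
      }
      bs[p$site] <- if (is.na(p$bond)) "free" else if (p$bond == "+") "any" else p$bond
      if (!is.na(p$bond) && p$bond != "+")
        tagEnds[[p$bond]] <- c(tagEnds[[p$bond]], list(list(m = i, s = p$site)))
    }
    states[[i]] <- st
    bondSpec[[i]] <- bs
  }
  for (tag in names(tagEnds))
    if (length(tagEnds[[tag]]) != 2L)
      stop("bond tag !", tag, " must appear exactly twice")
  bonds <- lapply(tagEnds, function(e)
    list(m1 = e[[1]]$m, s1 = e[[1]]$s, m2 = e[[2]]$m, s2 = e[[2]]$s))
  names(bonds) <- NULL
  if (asPattern) {
    new("ComplexPattern", molecules = molTypes, states = states,
        bondSpec = bondSpec, location = loc)
  } else {
    # fill defaults: unmentioned sites unbound, default state
    full <- lapply(seq_along(molTypes), function(i) {
      ty <- types[[molTypes[i]]]
      st <- vapply(ty@sites, `[[`, "", 1L)
      st[names(states[[i]])] <- states[[i]]
      st
    })
    sp <- new("ComplexSpecies", molecules = molTypes, states = full, bonds = bonds,
              location = if (is.na(loc)) "surface" else loc, label = "")
    canonicalize(sp, types)
  }
}

#' Parse a species from text
#'
#' @param text species string in the BNGL-like dialect (see package docs).
#' @param types named list of \linkS4class{MoleculeType}.
#' @return a canonicalized \linkS4class{ComplexSpecies}.
#' @examples
#' types <- vegfMoleculeTypes()
#' parseSpecies("VEGFR2(L,C,Y~U)@surface", types)
#' @export
parseSpecies <- function(text, types) .parseText(text, types, asPattern = FALSE)

#' Parse a pattern from text
#'
#' @inheritParams parseSpecies
#' @return a \linkS4class{ComplexPattern}.
#' @examples
#' types <- vegfMoleculeTypes()
#' parsePattern("VEGFR2(Y~P)", types)         # any phosphorylated VEGFR2
#' parsePattern("VEGFR2(C!+)", types)         # coupled via C to anything
#' @export
parsePattern <- function(text, types) .parseText(text, types, asPattern = TRUE)

#' Render a pattern back to text
#' @param p ComplexPattern
#' @return character
#' @export
patternToText <- function(p) {
  toks <- vapply(seq_along(p@molecules), function(i) {
    sites <- union(names(p@states[[i]]), names(p@bondSpec[[i]]))
    st <- vapply(sites, function(s) {
      a <- if (s %in% names(p@states[[i]])) paste0("~", p@states[[i]][[s]]) else ""
      b <- p@bondSpec[[i]][s]
      bt <- if (is.na(b) || b == "free") "" else if (b == "any") "!+" else paste0("!", b)
      paste0(s, a, bt)
    }, "")
    paste0(p@molecules[i], "(", paste(st, collapse = ","), ")")
  }, "")
  paste0(paste(toks, collapse = "."),
         if (!is.na(p@location)) paste0("@", p@location) else "")
}
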