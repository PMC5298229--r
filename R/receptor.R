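# VEGF receptor layer: molecule types, seed species and the interaction /
# trafficking rule set (ligand binding, dimerization, NRP1 coupling, Y1175
# phosphorylation, internalization, recycling, degradation).

#' Molecule types of the VEGF receptor model
#'
#' \itemize{
#'   \item \code{V}: VEGF-A(165) dimer with two receptor-binding interfaces
#'     (\code{r1}, \code{r2}) and the C-terminal NRP1-binding domain (\code{n}).
#'   \item \code{VEGFR2}: ligand site \code{L}, receptor-coupling site \code{C},
#'     phosphosite \code{Y} (Y1175) with states \code{U}/\code{P}.
#'   \item \code{VEGFR1}: ligand site \code{L}, coupling site \code{C},
#'     NRP1-binding site \code{N}; a non-signalling decoy in this model.
#'   \item \code{NRP1}: single site \code{b} binding either VEGF's \code{n}
#'     domain or VEGFR1's \code{N} site (competitively).
#'   \item \code{R2deg}, \code{N1deg}, \code{Vdeg}: degradation sink counters
#'     so that moiety totals are exactly conserved.
#' }
#' @return named list of \linkS4class{MoleculeType}.
#' @export
vegfMoleculeTypes <- function() {
  tl <- list(
    moleculeType("V", list(r1 = "0", r2 = "0", n = "0"), isMembrane = FALSE),
    moleculeType("VEGFR2", list(L = "0", C = "0", Y = c("U", "P")), isMembrane = TRUE),
    moleculeType("VEGFR1", list(L = "0", C = "0", N = "0"), isMembrane = TRUE),
    moleculeType("NRP1", list(b = "0"), isMembrane = TRUE),
    moleculeType("R2deg", list(), isMembrane = FALSE),
    moleculeType("N1deg", list(), isMembrane = FALSE),
    moleculeType("Vdeg", list(), isMembrane = FALSE))
  names(tl) <- vapply(tl, function(t) t@name, "")
  tl
}

#' Seed species of the receptor model
#' @param types molecule types (default \code{\link{vegfMoleculeTypes}}).
#' @return list of canonical \linkS4class{ComplexSpecies}: free VEGF in
#'   solution and monomeric VEGFR2, VEGFR1 and NRP1 at the cell surface.
#' @export
receptorSeeds <- function(types = vegfMoleculeTypes()) {
  lapply(c("V(r1,r2,n)@solution",
           "VEGFR2(L,C,Y~U)@surface",
           "VEGFR1(L,C,N)@surface",
           "NRP1(b)@surface"),
         parseSpecies, types = types)
}

.degCounters <- c(VEGFR2 = "R2deg", NRP1 = "N1deg", V = "Vdeg")

#' Build the receptor interaction and trafficking rule set
#'
#' Encodes: VEGF binding to VEGFR2/VEGFR1 from solution and ligand-mediated
#' receptor bridging (dimerization); ligand-independent coupling of monomeric
#' receptors through their C sites; ligand-independent VEGFR1-NRP1 coupling;
#' NRP1 recruitment through VEGF's C-terminal domain; Y1175 trans-
#' autophosphorylation restricted to ligand-carrying VEGFR2 homodimers;
#' location-specific dephosphorylation; internalization of liganded
#' VEGFR2 complexes with NRP1-dependent rates (VEGFR1-containing complexes stay
#' at the membrane); recycling of unphosphorylated endosomal complexes
#' (phosphorylated receptors do not recycle); endosomal degradation into sink
#' counters; and a constitutive internalize/recycle/degrade/synthesize cycle
#' for unliganded monomeric VEGFR2 that keeps receptor totals stationary in
#' the absence of ligand.
#'
#' @param types molecule types (default \code{\link{vegfMoleculeTypes}}).
#' @return list of \linkS4class{ReactionRule}.
#' @export
buildReceptorRules <- function(types = vegfMoleculeTypes()) {
  ct <- .degCounters
  noP <- "VEGFR2(Y~P)"   # exclusion pattern: any phosphorylated receptor
  rules <- list(
    ## --- VEGF binding from solution -------------------------------------
    bindRule("bind_V_R2_sol", "V(r1,r2,n)@solution", "VEGFR2(L)@surface",
             c(1, "r1"), c(1, "L"), "kon_V_R2", types),
    bindRule("bind_V_R1_sol", "V(r1,r2,n)@solution", "VEGFR1(L)@surface",
             c(1, "r1"), c(1, "L"), "kon_V_R1", types),
    bindRule("bind_V_N1_sol", "V(r1,r2,n)@solution", "NRP1(b)@surface",
             c(1, "n"), c(1, "b"), "kon_V_N1", types),
    unbindRule("unbind_Vr1_R2", "V(r1!1).VEGFR2(L!1)@surface", c(1, "r1"),
               "koff_V_R2", types),
    unbindRule("unbind_Vr2_R2", "V(r2!1).VEGFR2(L!1)@surface", c(1, "r2"),
               "koff_V_R2", types),
    unbindRule("unbind_Vr1_R1", "V(r1!1).VEGFR1(L!1)@surface", c(1, "r1"),
               "koff_V_R1", types),
    unbindRule("unbind_Vr2_R1", "V(r2!1).VEGFR1(L!1)@surface", c(1, "r2"),
               "koff_V_R1", types),
    unbindRule("unbind_V_N1", "V(n!1).NRP1(b!1)@surface", c(1, "n"),
               "koff_V_N1", types),

    ## --- ligand-mediated receptor bridging (dimerization) ----------------
    # the anchoring receptor's C site must be free, and the target must be an
    # unliganded, uncoupled receptor: keeps aggregates at tetramer scale
    bindRule("bridge_r2_R2fromR2", "V(r1!1,r2).VEGFR2(L!1,C)@surface",
             "VEGFR2(L,C)@surface", c(1, "r2"), c(1, "L"), "kc_V_R2", types),
    bindRule("bridge_r2_R1fromR2", "V(r1!1,r2).VEGFR2(L!1,C)@surface",
             "VEGFR1(L,C)@surface", c(1, "r2"), c(1, "L"), "kc_V_R1", types),
    bindRule("bridge_r2_R2fromR1", "V(r1!1,r2).VEGFR1(L!1,C)@surface",
             "VEGFR2(L,C)@surface", c(1, "r2"), c(1, "L"), "kc_V_R2", types),
    bindRule("bridge_r2_R1fromR1", "V(r1!1,r2).VEGFR1(L!1,C)@surface",
             "VEGFR1(L,C)@surface", c(1, "r2"), c(1, "L"), "kc_V_R1", types),
    bindRule("bridge_r1_R2fromR2", "V(r2!1,r1).VEGFR2(L!1,C)@surface",
             "VEGFR2(L,C)@surface", c(1, "r1"), c(1, "L"), "kc_V_R2", types),
    bindRule("bridge_r1_R1fromR2", "V(r2!1,r1).VEGFR2(L!1,C)@surface",
             "VEGFR1(L,C)@surface", c(1, "r1"), c(1, "L"), "kc_V_R1", types),
    bindRule("bridge_r1_R2fromR1", "V(r2!1,r1).VEGFR1(L!1,C)@surface",
             "VEGFR2(L,C)@surface", c(1, "r1"), c(1, "L"), "kc_V_R2", types),
    bindRule("bridge_r1_R1fromR1", "V(r2!1,r1).VEGFR1(L!1,C)@surface",
             "VEGFR1(L,C)@surface", c(1, "r1"), c(1, "L"), "kc_V_R1", types),

    ## --- NRP1 coupling ----------------------------------------------------
    bindRule("bind_V_N1_mem", "V(n)@surface", "NRP1(b)@surface",
             c(1, "n"), c(1, "b"), "kc_V_N1", types),
    bindRule("bind_R1_N1", "VEGFR1(N)@surface", "NRP1(b)@surface",
             c(1, "N"), c(1, "b"), "kc_R1_N1", types),
    unbindRule("unbind_R1_N1", "VEGFR1(N!1).NRP1(b!1)@surface", c(1, "N"),
               "koff_R1_N1", types),

    ## --- ligand-independent C-C dimerization of unliganded monomers ------
    bindRule("cc_R2R2", "VEGFR2(L,C)@surface", "VEGFR2(L,C)@surface",
             c(1, "C"), c(1, "C"), "kc_CC", types),
    bindRule("cc_R2R1", "VEGFR2(L,C)@surface", "VEGFR1(L,C)@surface",
             c(1, "C"), c(1, "C"), "kc_CC", types),
    bindRule("cc_R1R1", "VEGFR1(L,C)@surface", "VEGFR1(L,C)@surface",
             c(1, "C"), c(1, "C"), "kc_CC", types),
    unbindRule("uncc_R2R2", "VEGFR2(C!1).VEGFR2(C!1)@surface", c(1, "C"),
               "koff_CC", types),
    unbindRule("uncc_R2R1", "VEGFR2(C!1).VEGFR1(C!1)@surface", c(1, "C"),
               "koff_CC", types),
    unbindRule("uncc_R1R1", "VEGFR1(C!1).VEGFR1(C!1)@surface", c(1, "C"),
               "koff_CC", types),

    ## --- Y1175 phosphorylation in liganded VEGFR2 homodimers -------------
    # trans-autophosphorylation fires at the plasma membrane; internalized
    # complexes are processed (dephosphorylated, then recycled or degraded)
    stateRule("phos_bridged", "V(r1!1,r2!2).VEGFR2(L!1,Y~U).VEGFR2(L!2)@surface",
              2L, "Y", "P", "kphos", types),
    stateRule("phos_cc_trans", "VEGFR2(Y~U,C!1).VEGFR2(C!1,L!2).V(r1!2)@surface",
              1L, "Y", "P", "kphos", types),
    stateRule("phos_cc_cis", "VEGFR2(Y~U,C!1,L!2).V(r1!2).VEGFR2(C!1,L)@surface",
              1L, "Y", "P", "kphos", types),
    stateRule("dephos_surf", "VEGFR2(Y~P)@surface", 1L, "Y", "U",
              "kdephos_surf", types),
    stateRule("dephos_endo", "VEGFR2(Y~P)@endosome", 1L, "Y", "U",
              "kdephos_endo", types),

    ## --- trafficking of liganded complexes (VEGFR1 stays on the membrane) -
    transportRule("int_nrp1", "VEGFR2(L!+)@surface", "endosome", "kint_nrp1",
                  types, list(list(require = "NRP1", exclude = "VEGFR1"))),
    transportRule("int_plain", "VEGFR2(L!+)@surface", "endosome", "kint",
                  types, list(list(exclude = c("NRP1", "VEGFR1")))),
    transportRule("rec_nrp1", "VEGFR2(L!+)@endosome", "surface", "krec_nrp1",
                  types, list(list(require = "NRP1", excludePattern = noP))),
    transportRule("rec_plain", "VEGFR2(L!+)@endosome", "surface", "krec",
                  types, list(list(exclude = "NRP1", excludePattern = noP))),
    # degradation, like recycling, acts on dephosphorylated complexes:
    # internalized receptors are processed sequentially (dephosphorylate,
    # then sort between recycling and the degradative route)
    degradeRule("deg_nrp1", "VEGFR2(L!+)@endosome", ct, "kdeg_nrp1",
                types, list(list(require = "NRP1", excludePattern = noP))),
    degradeRule("deg_plain", "VEGFR2(L!+)@endosome", ct, "kdeg",
                types, list(list(exclude = "NRP1", excludePattern = noP))),

    ## --- constitutive turnover of unliganded monomeric VEGFR2 ------------
    transportRule("int_const", "VEGFR2(L,C)@surface", "endosome", "kint0",
                  types, list(list(maxSize = 1))),
    transportRule("rec_const", "VEGFR2(L,C)@endosome", "surface", "krec0",
                  types, list(list(maxSize = 1, excludePattern = noP))),
    degradeRule("deg_const", "VEGFR2(L,C)@endosome", ct, "kdeg0",
                types, list(list(maxSize = 1, excludePattern = noP))),
    synthRule("synth_R2", "VEGFR2(L,C,Y~U)@surface", "sR2", types))
  rules
}

#' Default observables of the receptor network
#'
#' Named pattern texts; weights follow BNGL "Molecules" semantics (per
#' embedding, i.e. per receptor copy).
#' @return named character vector of pattern texts.
#' @export
receptorObservables <- function() {
  c(R2tot      = "VEGFR2()",
    R2surf     = "VEGFR2()@surface",
    R2endo     = "VEGFR2()@endosome",
    pR2tot     = "VEGFR2(Y~P)",
    pR2surf    = "VEGFR2(Y~P)@surface",
    pR2endo    = "VEGFR2(Y~P)@endosome",
    R1tot      = "VEGFR1()",
    N1tot      = "NRP1()",
    boundV     = "V()@surface",
    freeV      = "V(r1,r2,n)@solution",
    R2degraded = "R2deg()@sink")
}

#' Expand the receptor network (memoised)
#'
#' Expands \code{\link{buildReceptorRules}} over \code{\link{receptorSeeds}}
#' and attaches the standard observables.  The expansion is deterministic, so
#' the result is cached for the session.
#'
#' @param maxAgg aggregate-size cap (molecules per complex).
#' @return a \linkS4class{ReactionNetwork}.
#' @export
receptorNetwork <- local({
  cache <- new.env(parent = emptyenv())
  function(maxAgg = 6L) {
    key <- as.character(maxAgg)
    if (!is.null(cache[[key]])) return(cache[[key]])
    types <- vegfMoleculeTypes()
    net <- expandNetwork(buildReceptorRules(types), receptorSeeds(types), types,
                         maxAgg = maxAgg)
    for (nm in names(receptorObservables()))
      net <- addObservable(net, nm, receptorObservables()[[nm]], types)
    cache[[key]] <- net
    net
  }
})
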