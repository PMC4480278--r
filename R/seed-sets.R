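## Step 1 of module construction: collect the seed set of a reference term.

#' Build the seed set for a reference term
#'
#' Seeds are the proteins \emph{directly} annotated with the term (not the
#' propagated closure), partitioned into those present in the interaction
#' network and those absent from it. Isolated seeds are carried through the
#' whole module construction as degree-0 members. An optional identifier
#' map translates network node names into annotation space first.
#'
#' @param term a term identifier.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param net an \code{\link{InteractionNetwork}} (already in annotation
#'   identifier space, or mapped via \code{idmap}).
#' @param idmap optional named character vector (network id to annotation
#'   id); applied to the network node names before membership testing.
#' @return A \code{\link{SeedSet}}.
#' @export
buildSeedSet <- function(term, corpus, net, idmap = NULL) {
  term <- resolveTermId(corpus@dag, term)
  seeds <- annotatedProteins(corpus, term, direct = TRUE)
  if (!length(seeds))
    stop("term ", term, " has no directly annotated protein: no module built")
  nodes <- networkNodes(net)
  if (!is.null(idmap) && length(idmap)) {
    hit <- nodes %in% names(idmap)
    nodes[hit] <- unname(idmap[nodes[hit]])
  }
  seeds <- sort(seeds)
  inNet <- seeds[seeds %in% nodes]
  new("SeedSet", term = term, inNetwork = inNet,
      isolated = setdiff(seeds, inNet))
}
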