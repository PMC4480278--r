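setOldClass("igraph")

## ---- OntologyDag -----------------------------------------------------------

#' Ontology DAG of terms
#'
#' A rooted directed acyclic graph of ontology terms connected by
#' \code{is_a} / \code{part_of} child-to-parent edges, as parsed from an
#' OBO 1.2 file by \code{\link{loadObo}}. Ancestor sets (term included) are
#' precomputed at load time; \code{alt_id} aliases resolve to primary ids.
#'
#' @slot terms character vector of primary term identifiers.
#' @slot parents named list; per term, its direct parent identifiers.
#' @slot children named list; per term, its direct child identifiers.
#' @slot roots character vector of terms with no parent.
#' @slot ancestors named list; per term, all ancestors including itself.
#' @slot aliases named character; \code{alt_id} to primary id.
#' @slot termNames named character; term id to human-readable name.
#'
#' @seealso \code{\link{loadObo}}, \code{\link{termAncestors}}
#' @export
setClass("OntologyDag",
  representation(
    terms     = "character",
    parents   = "list",
    children  = "list",
    roots     = "character",
    ancestors = "list",
    aliases   = "character",
    termNames = "character"
  )
)

setValidity("OntologyDag", function(object) {
  msg <- character()
  if (!setequal(names(object@parents), object@terms))
    msg <- c(msg, "parents must be named by exactly the term set")
  if (!all(object@roots %in% object@terms))
    msg <- c(msg, "roots must be terms")
  if (length(object@terms)) {
    bad <- vapply(object@terms, function(t) {
      anc <- object@ancestors[[t]]
      !(t %in% anc) || !any(anc %in% object@roots)
    }, logical(1))
    if (any(bad))
      msg <- c(msg, "every term must reach a root through its ancestor set")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OntologyDag primary term identifiers.
#' @param x an \code{OntologyDag}.
#' @export
setMethod("termIds", "OntologyDag", function(x) x@terms)

#' @describeIn OntologyDag root term identifiers.
#' @export
setMethod("dagRoots", "OntologyDag", function(x) x@roots)

#' @describeIn OntologyDag ancestors of \code{term} (itself included);
#'   \code{alt_id} aliases are resolved first.
#' @param term a term identifier.
#' @export
setMethod("termAncestors", "OntologyDag", function(x, term) {
  term <- resolveTermId(x, term)
  x@ancestors[[term]]
})

setMethod("show", "OntologyDag", function(object) {
  cat("OntologyDag with", length(object@terms), "terms,",
      length(object@roots), "root(s)\n")
  cat("  roots:", paste(utils::head(object@roots, 5), collapse = ", "), "\n")
  if (length(object@aliases))
    cat("  aliases:", length(object@aliases), "\n")
})

## ---- AnnotationCorpus ------------------------------------------------------

#' Protein-to-term annotation corpus
#'
#' Direct annotations plus their ancestor closure over an
#' \code{\link{OntologyDag}}, together with the inverse (term-to-protein)
#' maps used as enrichment backgrounds and as the frequency base for
#' information content.
#'
#' @slot dag the \code{OntologyDag} the annotations refer to.
#' @slot direct named list; protein id to directly annotated term ids.
#' @slot propagated named list; protein id to direct terms plus all ancestors.
#' @slot perTerm named list; term id to proteins carrying it after
#'   propagation (terms annotating no protein are absent).
#' @slot perTermDirect named list; term id to directly annotated proteins.
#'
#' @seealso \code{\link{loadAnnotations}}, \code{\link{informationContent}}
#' @export
setClass("AnnotationCorpus",
  representation(
    dag           = "OntologyDag",
    direct        = "list",
    propagated    = "list",
    perTerm       = "list",
    perTermDirect = "list"
  )
)

setValidity("AnnotationCorpus", function(object) {
  msg <- character()
  if (!setequal(names(object@direct), names(object@propagated)))
    msg <- c(msg, "direct and propagated must cover the same proteins")
  ok <- all(vapply(names(object@direct), function(p) {
    all(object@direct[[p]] %in% object@propagated[[p]])
  }, logical(1)))
  if (!ok) msg <- c(msg, "propagated(p) must contain direct(p)")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnnotationCorpus terms annotating at least one protein
#'   (after propagation).
#' @param x an \code{AnnotationCorpus}.
#' @export
setMethod("termIds", "AnnotationCorpus", function(x) names(x@perTerm))

setMethod("show", "AnnotationCorpus", function(object) {
  cat("AnnotationCorpus:", length(object@direct), "proteins,",
      length(object@perTerm), "terms with >= 1 annotation\n")
})

#' Proteins annotated with a term
#'
#' @param corpus an \code{AnnotationCorpus}.
#' @param term a term identifier.
#' @param direct if \code{TRUE} return only directly annotated proteins;
#'   otherwise the propagated (ancestor-closed) set.
#' @return Character vector of protein identifiers (possibly empty).
#' @export
annotatedProteins <- function(corpus, term, direct = FALSE) {
  term <- resolveTermId(corpus@dag, term)
  tab <- if (direct) corpus@perTermDirect else corpus@perTerm
  out <- tab[[term]]
  if (is.null(out)) character() else out
}

#' Terms annotated to a protein
#'
#' @param corpus an \code{AnnotationCorpus}.
#' @param protein a protein identifier.
#' @param direct if \code{TRUE} return the direct terms, else the propagated
#'   closure.
#' @return Character vector of term identifiers (empty for unannotated
#'   proteins).
#' @export
proteinTerms <- function(corpus, protein, direct = TRUE) {
  tab <- if (direct) corpus@direct else corpus@propagated
  out <- tab[[protein]]
  if (is.null(out)) character() else out
}

## ---- InteractionNetwork ----------------------------------------------------

#' Protein-protein interaction network
#'
#' An undirected, unweighted, simple graph of protein identifiers. Edge
#' scores and action types present in the source file are discarded at load
#' time; self-loops are dropped.
#'
#' @slot graph the underlying \code{igraph} object (named vertices).
#'
#' @seealso \code{\link{loadEdgeList}}, \code{\link{pairwiseSeedDistances}}
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must have no self-loops")
  if (igraph::any_multiple(g)) msg <- c(msg, "graph must have no duplicate edges")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named")
  if (length(msg)) msg else TRUE
})

#' @describeIn InteractionNetwork node (protein) identifiers.
#' @param x an \code{InteractionNetwork}.
#' @export
setMethod("networkNodes", "InteractionNetwork",
          function(x) igraph::V(x@graph)$name)

#' @describeIn InteractionNetwork two-column character matrix of undirected
#'   edges.
#' @export
setMethod("networkEdges", "InteractionNetwork",
          function(x) igraph::as_edgelist(x@graph, names = TRUE))

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges\n")
})

## ---- Module-construction stages -------------------------------------------

#' Seed set for one reference term
#'
#' The proteins directly annotated with the reference term, partitioned into
#' those present in the interaction network and those absent from it
#' (isolated seeds, carried through module construction as degree-0 members).
#'
#' @slot term reference term identifier.
#' @slot inNetwork seeds present in the interaction network.
#' @slot isolated seeds absent from the interaction network.
#'
#' @seealso \code{\link{buildSeedSet}}
#' @export
setClass("SeedSet",
  representation(term = "character", inNetwork = "character",
                 isolated = "character"))

setValidity("SeedSet", function(object) {
  if (length(intersect(object@inNetwork, object@isolated)))
    "inNetwork and isolated must be disjoint" else TRUE
})

#' @describeIn SeedSet all seed proteins (in-network and isolated).
#' @param x a \code{SeedSet}.
#' @export
setMethod("seedProteins", "SeedSet",
          function(x) c(x@inNetwork, x@isolated))

#' @describeIn SeedSet the reference term.
#' @export
setMethod("referenceTerm", "SeedSet", function(x) x@term)

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet for", object@term, "-", length(object@inNetwork),
      "in network,", length(object@isolated), "isolated\n")
})

#' Shortest path network of a seed set
#'
#' The subgraph of the interaction network formed by the union of all
#' shortest paths between every pair of in-network seeds, plus isolated
#' seeds as degree-0 nodes. Full-network seed-to-node distances and
#' shortest-path counts are cached for the ranking and minimization stages.
#'
#' @slot term reference term identifier.
#' @slot graph the SPN as an \code{igraph} (named vertices).
#' @slot seedsInNetwork seed nodes present in the network.
#' @slot isolatedSeeds seed proteins absent from the network.
#' @slot connecting non-seed nodes lying on some seed-pair shortest path.
#' @slot seedDist numeric matrix, seeds x all full-network nodes: hop
#'   distances in the full network.
#' @slot seedPathCounts numeric matrix, seeds x all full-network nodes:
#'   number of distinct shortest paths in the full network.
#'
#' @seealso \code{\link{extractShortestPathNetwork}}
#' @export
setClass("ShortestPathNetwork",
  representation(term = "character", graph = "igraph",
                 seedsInNetwork = "character", isolatedSeeds = "character",
                 connecting = "character", seedDist = "matrix",
                 seedPathCounts = "matrix"))

#' @describeIn ShortestPathNetwork connecting (non-seed) node identifiers.
#' @param x a \code{ShortestPathNetwork}.
#' @export
setMethod("connectingNodes", "ShortestPathNetwork", function(x) x@connecting)

#' @describeIn ShortestPathNetwork the reference term.
#' @export
setMethod("referenceTerm", "ShortestPathNetwork", function(x) x@term)

#' @describeIn ShortestPathNetwork nodes of the SPN (isolated seeds
#'   included).
#' @export
setMethod("networkNodes", "ShortestPathNetwork",
          function(x) c(igraph::V(x@graph)$name, x@isolatedSeeds))

#' @describeIn ShortestPathNetwork edges of the SPN.
#' @export
setMethod("networkEdges", "ShortestPathNetwork",
          function(x) igraph::as_edgelist(x@graph, names = TRUE))

setMethod("show", "ShortestPathNetwork", function(object) {
  cat("ShortestPathNetwork for", object@term, "-",
      igraph::vcount(object@graph), "nodes (",
      length(object@seedsInNetwork), "seeds,",
      length(object@connecting), "connecting ),",
      igraph::ecount(object@graph), "edges\n")
})

#' Function-specific minimal connecting module
#'
#' The minimal connecting network for one reference term: seeds plus the
#' connecting nodes that survive greedy distance-preserving removal, plus
#' isolated seeds. Quality-filter statistics are attached by
#' \code{\link{qualityFilter}} / \code{\link{buildAllModules}}.
#'
#' @slot term reference term identifier.
#' @slot seeds in-network seed proteins.
#' @slot connecting retained connecting nodes.
#' @slot isolatedSeeds seed proteins absent from the network.
#' @slot edges two-column character matrix of module edges.
#' @slot qualityP p-value of the quality t-test (\code{NA} when not
#'   applicable).
#' @slot passedTtest whether the quality t-test accepted the module.
#' @slot hasConnectingNodes whether any connecting node was retained.
#'
#' @seealso \code{\link{minimizeNetwork}}, \code{\link{qualityFilter}}
#' @export
setClass("FunctionModule",
  representation(term = "character", seeds = "character",
                 connecting = "character", isolatedSeeds = "character",
                 edges = "matrix", qualityP = "numeric",
                 passedTtest = "logical", hasConnectingNodes = "logical"))

setValidity("FunctionModule", function(object) {
  msg <- character()
  if (length(intersect(object@seeds, object@connecting)))
    msg <- c(msg, "seeds and connecting nodes must be disjoint")
  if (ncol(object@edges) != 2 && length(object@edges))
    msg <- c(msg, "edges must be a two-column matrix")
  if (length(msg)) msg else TRUE
})

#' @describeIn FunctionModule all member proteins: seeds, retained
#'   connecting nodes and isolated seeds.
#' @param x a \code{FunctionModule}.
#' @export
setMethod("moduleMembers", "FunctionModule",
          function(x) c(x@seeds, x@connecting, x@isolatedSeeds))

#' @describeIn FunctionModule seed proteins (in-network and isolated).
#' @export
setMethod("seedProteins", "FunctionModule",
          function(x) c(x@seeds, x@isolatedSeeds))

#' @describeIn FunctionModule retained connecting nodes.
#' @export
setMethod("connectingNodes", "FunctionModule", function(x) x@connecting)

#' @describeIn FunctionModule the reference term.
#' @export
setMethod("referenceTerm", "FunctionModule", function(x) x@term)

#' @describeIn FunctionModule module edges as a two-column matrix.
#' @export
setMethod("networkEdges", "FunctionModule", function(x) x@edges)

setMethod("show", "FunctionModule", function(object) {
  cat("FunctionModule for", object@term, "-",
      length(object@seeds), "seeds +", length(object@connecting),
      "connecting +", length(object@isolatedSeeds), "isolated;",
      nrow(object@edges), "edges\n")
  if (!is.na(object@qualityP))
    cat("  quality t-test p =", format(object@qualityP, digits = 4),
        if (isTRUE(object@passedTtest)) "(accepted)" else "(rejected)", "\n")
})

#' Collection of built modules plus the per-term build report
#'
#' @slot modules named list of accepted \code{FunctionModule} objects
#'   (names are reference terms).
#' @slot report data.frame with one row per attempted term: outcome
#'   (\code{built}, \code{rejected-by-ttest}, \code{single-connecting-node},
#'   \code{no-connecting-nodes}, \code{too-few-seeds}), seed counts, SPN and
#'   module sizes, quality p-value.
#' @slot alpha significance level used by the quality filter.
#' @slot metadata list of reproducibility metadata (tool version, parameters).
#'
#' @seealso \code{\link{buildAllModules}}, \code{\link{writeModules}}
#' @export
setClass("ModuleSet",
  representation(modules = "list", report = "data.frame",
                 alpha = "numeric", metadata = "list"))

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet:", length(object@modules), "accepted modules out of",
      nrow(object@report), "attempted terms (alpha =", object@alpha, ")\n")
  if (nrow(object@report)) {
    tab <- table(object@report$outcome)
    for (o in names(tab)) cat("  ", o, ":", tab[[o]], "\n")
  }
})

#' @describeIn ModuleSet reference terms of the accepted modules.
#' @param x a \code{ModuleSet}.
#' @export
setMethod("termIds", "ModuleSet", function(x) names(x@modules))

#' Extract the accepted modules of a ModuleSet as a plain list
#'
#' @param x a \code{ModuleSet}.
#' @return Named list of \code{FunctionModule} objects.
#' @export
moduleList <- function(x) x@modules

#' Per-term build report of a ModuleSet
#'
#' @param x a \code{ModuleSet}.
#' @return The report \code{data.frame}.
#' @export
buildReport <- function(x) x@report
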