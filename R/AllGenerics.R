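#' @import methods
#' @importFrom stats t.test phyper setNames
#' @importFrom utils read.delim write.table head
NULL

#' Term identifiers of an ontology or corpus object
#'
#' @param x an object holding ontology terms.
#' @return Character vector of primary term identifiers.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' Root terms of an ontology DAG
#'
#' @param x an \code{OntologyDag}.
#' @return Character vector of root term identifiers.
#' @export
setGeneric("dagRoots", function(x) standardGeneric("dagRoots"))

#' Ancestors of a term (including the term itself)
#'
#' @param x an \code{OntologyDag}.
#' @param term a term identifier (alt-ids are resolved).
#' @return Character vector of ancestor term identifiers, the term included.
#' @export
setGeneric("termAncestors", function(x, term) standardGeneric("termAncestors"))

#' Node identifiers of a network-like object
#'
#' @param x an object with a node set.
#' @return Character vector of node identifiers.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge list of a network-like object
#'
#' @param x an object with an edge set.
#' @return Two-column character matrix; one row per undirected edge.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Protein members of a module-like object
#'
#' @param x a \code{FunctionModule}.
#' @return Character vector of member protein identifiers (seeds, retained
#'   connecting nodes and isolated seeds).
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' Seed proteins of a module-like object
#'
#' @param x a \code{FunctionModule} or \code{SeedSet}.
#' @return Character vector of seed protein identifiers.
#' @export
setGeneric("seedProteins", function(x) standardGeneric("seedProteins"))

#' Connecting (non-seed) proteins of a module-like object
#'
#' @param x a \code{FunctionModule} or \code{ShortestPathNetwork}.
#' @return Character vector of connecting-node identifiers.
#' @export
setGeneric("connectingNodes", function(x) standardGeneric("connectingNodes"))

#' Reference ontology term of a module-like object
#'
#' @param x a module-stage object.
#' @return The reference term identifier.
#' @export
setGeneric("referenceTerm", function(x) standardGeneric("referenceTerm"))
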