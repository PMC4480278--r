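## Interaction-network loading, identifier mapping and distance queries.

#' Build an InteractionNetwork from an edge table
#'
#' Symmetric duplicate rows collapse to one undirected edge; self-loop rows
#' are dropped with a message. A node appearing only in self-loop rows is
#' dropped entirely (it has no usable interaction).
#'
#' @param edges two-column character matrix or data.frame of node pairs.
#' @return An \code{\link{InteractionNetwork}}.
#' @export
makeInteractionNetwork <- function(edges) {
  if (is.null(dim(edges)) || ncol(edges) < 2L)
    stop("edges must have two columns")
  a <- as.character(if (is.data.frame(edges)) edges[[1L]] else edges[, 1L])
  b <- as.character(if (is.data.frame(edges)) edges[[2L]] else edges[, 2L])
  loop <- a == b
  if (any(loop))
    message(sum(loop), " self-loop row(s) dropped")
  a <- a[!loop]; b <- b[!loop]
  if (!length(a)) stop("no edges after filtering")
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  keep <- !duplicated(key)
  el <- cbind(pmin(a, b)[keep], pmax(a, b)[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  new("InteractionNetwork", graph = g)
}

#' Load an interaction network from an edge-list file
#'
#' Two dialects are supported. \code{generic}: two tab-separated identifier
#' columns, \code{#} comments allowed. \code{string-actions}: a header line
#' plus tab-separated columns including \code{item_id_a}, \code{item_id_b}
#' and \code{mode}; all rows are retained irrespective of action mode or
#' score, and multiple modes on the same pair collapse to a single edge.
#' The loaded graph is undirected, unweighted and simple.
#'
#' @param path path to the edge-list file.
#' @param dialect \code{"generic"} or \code{"string-actions"}.
#' @return An \code{\link{InteractionNetwork}}.
#' @export
loadEdgeList <- function(path, dialect = c("generic", "string-actions")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "generic") {
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("no edges in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop("malformed edge row ", bad[1L], ": ", lines[bad[1L]])
    edges <- data.frame(a = vapply(fields, `[[`, "", 1L),
                        b = vapply(fields, `[[`, "", 2L))
  } else {
    if (length(lines) < 2L) stop("no edges in ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    ia <- match("item_id_a", header); ib <- match("item_id_b", header)
    if (is.na(ia) || is.na(ib))
      stop("string-actions header must contain item_id_a and item_id_b")
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(fields) < max(ia, ib))
    if (length(bad))
      stop("malformed edge row ", bad[1L] + 1L, ": ", lines[bad[1L] + 1L])
    edges <- data.frame(a = vapply(fields, `[[`, "", ia),
                        b = vapply(fields, `[[`, "", ib))
  }
  makeInteractionNetwork(edges)
}

#' Write a network as a generic two-column edge list
#'
#' @param net an \code{\link{InteractionNetwork}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  el <- networkEdges(net)
  ## deterministic row order
  o <- order(el[, 1L], el[, 2L])
  utils::write.table(el[o, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a network-to-annotation identifier map
#'
#' Two tab-separated columns (network id, annotation id); \code{#} comments
#' allowed. Network ids mapping to more than one annotation id are
#' ambiguous and dropped with a warning.
#'
#' @param path path to the mapping TSV.
#' @return Named character vector: network id to annotation id.
#' @export
loadIdMap <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("id map must have two columns")
  tab <- unique(tab[, 1:2])
  dup <- tab[[1L]][duplicated(tab[[1L]])]
  if (length(dup)) {
    warning(length(unique(dup)), " ambiguous network id(s) dropped: ",
            paste(unique(dup), collapse = ", "))
    tab <- tab[!tab[[1L]] %in% dup, ]
  }
  setNames(tab[[2L]], tab[[1L]])
}

#' Rename network nodes into annotation identifier space
#'
#' Nodes without a mapping keep their original identifier.
#'
#' @param net an \code{\link{InteractionNetwork}}.
#' @param idmap named character vector from \code{\link{loadIdMap}}, or
#'   \code{NULL} for a no-op.
#' @return An \code{\link{InteractionNetwork}} with renamed nodes.
#' @export
applyIdMap <- function(net, idmap) {
  if (is.null(idmap) || !length(idmap)) return(net)
  nm <- igraph::V(net@graph)$name
  hit <- nm %in% names(idmap)
  nm[hit] <- unname(idmap[nm[hit]])
  g <- net@graph
  igraph::V(g)$name <- nm
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new("InteractionNetwork", graph = g)
}

#' Hop distances between all pairs of seed proteins
#'
#' Breadth-first-search distances in the unweighted network; seed pairs in
#' different components map to \code{Inf}. Only unordered distinct pairs are
#' returned.
#'
#' @param net an \code{\link{InteractionNetwork}}.
#' @param seeds character vector of node identifiers present in \code{net}.
#' @return data.frame with columns \code{seed1}, \code{seed2},
#'   \code{distance}.
#' @export
pairwiseSeedDistances <- function(net, seeds) {
  seeds <- unique(seeds)
  missing <- setdiff(seeds, networkNodes(net))
  if (length(missing))
    stop("seed(s) absent from network: ", paste(missing, collapse = ", "))
  if (length(seeds) < 2L)
    return(data.frame(seed1 = character(), seed2 = character(),
                      distance = numeric()))
  d <- igraph::distances(net@graph, v = seeds, to = seeds, weights = NA)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  data.frame(seed1 = seeds[idx[, 1L]], seed2 = seeds[idx[, 2L]],
             distance = d[idx])
}
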