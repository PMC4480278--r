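## Step 2 of module construction: the shortest path network (SPN).

#' Extract the shortest path network of a seed set
#'
#' The SPN is the union of \emph{all} shortest paths between every pair of
#' in-network seeds: a non-seed node \code{v} belongs iff
#' \code{d(s,v) + d(v,t) = d(s,t)} for some seed pair \code{(s,t)}, and an
#' edge \code{(u,v)} belongs iff \code{d(s,u) + 1 + d(v,t) = d(s,t)} in
#' either orientation for some pair. Distances are unweighted hop counts in
#' the full network. Seed pairs in different components impose no
#' constraint; isolated seeds ride along as degree-0 nodes. Full-network
#' seed distances and shortest-path counts are cached on the returned
#' object for the ranking and minimization stages.
#'
#' @param net an \code{\link{InteractionNetwork}}.
#' @param seeds a \code{\link{SeedSet}} with at least one in-network seed.
#' @return A \code{\link{ShortestPathNetwork}}.
#' @export
extractShortestPathNetwork <- function(net, seeds) {
  sIn <- seeds@inNetwork
  if (!length(sIn))
    stop("no in-network seed for term ", seeds@term)
  g <- net@graph
  nodes <- igraph::V(g)$name
  dc <- .seedDistCounts(g, sIn)
  D <- dc$dist

  ns <- length(sIn)
  keepNode <- setNames(logical(length(nodes)), nodes)
  keepNode[sIn] <- TRUE
  el <- igraph::as_edgelist(g, names = TRUE)
  keepEdge <- logical(nrow(el))
  if (ns >= 2L) {
    du <- D[, el[, 1L], drop = FALSE]  # seeds x edges
    dv <- D[, el[, 2L], drop = FALSE]
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        dst <- D[i, sIn[j]]
        if (is.infinite(dst)) next
        keepNode <- keepNode | (D[i, ] + D[j, ] == dst)
        keepEdge <- keepEdge |
          (du[i, ] + 1 + dv[j, ] == dst) | (dv[i, ] + 1 + du[j, ] == dst)
      }
    }
  }
  spnNodes <- nodes[keepNode[nodes]]
  spnEdges <- el[keepEdge, , drop = FALSE]
  spnGraph <- igraph::graph_from_data_frame(
    as.data.frame(spnEdges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = spnNodes, stringsAsFactors = FALSE))

  new("ShortestPathNetwork",
      term = seeds@term, graph = spnGraph, seedsInNetwork = sIn,
      isolatedSeeds = seeds@isolated,
      connecting = sort(setdiff(spnNodes, sIn)),
      seedDist = D, seedPathCounts = dc$count)
}
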