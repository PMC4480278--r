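## Step 4 of module construction: greedy distance-preserving minimization.

#' Reduce a shortest path network to its minimal connecting module
#'
#' Processes the connecting nodes from least to most important (the order
#' of \code{ranking}) and deletes a node, with its incident edges, iff
#' after the deletion every connected seed pair still realizes its
#' original full-network shortest distance. The result is
#' distance-preserving and 1-minimal: no single retained connecting node
#' can be removed without stretching some seed pair. Because later
#' deletions only shrink the graph, a node retained once can never become
#' removable, so a single greedy pass suffices. The removal test always
#' compares against the \emph{full-network} distances cached on the SPN,
#' not distances in the partially minimized graph.
#'
#' @param spn a \code{\link{ShortestPathNetwork}}.
#' @param ranking removal order from \code{\link{rankConnectingNodes}};
#'   must cover exactly the SPN's connecting nodes.
#' @return A \code{\link{FunctionModule}} (quality flags unset).
#' @export
minimizeNetwork <- function(spn, ranking) {
  if (!setequal(ranking$node, spn@connecting))
    stop("ranking must cover exactly the connecting nodes of the SPN")
  g <- spn@graph
  seeds <- spn@seedsInNetwork
  ns <- length(seeds)
  ## required distances: originally-finite seed pairs only
  Dreq <- spn@seedDist[, seeds, drop = FALSE]
  finitePair <- is.finite(Dreq) & upper.tri(Dreq)

  for (v in ranking$node) {
    g2 <- igraph::delete_vertices(g, v)
    if (ns >= 2L && any(finitePair)) {
      d2 <- igraph::distances(g2, v = seeds, to = seeds, weights = NA)
      if (!all(d2[finitePair] == Dreq[finitePair])) next
    }
    g <- g2
  }
  retained <- sort(setdiff(igraph::V(g)$name, seeds))
  el <- igraph::as_edgelist(g, names = TRUE)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  new("FunctionModule",
      term = spn@term, seeds = seeds, connecting = retained,
      isolatedSeeds = spn@isolatedSeeds, edges = el,
      qualityP = NA_real_, passedTtest = NA,
      hasConnectingNodes = length(retained) > 0L)
}

#' Verify the distance-preservation invariant of a module
#'
#' Recomputes all connected seed-pair distances inside the module graph and
#' compares them with the full-network distances. Mainly used in tests and
#' reports.
#'
#' @param module a \code{\link{FunctionModule}}.
#' @param net the full \code{\link{InteractionNetwork}}.
#' @return \code{TRUE} when every originally connected seed pair keeps its
#'   full-network distance inside the module.
#' @export
preservesSeedDistances <- function(module, net) {
  seeds <- module@seeds
  if (length(seeds) < 2L) return(TRUE)
  dFull <- igraph::distances(net@graph, v = seeds, to = seeds, weights = NA)
  g <- .moduleGraph(module)
  dMod <- igraph::distances(g, v = seeds, to = seeds, weights = NA)
  fin <- is.finite(dFull) & upper.tri(dFull)
  all(dMod[fin] == dFull[fin])
}

## module as an igraph over seeds + retained connecting nodes
.moduleGraph <- function(module) {
  nodes <- c(module@seeds, module@connecting)
  igraph::graph_from_data_frame(
    as.data.frame(module@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}
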