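## Step 3 of module construction: rank connecting nodes for removal.

#' Rank the connecting nodes of a shortest path network
#'
#' Each connecting node gets the triple used as hierarchical sort keys for
#' greedy removal:
#' \describe{
#'   \item{sc (seed centrality)}{number of distinct seed pairs for which the
#'     node lies on some shortest path, counted on full-network distances.}
#'   \item{ss (semantic similarity)}{maximum Lin similarity between the
#'     node's direct annotation terms and the reference term; 0 for
#'     unannotated nodes.}
#'   \item{bc (seed-restricted betweenness)}{sum over connected seed pairs
#'     of the fraction of their shortest paths passing through the node,
#'     endpoints excluded.}
#' }
#' The returned table is sorted ascending by \code{(sc, ss, bc)} — least
#' important node first, which is the removal order — with ties broken by
#' ascending node identifier so that results are deterministic.
#'
#' @param spn a \code{\link{ShortestPathNetwork}}.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param reference the reference term; defaults to the SPN's term.
#' @return data.frame with columns \code{node}, \code{sc}, \code{ss},
#'   \code{bc}, one row per connecting node, in removal order.
#' @export
rankConnectingNodes <- function(spn, corpus,
                                reference = referenceTerm(spn)) {
  conn <- spn@connecting
  if (!length(conn))
    return(data.frame(node = character(), sc = integer(),
                      ss = numeric(), bc = numeric()))
  seeds <- spn@seedsInNetwork
  D <- spn@seedDist
  C <- spn@seedPathCounts
  ns <- length(seeds)
  sc <- setNames(integer(length(conn)), conn)
  bc <- setNames(numeric(length(conn)), conn)
  if (ns >= 2L) {
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        dst <- D[i, seeds[j]]
        if (is.infinite(dst)) next
        on <- D[i, conn] + D[j, conn] == dst
        sc[on] <- sc[on] + 1L
        sigma <- C[i, seeds[j]]
        bc[on] <- bc[on] + C[i, conn[on]] * C[j, conn[on]] / sigma
      }
    }
  }
  ss <- semanticSimilarityProfile(conn, reference, corpus)
  out <- data.frame(node = conn, sc = unname(sc), ss = unname(ss[conn]),
                    bc = unname(bc), stringsAsFactors = FALSE)
  out[order(out$sc, out$ss, out$bc, out$node), , drop = FALSE]
}
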