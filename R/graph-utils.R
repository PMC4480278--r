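## Internal BFS helpers. igraph provides distances but no per-pair
## shortest-path counts, so counting is done with an explicit layered BFS
## over integer adjacency lists.

## adjacency list as a list of integer vectors, 1-based vertex indices
.adjList <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

## distances and shortest-path counts from one source to every vertex.
## Returns list(dist = numeric (Inf if unreachable), count = numeric).
.bfsCounts <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n); count <- numeric(n)
  dist[src] <- 0; count[src] <- 1
  frontier <- src
  d <- 0
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- d + 1
          nxt <- c(nxt, w)
          count[w] <- count[v]
        } else if (dist[w] == d + 1) {
          count[w] <- count[w] + count[v]
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  list(dist = dist, count = count)
}

## seeds x all-vertices matrices of full-network distances and path counts
.seedDistCounts <- function(graph, seeds) {
  nodes <- igraph::V(graph)$name
  adj <- .adjList(graph)
  idx <- match(seeds, nodes)
  dist <- matrix(Inf, length(seeds), length(nodes),
                 dimnames = list(seeds, nodes))
  cnt <- matrix(0, length(seeds), length(nodes),
                dimnames = list(seeds, nodes))
  for (i in seq_along(seeds)) {
    b <- .bfsCounts(adj, idx[i])
    dist[i, ] <- b$dist
    cnt[i, ] <- b$count
  }
  list(dist = dist, count = cnt)
}
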