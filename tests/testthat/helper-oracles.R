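## Shared fixture builders and independent oracles. The oracles deliberately
## take different routes from the implementation: explicit shortest-path
## enumeration (igraph::all_shortest_paths), exhaustive subset search,
## direct log-space tail summation, and a from-scratch ancestor walk.

netFromEdges <- function(...) {
  pairs <- list(...)
  makeInteractionNetwork(do.call(rbind, pairs))
}

## random simple graph wrapped as InteractionNetwork (isolated nodes kept)
randomNet <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  new("InteractionNetwork", graph = g)
}

## two-term helper corpus over a chain DAG (root <- A <- C) with
## 10 proteins: 5 reach A (2 of which reach C), all reach root
chainCorpus <- function() {
  dag <- makeOntologyDag(list(R = character(), A = "R", C = "A"))
  ann <- rbind(
    data.frame(protein = sprintf("p%02d", 1:3), term = "A"),
    data.frame(protein = sprintf("p%02d", 4:5), term = "C"),
    data.frame(protein = sprintf("p%02d", 6:10), term = "R"))
  makeAnnotationCorpus(ann, dag)
}

## minimal corpus whose term TP directly annotates the given seeds
seedCorpus <- function(seeds, extraAnn = NULL) {
  dag <- makeOntologyDag(list(R = character(), TP = "R"))
  ann <- data.frame(protein = seeds, term = "TP")
  if (!is.null(extraAnn)) ann <- rbind(ann, extraAnn)
  makeAnnotationCorpus(ann, dag)
}

## ---- SPN oracle: enumerate all shortest paths explicitly ----------------

oracleSpn <- function(net, seeds) {
  g <- net@graph
  nodes <- character(); edges <- character()
  seeds <- intersect(seeds, igraph::V(g)$name)
  if (length(seeds) >= 2L) {
    for (i in seq_len(length(seeds) - 1L)) {
      for (j in (i + 1L):length(seeds)) {
        asp <- suppressWarnings(igraph::all_shortest_paths(
          g, from = seeds[i], to = seeds[j]))
        paths <- asp$res
        if (is.null(paths)) paths <- asp$vpaths
        for (p in paths) {
          nm <- igraph::V(g)$name[as.integer(p)]
          nodes <- c(nodes, nm)
          if (length(nm) > 1L) {
            a <- nm[-length(nm)]; b <- nm[-1L]
            edges <- c(edges, paste(pmin(a, b), pmax(a, b), sep = "|"))
          }
        }
      }
    }
  }
  list(nodes = sort(unique(c(nodes, seeds))),
       edges = sort(unique(edges)))
}

spnAsSets <- function(spn) {
  el <- networkEdges(spn)
  edges <- if (nrow(el)) sort(paste(pmin(el[, 1], el[, 2]),
                                    pmax(el[, 1], el[, 2]), sep = "|"))
           else character()
  list(nodes = sort(igraph::V(spn@graph)$name), edges = edges)
}

## ---- exact minimum distance-preserving subgraph (exhaustive) -------------

oracleMinPreserving <- function(net, seeds) {
  g <- net@graph
  all <- igraph::V(g)$name
  seeds <- intersect(seeds, all)
  dFull <- igraph::distances(g, v = seeds, to = seeds, weights = NA)
  fin <- is.finite(dFull) & upper.tri(dFull)
  others <- setdiff(all, seeds)
  best <- length(all)
  for (size in 0:length(others)) {
    if (length(seeds) + size >= best) break
    subsets <- if (size == 0L) list(character()) else
      asplit(utils::combn(others, size), 2L)
    for (s in subsets) {
      sub <- igraph::induced_subgraph(g, c(seeds, unlist(s)))
      d <- igraph::distances(sub, v = seeds, to = seeds, weights = NA)
      if (all(d[fin] == dFull[fin])) {
        best <- length(seeds) + size
        break
      }
    }
    if (best == length(seeds) + size) break
  }
  best
}

## ---- hypergeometric tail by direct log-space summation -------------------

oracleHyperTail <- function(N, K, n, k) {
  j <- k:min(K, n)
  if (!length(j)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

## ---- Lin similarity by from-scratch ancestor walk ------------------------

## ancestors via repeated parent expansion, independent of dag@ancestors
walkAncestors <- function(parents, term) {
  out <- character(); frontier <- term
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), out)
  }
  out
}

oracleLin <- function(corpus, t1, t2) {
  parents <- corpus@dag@parents
  nProt <- length(corpus@propagated)
  ## recount term frequencies from the direct annotations
  freq <- sapply(names(parents), function(t) {
    sum(vapply(corpus@direct, function(ts)
      any(vapply(ts, function(x) t %in% walkAncestors(parents, x),
                 logical(1))), logical(1)))
  })
  ic <- function(t) -log(freq[[t]] / nProt)
  common <- intersect(walkAncestors(parents, t1), walkAncestors(parents, t2))
  common <- common[freq[common] > 0]
  denom <- ic(t1) + ic(t2)
  if (denom == 0 || !length(common)) return(0)
  2 * max(vapply(common, ic, 0)) / denom
}

## random DAG (term i may have parents among earlier terms) + annotations
randomDagCorpus <- function(nTerms, nProteins, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(nTerms))
  parents <- list()
  parents[[terms[1L]]] <- character()
  for (i in seq_len(nTerms)[-1L]) {
    np <- sample(0:min(2L, i - 1L), 1L)
    parents[[terms[i]]] <- if (np) sample(terms[seq_len(i - 1L)], np)
                           else character()
  }
  dag <- makeOntologyDag(parents)
  prot <- sprintf("p%02d", seq_len(nProteins))
  ann <- data.frame(protein = sample(prot, nProteins * 2L, replace = TRUE),
                    term = sample(terms, nProteins * 2L, replace = TRUE))
  list(dag = dag, corpus = makeAnnotationCorpus(ann, dag))
}
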