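## Synthetic fixtures: random background interactome + planted
## function-specific modules + toy ontology + annotations.

## independent, reproducible substreams derived from one user seed
.substream <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k * 10007) %% 2147483647
}

#' Specification of a planted function-specific module
#'
#' @param term term identifier of the planted function.
#' @param nSeeds number of seed proteins (directly annotated with
#'   \code{term}).
#' @param nConnectors number of planted connecting proteins; the seeds are
#'   split into two groups wired as cliques, all direct cross-group edges
#'   are removed, and each connector bridges one matched cross-group seed
#'   pair — so it provably lies on that pair's shortest paths (at most
#'   \code{floor(nSeeds / 2)}).
#' @param wiringDensity probability of each non-consecutive within-group
#'   edge. The default 1 makes the two groups cliques, keeping seed-pair
#'   geodesics inside the planted module; lower values let them route
#'   through the background.
#' @return A list describing the module, for \code{\link{fixtureSpec}}.
#' @export
plantedModule <- function(term, nSeeds = 8L, nConnectors = 4L,
                          wiringDensity = 1) {
  stopifnot(nSeeds >= 2L, nConnectors >= 0L,
            nConnectors <= floor(nSeeds / 2),
            wiringDensity >= 0, wiringDensity <= 1)
  list(term = term, nSeeds = as.integer(nSeeds),
       nConnectors = as.integer(nConnectors),
       wiringDensity = wiringDensity)
}

#' Fixture specification
#'
#' Holds every parameter of the synthetic benchmark generator. The
#' defaults are the package's reference study conditions: a 300-node
#' Erdős–Rényi background with mean degree about 6, one subject module of
#' 12 proteins (8 seeds + 4 connectors) plus four decoy modules of the
#' same shape on disjoint nodes and disjoint ontology subtrees (an
#' overrepresentation background needs modules beyond the subject term),
#' and a 0.1 annotation noise rate.
#'
#' @slot seed master random seed; all substreams (graph, annotations,
#'   queries) derive from it.
#' @slot nNodes background network size.
#' @slot model \code{"erdos-renyi"} or \code{"preferential-attachment"}.
#' @slot edgeProb edge probability for the Erdős–Rényi model.
#' @slot paEdges edges per node for the preferential-attachment model.
#' @slot ontologyDepth,branching shape of the background term tree whose
#'   leaves are used as noise annotations.
#' @slot modules list of \code{\link{plantedModule}} specifications.
#' @slot noiseRate probability that a background (non-planted) node gets
#'   one uniformly random background leaf term.
#' @export
setClass("FixtureSpec",
  representation(seed = "numeric", nNodes = "integer", model = "character",
                 edgeProb = "numeric", paEdges = "integer",
                 ontologyDepth = "integer", branching = "integer",
                 modules = "list", noiseRate = "numeric"))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@nNodes < 1L) msg <- c(msg, "nNodes must be positive")
  if (object@noiseRate < 0 || object@noiseRate > 1)
    msg <- c(msg, "noiseRate must be in [0, 1]")
  if (!object@model %in% c("erdos-renyi", "preferential-attachment"))
    msg <- c(msg, "unknown background model")
  planted <- sum(vapply(object@modules,
                        function(m) m$nSeeds + m$nConnectors, 0))
  if (planted > object@nNodes)
    msg <- c(msg, "planted modules larger than the network: infeasible spec")
  if (length(msg)) msg else TRUE
})

#' Create a fixture specification
#'
#' @param seed master random seed.
#' @param nNodes background network size.
#' @param model background graph model.
#' @param edgeProb Erdős–Rényi edge probability.
#' @param paEdges preferential-attachment edges per node.
#' @param ontologyDepth,branching background term-tree shape.
#' @param modules list of \code{\link{plantedModule}} specs.
#' @param noiseRate background annotation noise rate.
#' @return A validated \code{\link{FixtureSpec}}.
#' @export
fixtureSpec <- function(seed = 1, nNodes = 300L,
                        model = c("erdos-renyi", "preferential-attachment"),
                        edgeProb = 0.02, paEdges = 3L,
                        ontologyDepth = 3L, branching = 2L,
                        modules = c(list(plantedModule("T:PLANTED1")),
                                    lapply(1:4, function(i)
                                      plantedModule(sprintf("T:DECOY%d", i)))),
                        noiseRate = 0.1) {
  model <- match.arg(model)
  new("FixtureSpec", seed = seed, nNodes = as.integer(nNodes),
      model = model, edgeProb = edgeProb, paEdges = as.integer(paEdges),
      ontologyDepth = as.integer(ontologyDepth),
      branching = as.integer(branching), modules = modules,
      noiseRate = noiseRate)
}

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec:", object@nNodes, "nodes (", object@model, "),",
      length(object@modules), "planted module(s), noise",
      object@noiseRate, ", seed", object@seed, "\n")
})

#' A generated synthetic fixture
#'
#' @slot network the planted \code{\link{InteractionNetwork}}.
#' @slot dag the toy \code{\link{OntologyDag}}.
#' @slot corpus the \code{\link{AnnotationCorpus}}.
#' @slot groundTruth named list: planted term to its planted member set
#'   (seeds then connectors).
#' @slot spec the generating \code{\link{FixtureSpec}}.
#' @export
setClass("SyntheticFixture",
  representation(network = "InteractionNetwork", dag = "OntologyDag",
                 corpus = "AnnotationCorpus", groundTruth = "list",
                 spec = "FixtureSpec"))

setMethod("show", "SyntheticFixture", function(object) {
  cat("SyntheticFixture:", igraph::vcount(object@network@graph),
      "nodes; planted terms:",
      paste(names(object@groundTruth), collapse = ", "), "\n")
})

## background tree: root -> internal levels -> leaves; returns parents list
.backgroundTree <- function(depth, branching) {
  parents <- list("T:ROOT" = character())
  level <- "T:ROOT"
  id <- 0L
  for (d in seq_len(depth)) {
    nxt <- character()
    for (p in level) {
      for (b in seq_len(branching)) {
        id <- id + 1L
        t <- sprintf("T:BG%04d", id)
        parents[[t]] <- p
        nxt <- c(nxt, t)
      }
    }
    level <- nxt
  }
  list(parents = parents, leaves = level)
}

#' Generate a synthetic fixture
#'
#' Builds the background graph, plants each module, assembles the toy
#' ontology and annotations, and returns everything plus the ground truth.
#' A planted module splits its seeds into two cliques whose direct
#' cross-group edges are removed; each connector \eqn{c_j} bridges one
#' matched cross-group seed pair, making that pair's distance exactly 2
#' with \eqn{c_j} on a shortest path by construction (and, barring a
#' chance background common neighbour, the only one, so minimization must
#' retain it). Seeds are directly annotated with the planted term and
#' each connector with its own sibling term under the same parent, so that
#' planted modules pass the semantic quality filter while background noise
#' annotations (drawn from a disjoint subtree) score zero similarity.
#' Background nodes left without any interaction are dropped so fixtures
#' round-trip exactly through edge-list files. Identical spec and seed
#' give identical fixtures.
#'
#' @param spec a \code{\link{FixtureSpec}}.
#' @return A \code{\link{SyntheticFixture}}.
#' @export
generateFixture <- function(spec) {
  validObject(spec)
  n <- spec@nNodes
  nodes <- sprintf("P%04d", seq_len(n))

  set.seed(.substream(spec@seed, 1L))  # graph substream
  g <- if (spec@model == "erdos-renyi")
    igraph::sample_gnp(n, spec@edgeProb)
  else
    igraph::sample_pa(n, m = spec@paEdges, directed = FALSE)
  igraph::V(g)$name <- nodes

  ## ontology: background tree + one subtree per planted module
  bg <- .backgroundTree(spec@ontologyDepth, spec@branching)
  parents <- bg$parents
  for (m in spec@modules) {
    par <- paste0(m$term, ":PARENT")
    parents[[par]] <- "T:ROOT"
    parents[[m$term]] <- par
    ## one related sibling term per connector: each annotates a single
    ## protein, so no module is attempted for it
    for (j in seq_len(m$nConnectors))
      parents[[paste0(m$term, ":REL", j)]] <- par
  }
  dag <- makeOntologyDag(parents)

  ## plant modules
  free <- nodes
  truth <- list()
  ann <- list(protein = character(), term = character())
  addAnn <- function(p, t) {
    ann$protein <<- c(ann$protein, p); ann$term <<- c(ann$term, t)
  }
  for (m in spec@modules) {
    size <- m$nSeeds + m$nConnectors
    if (size > length(free)) stop("infeasible spec: not enough free nodes")
    picked <- sort(sample(free, size))
    free <- setdiff(free, picked)
    seeds <- picked[seq_len(m$nSeeds)]
    connectors <- setdiff(picked, seeds)
    half <- ceiling(m$nSeeds / 2)
    groupA <- seeds[seq_len(half)]
    groupB <- seeds[-seq_len(half)]
    hasEdge <- function(a, b)
      suppressWarnings(igraph::get_edge_ids(g, c(a, b))) > 0
    dropEdge <- function(a, b) {
      eid <- suppressWarnings(igraph::get_edge_ids(g, c(a, b)))
      if (eid > 0) g <<- igraph::delete_edges(g, eid)
    }
    addEdge <- function(a, b) if (!hasEdge(a, b))
      g <<- igraph::add_edges(g, c(a, b))
    ## cross-group pairs interact only through connectors
    for (a in groupA) for (b in groupB) dropEdge(a, b)
    ## within-group wiring: consecutive edges always (connectivity),
    ## non-consecutive ones with probability wiringDensity
    for (grp in list(groupA, groupB)) {
      ng <- length(grp)
      if (ng < 2L) next
      for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
        if (j == i + 1L || stats::runif(1L) <= m$wiringDensity)
          addEdge(grp[i], grp[j])
      }
    }
    ## each connector bridges one matched cross-group seed pair; with no
    ## connector the groups are joined by one direct edge instead
    for (j in seq_along(connectors)) {
      addEdge(groupA[j], connectors[j])
      addEdge(connectors[j], groupB[j])
    }
    if (!length(connectors) && length(groupB))
      addEdge(groupA[1L], groupB[1L])
    for (s in seeds) addAnn(s, m$term)
    for (j in seq_along(connectors))
      addAnn(connectors[j], paste0(m$term, ":REL", j))
    truth[[m$term]] <- c(seeds, connectors)
  }

  ## annotation noise on unplanted nodes, from the background leaves
  set.seed(.substream(spec@seed, 2L))  # annotation substream
  noisy <- free[stats::runif(length(free)) < spec@noiseRate]
  if (length(noisy)) {
    terms <- sample(bg$leaves, length(noisy), replace = TRUE)
    for (i in seq_along(noisy)) addAnn(noisy[i], terms[i])
  }

  ## nodes with no interaction are unusable; drop them
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  net <- new("InteractionNetwork", graph = igraph::simplify(g))
  corpus <- makeAnnotationCorpus(
    data.frame(protein = ann$protein, term = ann$term), dag)
  new("SyntheticFixture", network = net, dag = dag, corpus = corpus,
      groundTruth = truth, spec = spec)
}

#' Sample a query protein set from a planted module
#'
#' @param fixture a \code{\link{SyntheticFixture}}.
#' @param term a planted term of the fixture.
#' @param nMembers planted members to include (error when more than
#'   planted).
#' @param nDecoys proteins sampled uniformly from network nodes outside the
#'   planted member set.
#' @param seed query random seed.
#' @return Character vector of protein identifiers.
#' @export
generateQuery <- function(fixture, term, nMembers, nDecoys = 0L, seed = 1) {
  members <- fixture@groundTruth[[term]]
  if (is.null(members)) stop("term ", term, " was not planted")
  if (nMembers > length(members))
    stop("requested ", nMembers, " members but only ", length(members),
         " planted")
  set.seed(.substream(seed, 3L))  # query substream
  picked <- if (nMembers > 0L) sample(members, nMembers) else character()
  pool <- setdiff(networkNodes(fixture@network), members)
  decoys <- if (nDecoys > 0L) sample(pool, nDecoys) else character()
  c(picked, decoys)
}

#' Write an ontology DAG as an OBO 1.2 file
#'
#' @param dag an \code{\link{OntologyDag}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeObo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in sort(dag@terms)) {
    nm <- dag@termNames[t]
    out <- c(out, "[Term]", paste0("id: ", t),
             if (!is.na(nm)) paste0("name: ", nm),
             if (length(dag@parents[[t]]))
               paste0("is_a: ", sort(dag@parents[[t]])), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize a fixture in the formats the pipeline reads
#'
#' Writes \code{network.tsv} (generic edge list), \code{ontology.obo},
#' \code{annotations.tsv}, \code{groundtruth.json} and \code{spec.json}
#' into \code{dir}.
#'
#' @param fixture a \code{\link{SyntheticFixture}}.
#' @param dir output directory (created when missing).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeEdgeList(fixture@network, file.path(dir, "network.tsv"))
  writeObo(fixture@dag, file.path(dir, "ontology.obo"))
  direct <- fixture@corpus@direct
  prot <- rep(names(direct), lengths(direct))
  term <- unlist(direct, use.names = FALSE)
  o <- order(prot, term)
  utils::write.table(data.frame(prot[o], term[o]),
                     file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(fixture@groundTruth,
                       file.path(dir, "groundtruth.json"), digits = NA,
                       pretty = TRUE)
  s <- fixture@spec
  jsonlite::write_json(
    list(seed = s@seed, nNodes = s@nNodes, model = s@model,
         edgeProb = s@edgeProb, paEdges = s@paEdges,
         ontologyDepth = s@ontologyDepth, branching = s@branching,
         modules = s@modules, noiseRate = s@noiseRate),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Hand-built fixture demonstrating the added-value mechanism
#'
#' A deterministic network in which a two-protein query hits one module
#' exclusively through its connecting nodes. The connecting nodes carry
#' annotations semantically close to, but different from, the module's
#' reference term, so standard enrichment finds nothing while network
#' enrichment returns the reference term as a significant new term. The
#' network also carries five parallel decoy modules (to give the module
#' background realistic bulk), a star-shaped protein family whose module
#' is trivially rejected, and a ring of unannotated filler proteins.
#'
#' @return list with elements \code{network}, \code{dag}, \code{corpus},
#'   \code{query} (the two connecting proteins) and \code{term} (the
#'   reference term the query should recover).
#' @export
addedValueFixture <- function() {
  parents <- list(
    "T:ROOT" = character(),
    "T:Q" = "T:ROOT", "T:TARGET" = "T:Q", "T:S1" = "T:Q", "T:S2" = "T:Q",
    "T:U" = "T:ROOT")
  edges <- list()
  ann <- list()
  addEdge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  addAnn <- function(p, t) ann[[length(ann) + 1L]] <<- c(p, t)

  ## target module: seeds s1..s3, connectors c1 (T:S1), c2 (T:S2)
  addEdge("s1", "c1"); addEdge("c1", "s2")
  addEdge("s2", "c2"); addEdge("c2", "s3")
  addEdge("c1", "x1"); addEdge("c2", "x2")
  for (s in c("s1", "s2", "s3")) addAnn(s, "T:TARGET")
  addAnn("c1", "T:S1"); addAnn("x1", "T:S1")
  addAnn("c2", "T:S2"); addAnn("x2", "T:S2")

  ## five decoy modules: 5 seeds + 2 connectors each
  for (i in 1:5) {
    w <- sprintf("T:W%d", i); v0 <- sprintf("T:V%d", i)
    v1 <- sprintf("T:V%dC", i)
    parents[[w]] <- "T:ROOT"; parents[[v0]] <- w; parents[[v1]] <- w
    vs <- sprintf("v%d_%d", i, 1:5); ds <- sprintf("d%d_%d", i, 1:2)
    addEdge(vs[1], ds[1]); addEdge(ds[1], vs[2])
    addEdge(vs[2], ds[2]); addEdge(ds[2], vs[3])
    addEdge(vs[3], vs[4]); addEdge(vs[4], vs[5])
    for (v in vs) addAnn(v, v0)
    for (d in ds) addAnn(d, v1)
  }

  ## star family annotated with a common term; its module is trivial
  us <- sprintf("u%d", 1:5)
  for (u in us[-1L]) addEdge(us[1L], u)
  for (u in us) addAnn(u, "T:U")

  ## unannotated filler ring
  fs <- sprintf("f%02d", 1:60)
  for (i in seq_along(fs)) addEdge(fs[i], fs[i %% length(fs) + 1L])
  addEdge(fs[1L], us[1L])

  net <- makeInteractionNetwork(do.call(rbind, edges))
  dag <- makeOntologyDag(parents)
  corpus <- makeAnnotationCorpus(
    do.call(rbind, lapply(ann, function(x)
      data.frame(protein = x[1L], term = x[2L]))), dag)
  list(network = net, dag = dag, corpus = corpus,
       query = c("c1", "c2"), term = "T:TARGET")
}
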