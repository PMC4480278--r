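test_that("seed sets partition direct annotations into in-network and isolated", {
  net <- netFromEdges(c("p1", "p2"))
  corpus <- seedCorpus(c("p1", "p2"))
  ss <- buildSeedSet("TP", corpus, net)
  expect_setequal(ss@inNetwork, c("p1", "p2"))
  expect_equal(ss@isolated, character())

  corpus2 <- seedCorpus(c("p1", "p9"))
  ss2 <- buildSeedSet("TP", corpus2, net)
  expect_equal(ss2@isolated, "p9")

  ## R is never directly annotated here
  expect_error(buildSeedSet("R", corpus, net), "no directly annotated")
})

test_that("SPN keeps exactly the nodes and edges on seed-pair shortest paths", {
  ## s-u-t and s-v-t have length 2; s-w-x-t has length 3 and is excluded
  net <- netFromEdges(c("s", "u"), c("u", "t"), c("s", "v"), c("v", "t"),
                      c("s", "w"), c("w", "x"), c("x", "t"))
  corpus <- seedCorpus(c("s", "t"))
  spn <- extractShortestPathNetwork(net, buildSeedSet("TP", corpus, net))
  expect_setequal(igraph::V(spn@graph)$name, c("s", "t", "u", "v"))
  expect_setequal(connectingNodes(spn), c("u", "v"))
  expect_equal(igraph::ecount(spn@graph), 4L)

  ## matches the explicit path-enumeration oracle
  expect_equal(spnAsSets(spn), oracleSpn(net, c("s", "t")))
})

test_that("degenerate SPNs: single seed, adjacent seeds, isolated seeds", {
  net <- netFromEdges(c("s", "t"), c("t", "z"))
  one <- new("SeedSet", term = "TP", inNetwork = "s", isolated = character())
  spn1 <- extractShortestPathNetwork(net, one)
  expect_equal(igraph::V(spn1@graph)$name, "s")
  expect_equal(connectingNodes(spn1), character())

  two <- new("SeedSet", term = "TP", inNetwork = c("s", "t"),
             isolated = "far")
  spn2 <- extractShortestPathNetwork(net, two)
  expect_setequal(igraph::V(spn2@graph)$name, c("s", "t"))
  expect_equal(igraph::ecount(spn2@graph), 1L)
  expect_true("far" %in% networkNodes(spn2))
})

test_that("SPN membership matches the oracle on random graphs", {
  for (seed in 1:30) {
    net <- randomNet(10, 0.25, seed)
    nodes <- networkNodes(net)
    set.seed(seed * 31L)
    seeds <- sample(nodes, sample(2:4, 1L))
    ss <- new("SeedSet", term = "TP", inNetwork = seeds,
              isolated = character())
    spn <- extractShortestPathNetwork(net, ss)
    expect_equal(spnAsSets(spn), oracleSpn(net, seeds),
                 info = paste("seed", seed))
  }
})

test_that("ranking scores: single path, star hub, ordering and tie-breaks", {
  net <- netFromEdges(c("s", "v"), c("v", "t"))
  corpus <- seedCorpus(c("s", "t"))
  spn <- extractShortestPathNetwork(net, buildSeedSet("TP", corpus, net))
  r <- rankConnectingNodes(spn, corpus)
  expect_equal(r$node, "v")
  expect_equal(r$sc, 1L)
  expect_equal(r$bc, 1)

  hub <- netFromEdges(c("s1", "h"), c("s2", "h"), c("s3", "h"))
  hc <- seedCorpus(c("s1", "s2", "s3"))
  spn2 <- extractShortestPathNetwork(hub, buildSeedSet("TP", hc, hub))
  r2 <- rankConnectingNodes(spn2, hc)
  expect_equal(r2$sc, 3L)
  expect_equal(r2$bc, 3)

  ## every connecting node of a valid SPN lies on at least one path
  for (seed in 1:10) {
    net <- randomNet(12, 0.2, seed)
    set.seed(seed)
    seeds <- sample(networkNodes(net), 3L)
    ss <- new("SeedSet", term = "TP", inNetwork = seeds,
              isolated = character())
    spn <- extractShortestPathNetwork(net, ss)
    if (!length(connectingNodes(spn))) next
    rr <- rankConnectingNodes(spn, seedCorpus(seeds))
    expect_true(all(rr$sc >= 1L))
    expect_true(all(rr$bc > 0))
    ## removal order is ascending in the lexicographic triple
    o <- order(rr$sc, rr$ss, rr$bc, rr$node)
    expect_equal(o, seq_len(nrow(rr)))
  }
})

test_that("minimization removes the tied diamond node deterministically", {
  net <- netFromEdges(c("s", "u"), c("u", "t"), c("s", "v"), c("v", "t"))
  corpus <- seedCorpus(c("s", "t"))
  spn <- extractShortestPathNetwork(net, buildSeedSet("TP", corpus, net))
  mod <- minimizeNetwork(spn, rankConnectingNodes(spn, corpus))
  ## u and v tie on (sc, ss, bc); u is processed first and removed
  expect_equal(connectingNodes(mod), "v")
  expect_equal(length(moduleMembers(mod)), 3L)
  expect_true(preservesSeedDistances(mod, net))
})

test_that("nodes on a unique path are never removed", {
  net <- netFromEdges(c("s", "a"), c("a", "b"), c("b", "t"))
  corpus <- seedCorpus(c("s", "t"))
  spn <- extractShortestPathNetwork(net, buildSeedSet("TP", corpus, net))
  mod <- minimizeNetwork(spn, rankConnectingNodes(spn, corpus))
  expect_setequal(connectingNodes(mod), c("a", "b"))
  ## and an empty ranking leaves the SPN unchanged
  net2 <- netFromEdges(c("s", "t"))
  spn2 <- extractShortestPathNetwork(net2, buildSeedSet(
    "TP", seedCorpus(c("s", "t")), net2))
  mod2 <- minimizeNetwork(spn2, rankConnectingNodes(spn2, corpus))
  expect_equal(connectingNodes(mod2), character())
  expect_equal(nrow(networkEdges(mod2)), 1L)
})

test_that("quality filter rejects trivial modules and accepts clear signal", {
  mkModule <- function(conn) new("FunctionModule", term = "TP",
    seeds = c("s1", "s2"), connecting = conn, isolatedSeeds = character(),
    edges = matrix(character(), 0, 2), qualityP = NA_real_,
    passedTtest = NA, hasConnectingNodes = length(conn) > 0)
  net <- randomNet(40, 0.1, seed = 5)
  nodes <- networkNodes(net)

  expect_equal(qualityFilter(mkModule(character()), NULL, net,
                             ssAll = NULL)$reason, "no-connecting-nodes")
  set.seed(9)
  ssAll <- setNames(pmin(1, abs(rnorm(length(nodes), 0.1, 0.1))), nodes)
  expect_equal(qualityFilter(mkModule(nodes[1]), NULL, net,
                             ssAll = ssAll)$reason,
               "single-connecting-node")

  ## connecting nodes far above the network mean are accepted
  conn <- nodes[1:4]
  ssAll[conn] <- 1
  dec <- qualityFilter(mkModule(conn), NULL, net, ssAll = ssAll)
  expect_true(dec$accepted)
  expect_lt(dec$p, 1e-6)
})

test_that("quality t-test controls false acceptance near alpha", {
  set.seed(2024)
  net <- randomNet(300, 0.02, seed = 77)
  nodes <- networkNodes(net)
  accepted <- 0L
  for (rep in 1:200) {
    ## connecting scores drawn from the same distribution as the network
    ssAll <- setNames(pmin(1, abs(rnorm(length(nodes), 0.1, 0.15))), nodes)
    conn <- sample(nodes, 30L)
    mod <- new("FunctionModule", term = "TP", seeds = c("s1", "s2"),
               connecting = conn, isolatedSeeds = character(),
               edges = matrix(character(), 0, 2), qualityP = NA_real_,
               passedTtest = NA, hasConnectingNodes = TRUE)
    if (qualityFilter(mod, NULL, net, ssAll = ssAll)$accepted)
      accepted <- accepted + 1L
  }
  ## null acceptance should track alpha: rejected in >= 90% of replicates
  expect_lte(accepted, 20L)
})

## hand fixture: one genuine module + two terms that cannot yield one
handFixture <- function() {
  dag <- makeOntologyDag(list(
    R = character(), P = "R", TP = "P", REL1 = "P", REL2 = "P",
    TU = "R", TW = "R"))
  edges <- list(
    c("a1", "a2"), c("a3", "a4"),              # two seed cliques
    c("a1", "c1"), c("c1", "a3"),              # bridge 1
    c("a2", "c2"), c("c2", "a4"),              # bridge 2
    c("u1", "u2"), c("u1", "u3"), c("u1", "u4"),  # star family
    c("w1", "w2"))                             # adjacent pair
  ring <- sprintf("f%02d", 1:20)
  for (i in seq_along(ring))
    edges[[length(edges) + 1L]] <- c(ring[i], ring[i %% 20 + 1L])
  edges[[length(edges) + 1L]] <- c("f01", "u1")
  net <- makeInteractionNetwork(do.call(rbind, edges))
  ann <- rbind(
    data.frame(protein = c("a1", "a2", "a3", "a4"), term = "TP"),
    data.frame(protein = "c1", term = "REL1"),
    data.frame(protein = "c2", term = "REL2"),
    data.frame(protein = c("u1", "u2", "u3", "u4"), term = "TU"),
    data.frame(protein = c("w1", "w2"), term = "TW"))
  list(net = net, corpus = makeAnnotationCorpus(ann, dag))
}

test_that("buildAllModules accepts the genuine module and explains the rest", {
  fx <- handFixture()
  ms <- buildAllModules(fx$net, fx$corpus)
  expect_equal(termIds(ms), "TP")
  mod <- moduleList(ms)[["TP"]]
  expect_setequal(moduleMembers(mod), c("a1", "a2", "a3", "a4", "c1", "c2"))
  rep <- buildReport(ms)
  expect_equal(rep$outcome[rep$term == "TU"], "no-connecting-nodes")
  expect_equal(rep$outcome[rep$term == "TW"], "no-connecting-nodes")
  expect_equal(rep$outcome[rep$term %in% c("REL1", "REL2")],
               rep("too-few-seeds", 2L))
  expect_true(preservesSeedDistances(mod, fx$net))
})

test_that("module archives round-trip and are byte-identical across runs", {
  fx <- handFixture()
  ms1 <- buildAllModules(fx$net, fx$corpus)
  ms2 <- buildAllModules(fx$net, fx$corpus)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeModules(ms1, f1); writeModules(ms2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- readModules(f1)
  expect_equal(termIds(back), termIds(ms1))
  expect_setequal(moduleMembers(moduleList(back)[["TP"]]),
                  moduleMembers(moduleList(ms1)[["TP"]]))
  expect_equal(buildReport(back)$outcome, buildReport(ms1)$outcome)

  ## per-term edge-list export loads back as a graph over module members
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportModuleEdges(moduleList(ms1)[["TP"]], tsv)
  asNet <- loadEdgeList(tsv)
  expect_true(all(networkNodes(asNet) %in%
                  moduleMembers(moduleList(ms1)[["TP"]])))
})

test_that("modules shrink monotonically from SPN to minimal network", {
  fx <- generateFixture(fixtureSpec(seed = 9))
  rep <- buildReport(buildAllModules(fx@network, fx@corpus))
  done <- rep[!is.na(rep$spn_nodes), ]
  expect_true(all(done$module_nodes <= done$spn_nodes))
  ## inflation: module/seed ratio never exceeds SPN/seed ratio
  expect_true(all(done$module_nodes / done$n_in_network <=
                  done$spn_nodes / done$n_in_network))
})
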