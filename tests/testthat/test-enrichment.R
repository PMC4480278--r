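test_that("Fisher upper tail reproduces the worked ratio and edge cases", {
  expect_equal(fisherUpperTail(20, 5, 4, 3), 155 / 4845, tolerance = 1e-12)
  expect_equal(fisherUpperTail(20, 5, 4, 0), 1)
  expect_equal(fisherUpperTail(7, 7, 7, 7), 1)
  expect_error(fisherUpperTail(10, 12, 3, 1), "invalid contingency")
  expect_error(fisherUpperTail(10, 5, 3, 4), "invalid contingency")
})

test_that("Fisher upper tail matches direct tail summation and is monotone", {
  set.seed(42)
  for (rep in 1:300) {
    N <- sample(2:60, 1L)
    K <- sample(0:N, 1L)
    n <- sample(0:N, 1L)
    k <- sample(0:min(K, n), 1L)
    expect_equal(fisherUpperTail(N, K, n, k), oracleHyperTail(N, K, n, k),
                 tolerance = 1e-10, info = paste(N, K, n, k))
  }
  ## increasing k never increases the tail probability
  ks <- 0:5
  p <- fisherUpperTail(30, 10, 5, ks)
  expect_true(all(diff(p) <= 0))
})

## corpus of 30 proteins: rare term TR annotates 3, common term TC 20
enrichCorpus <- function() {
  dag <- makeOntologyDag(list(R = character(), TR = "R", TC = "R"))
  ann <- rbind(
    data.frame(protein = sprintf("r%02d", 1:3), term = "TR"),
    data.frame(protein = sprintf("c%02d", 1:20), term = "TC"),
    data.frame(protein = sprintf("x%02d", 1:7), term = "R"))
  makeAnnotationCorpus(ann, dag)
}

test_that("standard enrichment finds the rare term with the oracle p-value", {
  corpus <- enrichCorpus()
  res <- standardEnrichment(sprintf("r%02d", 1:3), corpus)
  expect_equal(res$term_id[1L], "TR")
  row <- res[res$term_id == "TR", ]
  expect_equal(row$N, 30L)
  expect_equal(row$K, 3L)
  expect_equal(row$k, 3L)
  expect_equal(row$p_raw, oracleHyperTail(30, 3, 3, 3), tolerance = 1e-12)
  ## Bonferroni over the tested terms (TR and R here)
  expect_equal(row$p_bonferroni, min(1, 2 * row$p_raw))
  expect_false(any(res$is_new_term))
})

test_that("standard enrichment degenerate inputs behave", {
  corpus <- enrichCorpus()
  expect_warning(res <- standardEnrichment("nobody", corpus), "no input")
  expect_equal(nrow(res), 0L)
  ## the whole universe saturates every test
  all <- names(corpus@propagated)
  res2 <- standardEnrichment(all, corpus)
  expect_equal(nrow(res2), 0L)
})

test_that("bonferroni universe mode multiplies by all background terms", {
  corpus <- enrichCorpus()
  a <- standardEnrichment(sprintf("r%02d", 1:3), corpus,
                          bonferroni = "tested")
  b <- standardEnrichment(sprintf("r%02d", 1:3), corpus,
                          bonferroni = "universe")
  rowA <- a[a$term_id == "TR", ]; rowB <- b[b$term_id == "TR", ]
  expect_equal(rowA$p_raw, rowB$p_raw)
  ## 3 terms have annotations (R, TR, TC) vs 2 tested
  expect_equal(rowB$p_bonferroni, min(1, 3 * rowB$p_raw))
  expect_gte(rowB$p_bonferroni, rowA$p_bonferroni)
})

test_that("network enrichment recovers the planted module term", {
  fx <- generateFixture(fixtureSpec(seed = 31))
  ms <- suppressMessages(buildAllModules(fx@network, fx@corpus))
  q <- generateQuery(fx, "T:PLANTED1", 5, seed = 31)
  ne <- suppressMessages(networkEnrichment(q, ms, fx@corpus))
  expect_equal(ne$term_id[1L], "T:PLANTED1")
  expect_equal(ne$mode[1L], "network")
  ## seeds in the query carry the term: not a novel annotation
  expect_false(ne$is_new_term[ne$term_id == "T:PLANTED1"])

  expect_warning(none <- networkEnrichment("zz", ms, fx@corpus),
                 "no input protein")
  expect_equal(nrow(none), 0L)
})

test_that("terms reached only through connecting nodes are flagged new", {
  fx <- addedValueFixture()
  ms <- suppressMessages(buildAllModules(fx$network, fx$corpus))
  ne <- suppressMessages(networkEnrichment(fx$query, ms, fx$corpus))
  expect_true(fx$term %in% ne$term_id)
  expect_true(ne$is_new_term[ne$term_id == fx$term])
})

test_that("ancestor deduplication keeps the most specific terms", {
  dag <- makeOntologyDag(list(R = character(), A = "R", B = "R"))
  res <- data.frame(term_id = c("A", "R"), term_name = "", mode = "standard",
                    N = 10L, K = 2L, n = 2L, k = 2L, p_raw = 0.01,
                    p_bonferroni = 0.02, is_new_term = FALSE,
                    member_ids = "p1,p2", stringsAsFactors = FALSE)
  dd <- deduplicateAncestors(res, dag)
  expect_equal(dd$term_id, "A")
  ## disjoint terms are untouched
  res2 <- res; res2$term_id <- c("A", "B")
  expect_equal(deduplicateAncestors(res2, dag)$term_id, c("A", "B"))
  ## comparison mode: drop terms ancestral to the reference list
  ref <- res[res$term_id == "A", ]
  onlyR <- res[res$term_id == "R", ]
  expect_equal(nrow(deduplicateAncestors(onlyR, dag, referenceSet = ref)), 0L)
})

test_that("comparison classes follow the precedence rule", {
  fx <- addedValueFixture()
  corpus <- fx$corpus; dag <- fx$dag
  empty <- netenrich:::.emptyEnrichment()
  expect_equal(classifyComparison(empty, empty, fx$query, corpus),
               "none_significant")

  ms <- suppressMessages(buildAllModules(fx$network, fx$corpus))
  se <- suppressMessages(standardEnrichment(fx$query, corpus))
  ne <- suppressMessages(networkEnrichment(fx$query, ms, corpus))
  expect_equal(classifyComparison(se, ne, fx$query, corpus),
               "net_new_terms")

  ## identical lists add nothing
  expect_equal(classifyComparison(ne, ne, fx$query, corpus), "same_terms")

  ## adding only an ancestor of a standard term is filtered to same_terms
  seA <- data.frame(term_id = "T:TARGET", term_name = "", mode = "standard",
                    N = 10L, K = 2L, n = 2L, k = 2L, p_raw = 0.01,
                    p_bonferroni = 0.02, is_new_term = FALSE,
                    member_ids = "", stringsAsFactors = FALSE)
  neR <- seA; neR$term_id <- "T:Q"; neR$mode <- "network"
  expect_equal(classifyComparison(seA, rbind(seA, neR), c("s1", "s2"),
                                  corpus), "same_terms")

  ## a known (annotated) extra term classes as net_more_known_terms
  neK <- seA; neK$term_id <- "T:S1"; neK$mode <- "network"
  expect_equal(classifyComparison(seA, rbind(seA, neK), c("c1", "x1"),
                                  corpus), "net_more_known_terms")
})

test_that("type-I error of the whole pipeline is controlled on random input", {
  fx <- generateFixture(fixtureSpec(seed = 55))
  ms <- suppressMessages(buildAllModules(fx@network, fx@corpus))
  universe <- unique(unlist(lapply(moduleList(ms), moduleMembers)))
  hits <- 0L
  set.seed(56)
  for (rep in 1:100) {
    q <- sample(universe, 4L)
    ne <- suppressWarnings(suppressMessages(
      networkEnrichment(q, ms, fx@corpus)))
    if (nrow(ne)) hits <- hits + 1L
  }
  expect_lte(hits / 100, 0.1)
})
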