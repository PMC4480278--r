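## One-shot module construction over every term of the corpus.

#' Build minimal connecting modules for every directly annotated term
#'
#' Runs the full construction (seed set, shortest path network, ranked
#' greedy minimization, quality filter) for each term with at least one
#' directly annotated protein. Terms with fewer than two in-network seeds
#' yield no seed pair, hence no connecting node, and are reported as
#' \code{too-few-seeds}; modules without connecting nodes and modules
#' failing the quality t-test are likewise reported but excluded from the
#' accepted set. Per-term failures are never fatal.
#'
#' @param net an \code{\link{InteractionNetwork}}.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param idmap optional named character vector (network id to annotation
#'   id), applied to the network before construction.
#' @param alpha significance level for the quality filter (default 0.05).
#' @return A \code{\link{ModuleSet}}: accepted modules plus a per-term
#'   report with seed counts, SPN and module sizes and quality p-values.
#' @export
buildAllModules <- function(net, corpus, idmap = NULL, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  net <- applyIdMap(net, idmap)
  terms <- sort(names(corpus@perTermDirect))
  rows <- vector("list", length(terms))
  modules <- list()
  for (ti in seq_along(terms)) {
    term <- terms[ti]
    seeds <- buildSeedSet(term, corpus, net)
    row <- data.frame(term = term, outcome = NA_character_,
                      n_seeds = length(seedProteins(seeds)),
                      n_in_network = length(seeds@inNetwork),
                      spn_nodes = NA_integer_, module_nodes = NA_integer_,
                      quality_p = NA_real_, stringsAsFactors = FALSE)
    if (length(seeds@inNetwork) < 2L) {
      row$outcome <- "too-few-seeds"
      rows[[ti]] <- row
      next
    }
    spn <- extractShortestPathNetwork(net, seeds)
    row$spn_nodes <- igraph::vcount(spn@graph)
    ranking <- rankConnectingNodes(spn, corpus)
    module <- minimizeNetwork(spn, ranking)
    row$module_nodes <- length(module@seeds) + length(module@connecting)
    decision <- qualityFilter(module, corpus, net, alpha = alpha)
    row$quality_p <- decision$p
    row$outcome <- decision$reason
    if (decision$accepted) {
      row$outcome <- "built"
      modules[[term]] <- setQualityFlags(module, decision)
    }
    rows[[ti]] <- row
  }
  report <- do.call(rbind, rows)
  if (is.null(report))
    report <- data.frame(term = character(), outcome = character(),
                         n_seeds = integer(), n_in_network = integer(),
                         spn_nodes = integer(), module_nodes = integer(),
                         quality_p = numeric())
  new("ModuleSet", modules = modules, report = report, alpha = alpha,
      metadata = list(
        tool = "netenrich",
        version = as.character(utils::packageVersion("netenrich")),
        alpha = alpha,
        n_terms_attempted = nrow(report),
        n_modules = length(modules)))
}
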