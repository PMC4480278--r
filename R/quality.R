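## Quality filtering of minimal connecting modules.

#' Quality-filter a minimal connecting module
#'
#' A module is rejected outright when it has no connecting node, and also
#' when it has exactly one (the group variance needed by the test is then
#' undefined). Otherwise it is accepted iff a one-sided Welch two-sample
#' t-test finds the mean maximum semantic similarity of its connecting
#' nodes to the reference term significantly \emph{higher} than the mean
#' over all network nodes, at level \code{alpha}. This discards modules
#' whose connecting nodes are functionally unrelated to the reference term
#' (typically long chains through generic hubs).
#'
#' @param module a \code{\link{FunctionModule}}.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param net the full \code{\link{InteractionNetwork}}.
#' @param alpha significance level (default 0.05).
#' @param reference the reference term; defaults to the module's term.
#' @param ssAll optional precomputed named vector of
#'   \code{\link{maxSemanticSimilarity}} for all network nodes against the
#'   reference term (computed when missing).
#' @return list with elements \code{accepted} (logical), \code{p}
#'   (t-test p-value or \code{NA}) and \code{reason} (\code{"accepted"},
#'   \code{"rejected-by-ttest"}, \code{"single-connecting-node"} or
#'   \code{"no-connecting-nodes"}).
#' @export
qualityFilter <- function(module, corpus, net, alpha = 0.05,
                          reference = referenceTerm(module),
                          ssAll = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  conn <- module@connecting
  if (!length(conn))
    return(list(accepted = FALSE, p = NA_real_,
                reason = "no-connecting-nodes"))
  if (length(conn) == 1L)
    return(list(accepted = FALSE, p = NA_real_,
                reason = "single-connecting-node"))
  if (is.null(ssAll))
    ssAll <- semanticSimilarityProfile(networkNodes(net), reference, corpus)
  ssConn <- ssAll[conn]
  p <- tryCatch(
    stats::t.test(ssConn, ssAll, alternative = "greater")$p.value,
    error = function(e) NA_real_)  # both groups constant -> undecidable
  accepted <- !is.na(p) && p <= alpha
  list(accepted = accepted, p = p,
       reason = if (accepted) "accepted" else "rejected-by-ttest")
}

#' Attach quality-filter results to a module
#'
#' @param module a \code{\link{FunctionModule}}.
#' @param decision the list returned by \code{\link{qualityFilter}}.
#' @return The module with \code{qualityP} and \code{passedTtest} set.
#' @export
setQualityFlags <- function(module, decision) {
  module@qualityP <- decision$p
  module@passedTtest <- isTRUE(decision$accepted)
  module
}
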