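## Standard-vs-network outcome classification.

#' Classify the standard vs network enrichment outcome for one input set
#'
#' Assigns one of four mutually exclusive classes by precedence:
#' \enumerate{
#'   \item \code{none_significant} — both result lists empty;
#'   \item \code{net_new_terms} — the network analysis adds at least one
#'     term (surviving ancestor-deduplication against the standard results)
#'     that occurs in the propagated annotations of no input protein;
#'   \item \code{net_more_known_terms} — the network analysis adds at least
#'     one surviving term that input proteins do carry;
#'   \item \code{same_terms} — otherwise.
#' }
#' Terms the network analysis adds that are ancestors of standard-enriched
#' terms are filtered away before classification, so they never count as
#' additions.
#'
#' @param se standard-enrichment data.frame.
#' @param ne network-enrichment data.frame (same input set).
#' @param input the input protein identifiers.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param dag an \code{\link{OntologyDag}}; defaults to the corpus DAG.
#' @return A single character string, one of the four class labels.
#' @export
classifyComparison <- function(se, ne, input, corpus, dag = corpus@dag) {
  if (!nrow(se) && !nrow(ne)) return("none_significant")
  added <- ne[!(ne$term_id %in% se$term_id), , drop = FALSE]
  added <- deduplicateAncestors(added, dag, referenceSet = se)
  if (!nrow(added)) return("same_terms")
  inputTerms <- unique(unlist(corpus@propagated[intersect(
    unique(input), names(corpus@propagated))], use.names = FALSE))
  if (any(!(added$term_id %in% inputTerms))) return("net_new_terms")
  "net_more_known_terms"
}
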