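## Information content and Lin semantic similarity over the annotation DAG.

#' Information content of a term
#'
#' \code{IC(t) = -log(|proteins annotated with t| / |annotated proteins|)}
#' with natural logarithm, counting proteins through propagated
#' (ancestor-closed) annotations. Terms annotating no protein have undefined
#' information content and raise an error (use \code{\link{hasDefinedIc}}
#' to probe).
#'
#' @param term a term identifier.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @return Non-negative numeric; 0 exactly for terms annotating every
#'   protein in the corpus.
#' @export
informationContent <- function(term, corpus) {
  term <- resolveTermId(corpus@dag, term)
  n <- length(corpus@perTerm[[term]])
  if (n == 0L)
    stop("term ", term, " annotates no protein: information content undefined")
  -log(n / length(corpus@propagated))
}

#' Does a term have defined information content?
#'
#' @param term a term identifier (unknown ids give \code{FALSE}).
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @return \code{TRUE} when the term annotates at least one protein.
#' @export
hasDefinedIc <- function(term, corpus) {
  term <- tryCatch(resolveTermId(corpus@dag, term), error = function(e) NA)
  !is.na(term) && length(corpus@perTerm[[term]]) > 0L
}

#' Lin semantic similarity between two terms
#'
#' \code{sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))} where MICA is the
#' common ancestor of maximal information content, the compared terms
#' themselves included. Terms with no common ancestor (disjoint roots) or a
#' zero IC denominator score 0.
#'
#' @param t1,t2 term identifiers with defined information content.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @return Numeric in \code{[0, 1]}; symmetric in its term arguments.
#' @export
linSimilarity <- function(t1, t2, corpus) {
  dag <- corpus@dag
  t1 <- resolveTermId(dag, t1); t2 <- resolveTermId(dag, t2)
  ic1 <- informationContent(t1, corpus)
  ic2 <- informationContent(t2, corpus)
  if (ic1 + ic2 == 0) return(0)
  common <- intersect(dag@ancestors[[t1]], dag@ancestors[[t2]])
  common <- common[vapply(common, hasDefinedIc, logical(1), corpus = corpus)]
  if (!length(common)) {
    message("terms ", t1, " and ", t2, " share no common ancestor; sim = 0")
    return(0)
  }
  icMica <- max(vapply(common, informationContent, 0, corpus = corpus))
  2 * icMica / (ic1 + ic2)
}

#' Maximum semantic similarity of a protein to a reference term
#'
#' The highest Lin similarity between any of the protein's direct
#' annotation terms and the reference term. Unannotated proteins (and
#' proteins whose terms all lack defined IC) score 0, so that unannotated
#' connecting nodes remain rankable.
#'
#' @param protein a protein identifier.
#' @param reference a term identifier with defined information content.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @return Numeric in \code{[0, 1]}.
#' @export
maxSemanticSimilarity <- function(protein, reference, corpus) {
  terms <- proteinTerms(corpus, protein, direct = TRUE)
  terms <- terms[vapply(terms, hasDefinedIc, logical(1), corpus = corpus)]
  if (!length(terms)) return(0)
  max(vapply(terms, linSimilarity, 0, t2 = reference, corpus = corpus))
}

#' Maximum semantic similarity of many proteins to one reference term
#'
#' Vectorized form of \code{\link{maxSemanticSimilarity}} that computes each
#' distinct term's Lin similarity to the reference once; used to score every
#' network node during quality filtering.
#'
#' @param proteins character vector of protein identifiers.
#' @param reference a term identifier with defined information content.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @return Named numeric vector in \code{[0, 1]}, one entry per protein.
#' @export
semanticSimilarityProfile <- function(proteins, reference, corpus) {
  allTerms <- unique(unlist(corpus@direct[proteins], use.names = FALSE))
  allTerms <- allTerms[vapply(allTerms, hasDefinedIc, logical(1),
                              corpus = corpus)]
  simByTerm <- vapply(allTerms, linSimilarity, 0, t2 = reference,
                      corpus = corpus)
  names(simByTerm) <- allTerms
  vapply(setNames(nm = proteins), function(p) {
    ts <- intersect(proteinTerms(corpus, p, direct = TRUE), allTerms)
    if (!length(ts)) 0 else max(simByTerm[ts])
  }, 0)
}
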