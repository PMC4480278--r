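## Standard (annotation-based) and network (module-based) enrichment.

.emptyEnrichment <- function() {
  data.frame(term_id = character(), term_name = character(),
             mode = character(), N = integer(), K = integer(),
             n = integer(), k = integer(), p_raw = numeric(),
             p_bonferroni = numeric(), is_new_term = logical(),
             member_ids = character(), stringsAsFactors = FALSE)
}

## shared Fisher-test + Bonferroni machinery over a term -> member-set map
.enrichAgainst <- function(input, membership, universe, mode, dag,
                           newTermFlag, alpha, bonferroni) {
  input <- unique(input)
  inUniverse <- intersect(input, universe)
  nDropped <- length(input) - length(inUniverse)
  if (nDropped > 0L)
    message(nDropped, " input protein(s) outside the ", mode,
            " background dropped")
  if (!length(inUniverse)) {
    warning("no input protein in the ", mode, " background")
    return(.emptyEnrichment())
  }
  N <- length(universe); n <- length(inUniverse)
  k <- vapply(membership, function(m) length(intersect(m, inUniverse)), 0L)
  tested <- names(membership)[k >= 1L]
  if (!length(tested)) {
    warning("no term overlaps the input set in ", mode, " mode")
    return(.emptyEnrichment())
  }
  m <- switch(bonferroni, tested = length(tested),
              universe = length(membership))
  K <- lengths(membership[tested])
  kk <- k[tested]
  pRaw <- fisherUpperTail(N, K, n, kk)
  pCor <- pmin(1, m * pRaw)
  termName <- dag@termNames[tested]
  termName[is.na(termName)] <- ""
  members <- vapply(tested, function(t)
    paste(sort(intersect(membership[[t]], inUniverse)), collapse = ","), "")
  out <- data.frame(term_id = tested, term_name = unname(termName),
                    mode = mode, N = N, K = unname(K), n = n,
                    k = unname(kk), p_raw = unname(pRaw),
                    p_bonferroni = unname(pCor),
                    is_new_term = unname(newTermFlag[tested]),
                    member_ids = unname(members), stringsAsFactors = FALSE)
  out <- out[out$p_bonferroni <= alpha, , drop = FALSE]
  out <- out[order(out$p_bonferroni, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard annotation-based enrichment
#'
#' One-sided Fisher overrepresentation test of the input proteins against
#' the propagated annotation sets, Bonferroni-corrected. The background
#' universe is every protein in the corpus with at least one annotation;
#' input proteins outside it are dropped from \code{n} (with a message).
#' Only terms overlapping the input (\code{k >= 1}) are tested; by default
#' Bonferroni multiplies by the number of tested terms, the
#' \code{"universe"} mode multiplies by all annotated terms instead.
#'
#' @param input character vector of protein identifiers.
#' @param corpus an \code{\link{AnnotationCorpus}}.
#' @param alpha significance level applied to corrected p-values.
#' @param bonferroni \code{"tested"} or \code{"universe"}.
#' @return data.frame of significant terms with columns \code{term_id},
#'   \code{term_name}, \code{mode}, \code{N}, \code{K}, \code{n}, \code{k},
#'   \code{p_raw}, \code{p_bonferroni}, \code{is_new_term},
#'   \code{member_ids}, sorted by corrected then raw p-value then term id.
#' @export
standardEnrichment <- function(input, corpus, alpha = 0.05,
                               bonferroni = c("tested", "universe")) {
  bonferroni <- match.arg(bonferroni)
  stopifnot(length(input) > 0L, alpha > 0, alpha < 1)
  universe <- names(corpus@propagated)
  ## standard enrichment can only ever return annotated terms
  flag <- setNames(rep(FALSE, length(corpus@perTerm)), names(corpus@perTerm))
  .enrichAgainst(input, corpus@perTerm, universe, "standard",
                 corpus@dag, flag, alpha, bonferroni)
}

#' Network module-based enrichment
#'
#' One-sided Fisher overrepresentation test of the input proteins against
#' module member sets. The background universe is the union of all module
#' members. A result is flagged \code{is_new_term} when the term occurs in
#' the propagated annotations of \emph{no} input protein — the added-value
#' terms that standard enrichment can never return.
#'
#' @param input character vector of protein identifiers.
#' @param modules a \code{\link{ModuleSet}} or a named list of
#'   \code{\link{FunctionModule}} objects.
#' @param corpus the \code{\link{AnnotationCorpus}} used to evaluate term
#'   novelty (and for term names).
#' @param alpha significance level applied to corrected p-values.
#' @param bonferroni \code{"tested"} or \code{"universe"}.
#' @return data.frame in the format of \code{\link{standardEnrichment}}.
#' @export
networkEnrichment <- function(input, modules, corpus, alpha = 0.05,
                              bonferroni = c("tested", "universe")) {
  bonferroni <- match.arg(bonferroni)
  if (is(modules, "ModuleSet")) modules <- modules@modules
  stopifnot(length(input) > 0L, alpha > 0, alpha < 1)
  if (!length(modules)) {
    warning("no modules: empty network enrichment")
    return(.emptyEnrichment())
  }
  membership <- lapply(modules, moduleMembers)
  universe <- unique(unlist(membership, use.names = FALSE))
  inputTerms <- unique(unlist(corpus@propagated[intersect(
    unique(input), names(corpus@propagated))], use.names = FALSE))
  flag <- setNames(!(names(membership) %in% inputTerms), names(membership))
  .enrichAgainst(input, membership, universe, "network",
                 corpus@dag, flag, alpha, bonferroni)
}

#' Remove enriched terms that are ancestors of other enriched terms
#'
#' Produces the non-redundant ranking: a result is dropped when its term is
#' a strict ancestor of a term present in \code{referenceSet} (comparison
#' mode, e.g. network results against standard results) or, when
#' \code{referenceSet} is \code{NULL}, of another term in \code{results}
#' itself (self mode, keeping the most specific term on each path). Order
#' is preserved.
#'
#' @param results an enrichment data.frame.
#' @param dag an \code{\link{OntologyDag}}.
#' @param referenceSet optional second enrichment data.frame.
#' @return The filtered data.frame.
#' @export
deduplicateAncestors <- function(results, dag, referenceSet = NULL) {
  if (!nrow(results)) return(results)
  refTerms <- if (is.null(referenceSet)) results$term_id
              else referenceSet$term_id
  ## strict ancestors of the reference terms
  anc <- unique(unlist(lapply(refTerms, function(t)
    setdiff(termAncestors(dag, t), t)), use.names = FALSE))
  out <- results[!(results$term_id %in% anc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an input protein set from a text file
#'
#' One identifier per line; \code{#} comments and blank lines ignored.
#'
#' @param path path to the file.
#' @return Character vector of identifiers.
#' @export
readProteinSet <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write enrichment results as TSV
#'
#' @param results an enrichment data.frame (possibly empty).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEnrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
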