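## Ontology construction and the OBO / annotation readers.

#' Resolve a (possibly alternative) term identifier to its primary id
#'
#' @param dag an \code{OntologyDag}.
#' @param term a primary term id or an \code{alt_id} alias.
#' @return The primary term identifier.
#' @export
resolveTermId <- function(dag, term) {
  stopifnot(is.character(term), length(term) == 1L)
  if (term %in% dag@terms) return(term)
  if (term %in% names(dag@aliases)) return(unname(dag@aliases[[term]]))
  stop("unknown term: ", term)
}

#' Build an OntologyDag from parent lists
#'
#' Low-level constructor used by \code{\link{loadObo}} and by the synthetic
#' fixture generator. Computes ancestor closures by topological traversal
#' and fails on cyclic parent relations.
#'
#' @param parents named list: term id to character vector of parent ids
#'   (empty vector for roots). Every term must appear as a name.
#' @param termNames optional named character of human-readable names.
#' @param aliases optional named character mapping alternative ids to
#'   primary ids.
#' @return An \code{\link{OntologyDag}}.
#' @export
makeOntologyDag <- function(parents, termNames = character(),
                            aliases = character()) {
  terms <- names(parents)
  if (is.null(terms) || any(terms == ""))
    stop("every term must be named in 'parents'")
  unknown <- setdiff(unique(unlist(parents)), terms)
  if (length(unknown))
    stop("parent terms not defined as terms: ", paste(unknown, collapse = ", "))

  ## topological order (parents before children); Kahn's algorithm
  remaining <- setNames(lengths(parents), terms)
  ancestors <- vector("list", length(terms)); names(ancestors) <- terms
  queue <- terms[remaining == 0L]
  children <- lapply(setNames(nm = terms), function(t) character())
  for (t in terms) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  done <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; done <- done + 1L
    ancestors[[t]] <- unique(c(t, unlist(ancestors[parents[[t]]],
                                         use.names = FALSE)))
    for (ch in children[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(terms))
    stop("cyclic term relations involving: ",
         paste(terms[remaining > 0L], collapse = ", "))

  new("OntologyDag",
      terms = terms, parents = parents, children = children,
      roots = terms[lengths(parents) == 0L], ancestors = ancestors,
      aliases = aliases, termNames = termNames)
}

#' Load an ontology from an OBO 1.2 file
#'
#' Parses \code{[Term]} stanzas; obsolete terms are excluded, \code{alt_id}
#' entries are recorded as aliases resolving to the primary id, and only
#' \code{is_a} and \code{part_of} relations are retained as parent edges
#' (\code{regulates}-type relations are ignored). Cyclic relations raise an
#' error.
#'
#' @param path path to an OBO 1.2 flat file.
#' @return An \code{\link{OntologyDag}}.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: T:0001",
#'              "name: root", "", "[Term]", "id: T:0002",
#'              "name: child", "is_a: T:0001 ! root"), obo)
#' dag <- loadObo(obo)
#' dagRoots(dag)
#' @export
loadObo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## stanza boundaries
  headers <- grep("^\\[", lines)
  termStarts <- headers[lines[headers] == "[Term]"]
  if (!length(termStarts)) stop("no [Term] stanzas in ", path)
  stanzaEnd <- function(start) {
    nxt <- headers[headers > start]
    if (length(nxt)) nxt[1L] - 1L else length(lines)
  }

  parents <- list(); termNames <- character(); aliases <- character()
  obsolete <- character()
  for (start in termStarts) {
    body <- lines[(start + 1L):stanzaEnd(start)]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    bad <- which(lengths(kv) != 3L)
    if (length(bad))
      stop("malformed OBO line ", start + bad[1L], ": ",
           body[bad[1L]])
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    id <- vals[keys == "id"]
    if (length(id) != 1L)
      stop("malformed [Term] stanza at line ", start, ": need exactly one id")
    if (any(keys == "is_obsolete" & grepl("^true", vals))) {
      obsolete <- c(obsolete, id)
      next
    }
    stripComment <- function(v) sub("\\s*!.*$", "", v)
    isa <- stripComment(vals[keys == "is_a"])
    rel <- vals[keys == "relationship"]
    partof <- sub("^part_of\\s+", "", stripComment(rel[grepl("^part_of\\s", rel)]))
    parents[[id]] <- unique(c(isa, partof))
    nm <- vals[keys == "name"]
    if (length(nm)) termNames[[id]] <- nm[1L]
    for (alt in vals[keys == "alt_id"]) aliases[[alt]] <- id
  }
  ## drop parent edges pointing at obsolete (excluded) terms
  parents <- lapply(parents, setdiff, y = obsolete)
  aliases <- aliases[!aliases %in% obsolete]
  makeOntologyDag(parents, termNames = termNames, aliases = aliases)
}

#' Build an AnnotationCorpus from direct protein-to-term annotations
#'
#' Computes the ancestor closure (propagated annotations) and the inverse
#' term-to-protein maps. Annotations to terms absent from the DAG are
#' dropped with a warning.
#'
#' @param direct named list or two-column data.frame/matrix
#'   (protein, term) of direct annotations.
#' @param dag an \code{\link{OntologyDag}}.
#' @return An \code{\link{AnnotationCorpus}}.
#' @export
makeAnnotationCorpus <- function(direct, dag) {
  if (is.data.frame(direct) || is.matrix(direct)) {
    direct <- split(as.character(direct[, 2L]), as.character(direct[, 1L]))
  }
  direct <- lapply(direct, unique)
  ## resolve aliases, drop unknown terms
  known <- c(dag@terms, names(dag@aliases))
  nDropped <- 0L
  direct <- lapply(direct, function(ts) {
    drop <- !(ts %in% known)
    nDropped <<- nDropped + sum(drop)
    ts <- ts[!drop]
    unique(vapply(ts, resolveTermId, "", dag = dag, USE.NAMES = FALSE))
  })
  if (nDropped > 0L)
    warning(nDropped, " annotation(s) to unknown terms dropped")
  direct <- direct[lengths(direct) > 0L]
  if (!length(direct)) stop("empty annotation corpus after filtering")

  propagated <- lapply(direct, function(ts)
    unique(unlist(dag@ancestors[ts], use.names = FALSE)))
  perTerm <- invertMembership(propagated)
  perTermDirect <- invertMembership(direct)
  new("AnnotationCorpus", dag = dag, direct = direct,
      propagated = propagated, perTerm = perTerm,
      perTermDirect = perTermDirect)
}

## invert a named list protein -> terms into term -> proteins
invertMembership <- function(x) {
  if (!length(x)) return(list())
  prot <- rep(names(x), lengths(x))
  term <- unlist(x, use.names = FALSE)
  lapply(split(prot, term), unique)
}

#' Load protein annotations from a GAF 2.x or two-column TSV file
#'
#' The format is detected from the content unless forced: GAF lines are
#' tab-separated with 15 or more columns (column 2 = protein id, column 4 =
#' qualifier, column 5 = term id; rows whose qualifier contains \code{NOT}
#' are dropped), the generic dialect is \code{protein<TAB>term} with
#' \code{#} comments. Annotations to terms not in \code{dag} are dropped
#' with a warning; an empty corpus after filtering is an error.
#'
#' @param path path to the annotation file.
#' @param dag an \code{\link{OntologyDag}}.
#' @param format \code{"auto"}, \code{"gaf"} or \code{"tsv"}.
#' @return An \code{\link{AnnotationCorpus}} with propagated annotations.
#' @export
loadAnnotations <- function(path, dag, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "!") & !startsWith(lines, "#")]
  if (!length(body)) stop("empty annotation corpus after filtering")
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (stats::median(lengths(fields)) >= 15L) "gaf" else "tsv"
  if (format == "gaf") {
    keep <- vapply(fields, function(f)
      length(f) >= 5L && !grepl("NOT", f[[4L]]), logical(1))
    fields <- fields[keep]
    if (!length(fields)) stop("empty annotation corpus after filtering")
    ann <- data.frame(protein = vapply(fields, `[[`, "", 2L),
                      term = vapply(fields, `[[`, "", 5L))
  } else {
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop("malformed annotation row ", bad[1L], ": ", body[bad[1L]])
    ann <- data.frame(protein = vapply(fields, `[[`, "", 1L),
                      term = vapply(fields, `[[`, "", 2L))
  }
  makeAnnotationCorpus(ann, dag)
}
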