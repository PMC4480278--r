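## JSON (de)serialization of module archives.

#' Write a ModuleSet to a JSON archive
#'
#' The archive holds, per term: seeds, retained connecting nodes, isolated
#' seeds, edges and quality statistics, plus build metadata. Serialization
#' is deterministic (sorted terms, sorted members, no timestamps), so two
#' runs on identical inputs produce byte-identical archives.
#'
#' @param moduleSet a \code{\link{ModuleSet}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeModules <- function(moduleSet, path) {
  mods <- moduleSet@modules[order(names(moduleSet@modules))]
  payload <- list(
    metadata = moduleSet@metadata,
    modules = lapply(mods, function(m) list(
      term = m@term,
      seeds = as.list(sort(m@seeds)),
      connecting = as.list(sort(m@connecting)),
      isolated_seeds = as.list(sort(m@isolatedSeeds)),
      edges = if (nrow(m@edges)) unname(apply(m@edges, 1L, as.list))
              else list(),
      quality_p = m@qualityP,
      passed_ttest = m@passedTtest)),
    report = moduleSet@report,
    alpha = moduleSet@alpha)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a ModuleSet back from a JSON archive
#'
#' @param path path to an archive written by \code{\link{writeModules}}.
#' @return A \code{\link{ModuleSet}}.
#' @export
readModules <- function(path) {
  payload <- jsonlite::read_json(path)
  asChr <- function(x) as.character(unlist(x, use.names = FALSE))
  mods <- lapply(payload$modules, function(m) {
    edges <- if (length(m$edges))
      do.call(rbind, lapply(m$edges, asChr))
    else matrix(character(), 0L, 2L)
    new("FunctionModule",
        term = m$term, seeds = asChr(m$seeds),
        connecting = asChr(m$connecting),
        isolatedSeeds = asChr(m$isolated_seeds), edges = edges,
        qualityP = if (is.null(m$quality_p)) NA_real_
                   else as.numeric(m$quality_p),
        passedTtest = isTRUE(m$passed_ttest),
        hasConnectingNodes = length(m$connecting) > 0L)
  })
  names(mods) <- vapply(mods, referenceTerm, "")
  rep <- payload$report
  report <- if (length(rep)) {
    do.call(rbind, lapply(rep, function(r)
      data.frame(term = r$term, outcome = r$outcome,
                 n_seeds = as.integer(r$n_seeds),
                 n_in_network = as.integer(r$n_in_network),
                 spn_nodes = if (is.null(r$spn_nodes)) NA_integer_
                             else as.integer(r$spn_nodes),
                 module_nodes = if (is.null(r$module_nodes)) NA_integer_
                                else as.integer(r$module_nodes),
                 quality_p = if (is.null(r$quality_p)) NA_real_
                             else as.numeric(r$quality_p),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(term = character(), outcome = character(),
               n_seeds = integer(), n_in_network = integer(),
               spn_nodes = integer(), module_nodes = integer(),
               quality_p = numeric())
  }
  new("ModuleSet", modules = mods, report = report,
      alpha = as.numeric(payload$alpha),
      metadata = lapply(payload$metadata, function(x) x))
}

#' Export one module as a two-column edge list
#'
#' Suitable for loading into graph viewers; isolated members are not
#' representable in an edge list and are omitted.
#'
#' @param module a \code{\link{FunctionModule}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
exportModuleEdges <- function(module, path) {
  utils::write.table(module@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
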