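#' @import methods
#' @importFrom stats cor quantile median qbeta rbinom rnorm runif rpois setNames
#' @importFrom utils head read.delim write.table
NULL

#' Gene Ontology DAG with precomputed depths and ancestor sets
#'
#' Holds the ontology as a directed acyclic graph of child-to-parent links,
#' one root per namespace, together with the longest-path depth of every term
#' and its full ancestor set.  Depth is the number of edges on the longest
#' path from the namespace root down to the term; roots have depth 0.  The
#' three namespaces (biological_process, molecular_function,
#' cellular_component) are treated equivalently for depth purposes.
#'
#' @slot termIds character vector of term identifiers.
#' @slot namespace named character, term -> namespace label.
#' @slot parents named list, term -> character vector of direct parents.
#' @slot roots named character, namespace -> root term id.
#' @slot depth named integer, term -> longest-path depth from its root.
#' @slot ancestors named list, term -> all ancestors (excluding the term).
#'
#' @seealso [loadOntology()], [termDepth()], [ancestralClosure()]
#' @export
setClass("OntologyGraph",
  representation(
    termIds   = "character",
    namespace = "character",
    parents   = "list",
    roots     = "character",
    depth     = "integer",
    ancestors = "list"
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  ids <- object@termIds
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated term ids")
  if (!all(names(object@parents) == ids)) msgs <- c(msgs, "parents misnamed")
  allpar <- unique(unlist(object@parents, use.names = FALSE))
  if (!all(allpar %in% ids)) msgs <- c(msgs, "parent reference outside graph")
  for (ns in names(object@roots)) {
    r <- object@roots[[ns]]
    if (!r %in% ids) msgs <- c(msgs, sprintf("root %s not a term", r))
    else if (object@depth[[r]] != 0L) msgs <- c(msgs, "root with nonzero depth")
  }
  cross <- vapply(ids, function(t) {
    p <- object@parents[[t]]
    length(p) > 0 && any(object@namespace[p] != object@namespace[[t]])
  }, logical(1))
  if (any(cross)) msgs <- c(msgs, "edge crosses namespaces")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(object@termIds), "terms,",
      sum(lengths(object@parents)), "edges\n")
  tab <- table(object@namespace)
  cat("  namespaces:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  max depth:", max(object@depth), "\n")
})

#' Protein-to-term annotation store with provenance
#'
#' Stores protein -> GO term assignments together with the source each
#' assignment came from, an optional confidence score, and a flag marking
#' assignments added by ancestral closure.  Once closed, every protein's term
#' set contains all ancestors of each member term.
#'
#' @slot assignments data.frame with columns protein_id, term_id, source,
#'   score (NA allowed) and via_closure (logical).
#' @slot closed logical; TRUE once the ancestral closure has been applied.
#'
#' @seealso [mergeAnnotationSources()], [closeStore()], [proteinTerms()]
#' @export
setClass("AnnotationStore",
  representation(assignments = "data.frame", closed = "logical")
)

setValidity("AnnotationStore", function(object) {
  need <- c("protein_id", "term_id", "source", "score", "via_closure")
  if (!all(need %in% names(object@assignments)))
    return(paste("assignments must have columns:", paste(need, collapse = ", ")))
  TRUE
})

setMethod("show", "AnnotationStore", function(object) {
  a <- object@assignments
  cat("AnnotationStore:", length(unique(a$protein_id)), "proteins,",
      length(unique(a$term_id)), "distinct terms,",
      nrow(a), "assignments",
      if (object@closed) "(ancestor-closed)\n" else "(not closed)\n")
})

#' Predicted-similarity hit network
#'
#' Simple undirected graph over proteins whose edges are pairs with a
#' predicted deepest-shared-GO-term depth above the hit cutoff.  Each edge
#' carries the pair's predicted depth and its full similarity feature vector,
#' which the term-transfer engine summarizes per candidate term.
#'
#' @slot nodes character vector of protein ids (the scoring universe).
#' @slot edges data.frame with columns protein_a, protein_b, predicted_depth
#'   and one column per pair feature.
#' @slot hitCutoff numeric, the strict lower bound on predicted depth.
#'
#' @seealso [predictHits()], [buildHitSets()], [asIgraph()]
#' @export
setClass("HitNetwork",
  representation(nodes = "character", edges = "data.frame",
                 hitCutoff = "numeric")
)

setValidity("HitNetwork", function(object) {
  e <- object@edges
  if (!all(c("protein_a", "protein_b", "predicted_depth") %in% names(e)))
    return("edges need protein_a, protein_b, predicted_depth")
  if (nrow(e)) {
    if (any(e$protein_a == e$protein_b)) return("self edge present")
    key <- paste(pmin(e$protein_a, e$protein_b), pmax(e$protein_a, e$protein_b))
    if (anyDuplicated(key)) return("duplicate edge")
    if (!all(c(e$protein_a, e$protein_b) %in% object@nodes))
      return("edge endpoint outside node set")
  }
  TRUE
})

setMethod("show", "HitNetwork", function(object) {
  cat("HitNetwork:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges (predicted depth >", object@hitCutoff, ")\n")
})

# ---- accessors -------------------------------------------------------------

#' Term identifiers of an ontology
#' @param object an OntologyGraph
#' @return character vector of term ids
#' @export
termIds <- function(object) object@termIds

#' Namespace label of each term
#' @param object an OntologyGraph
#' @return named character vector, term -> namespace
#' @export
termNamespace <- function(object) object@namespace

#' Namespace roots
#' @param object an OntologyGraph
#' @return named character vector, namespace -> root term id
#' @export
rootTerms <- function(object) object@roots

#' Protein ids present in an annotation store
#' @param store an AnnotationStore
#' @return character vector
#' @export
proteinIds <- function(store) unique(store@assignments$protein_id)

#' Terms assigned to one protein
#' @param store an AnnotationStore
#' @param protein protein id
#' @param direct_only if TRUE, drop assignments added by closure
#' @return character vector of term ids (empty if the protein is absent)
#' @export
proteinTerms <- function(store, protein, direct_only = FALSE) {
  a <- store@assignments
  sel <- a$protein_id == protein
  if (direct_only) sel <- sel & !a$via_closure
  unique(a$term_id[sel])
}

#' The assignment table of an annotation store
#' @param store an AnnotationStore
#' @return data.frame (protein_id, term_id, source, score, via_closure)
#' @export
annotationTable <- function(store) store@assignments

#' All protein -> term sets as a named list
#' @param store an AnnotationStore
#' @return named list, protein -> character vector of terms
#' @export
proteinTermSets <- function(store) {
  a <- store@assignments
  lapply(split(a$term_id, a$protein_id), unique)
}

#' Edge table of a hit network
#' @param network a HitNetwork
#' @return data.frame of edges with predicted depth and feature payload
#' @export
hitEdges <- function(network) network@edges

#' Node set of a hit network
#' @param network a HitNetwork
#' @return character vector of protein ids
#' @export
hitNodes <- function(network) network@nodes

#' Convert a HitNetwork to an igraph object
#' @param network a HitNetwork
#' @return an undirected igraph graph over all nodes (isolates retained)
#' @export
asIgraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network@nodes), name = network@nodes)
  if (nrow(network@edges))
    g <- igraph::add_edges(
      g, rbind(network@edges$protein_a, network@edges$protein_b))
  g
}
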