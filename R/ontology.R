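# Ontology parsing, depths, closures, PUF classification, source merging.

#' Construct an OntologyGraph from term and edge tables
#'
#' Internal constructor shared by the OBO loader and the synthetic generator.
#' Validates acyclicity, computes longest-path depths and ancestor sets once.
#'
#' @param term_ids character vector of term identifiers.
#' @param namespace named character, term -> namespace.
#' @param parent_list named list, term -> character vector of direct parents.
#' @return an [OntologyGraph-class] object.
#' @keywords internal
makeOntologyGraph <- function(term_ids, namespace, parent_list) {
  stopifnot(length(term_ids) > 0)
  parent_list <- parent_list[term_ids]
  names(parent_list) <- term_ids
  parent_list <- lapply(parent_list, function(p) if (is.null(p)) character() else p)

  allpar <- unique(unlist(parent_list, use.names = FALSE))
  bad <- setdiff(allpar, term_ids)
  if (length(bad))
    stop("unknown parent reference: ", paste(head(bad, 5), collapse = ", "))

  # parent -> child igraph; topological order puts parents before children
  edges <- do.call(rbind, lapply(term_ids, function(t) {
    p <- parent_list[[t]]
    if (length(p)) cbind(parent = p, child = t) else NULL
  }))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(term_ids), name = term_ids)
  if (!is.null(edges)) g <- igraph::add_edges(g, rbind(edges[, 1], edges[, 2]))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    off <- igraph::ends(g, cyc[1])[1, 1]
    stop("cycle detected in ontology involving term ", off)
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))

  roots <- term_ids[lengths(parent_list) == 0L]
  rns <- namespace[roots]
  if (anyDuplicated(rns))
    stop("multiple roots in namespace ", rns[duplicated(rns)][1])
  roots <- setNames(roots, rns)

  depth <- setNames(integer(length(term_ids)), term_ids)
  ancestors <- setNames(vector("list", length(term_ids)), term_ids)
  for (t in topo) {
    p <- parent_list[[t]]
    if (length(p) == 0L) {
      depth[[t]] <- 0L
      ancestors[[t]] <- character()
    } else {
      depth[[t]] <- 1L + max(depth[p])
      ancestors[[t]] <- unique(c(p, unlist(ancestors[p], use.names = FALSE)))
    }
  }

  new("OntologyGraph", termIds = term_ids, namespace = namespace[term_ids],
      parents = parent_list, roots = roots, depth = depth,
      ancestors = ancestors)
}

#' Load a Gene Ontology DAG from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, drops obsolete terms, and retains `is_a` edges
#' plus, by default, `part_of` relationships (the conventional true-path
#' propagation set).  Depths and ancestor sets are computed once at load.
#'
#' @param path path to an OBO 1.2 file, or a connection.
#' @param include_part_of logical; also keep `relationship: part_of` edges.
#' @return an [OntologyGraph-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:1", "namespace: biological_process", "",
#'              "[Term]", "id: T:2", "namespace: biological_process",
#'              "is_a: T:1"), obo)
#' g <- loadOntology(obo)
#' termDepth(g)
#' @export
loadOntology <- function(path, include_part_of = TRUE) {
  lines <- if (inherits(path, "connection")) readLines(path) else readLines(path)
  lines <- trimws(lines)

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found")

  ids <- character(); ns <- character(); parents <- list(); names_ <- character()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    getv <- function(key) {
      hits <- grep(paste0("^", key, ":"), block, value = TRUE)
      sub("\\s*!.*$", "", trimws(sub(paste0("^", key, ":"), "", hits)))
    }
    if (any(getv("is_obsolete") == "true")) next
    id <- getv("id")[1]
    if (is.na(id)) stop("[Term] stanza without id")
    par <- getv("is_a")
    if (include_part_of) {
      rel <- getv("relationship")
      po <- grep("^part_of\\s", rel, value = TRUE)
      par <- c(par, sub("^part_of\\s+", "", po))
    }
    ids <- c(ids, id)
    ns <- c(ns, if (length(getv("namespace"))) getv("namespace")[1] else NA_character_)
    nm <- getv("name")
    names_ <- c(names_, if (length(nm)) nm[1] else id)
    parents[[id]] <- unique(par)
  }
  if (anyDuplicated(ids)) stop("duplicate term id in OBO file")
  makeOntologyGraph(ids, setNames(ns, ids), parents)
}

#' Longest-path depth of every term
#'
#' Depth is the number of edges on the longest path from the namespace root
#' to the term: roots have depth 0 and `depth(t) = 1 + max(depth(parents))`.
#' Depths are memoized at load time, so this is a lookup.
#'
#' @param graph an [OntologyGraph-class].
#' @return named integer vector, term -> depth.
#' @export
termDepth <- function(graph) graph@depth

#' Ancestral closure of a term set
#'
#' Augments a set of terms with every parent term necessitated by the
#' ontology structure (the transitive closure under the parent relation).
#' Idempotent.
#'
#' @param graph an [OntologyGraph-class].
#' @param terms character vector of term ids.
#' @return character vector: the input plus all ancestors, deduplicated.
#' @export
ancestralClosure <- function(graph, terms) {
  if (!length(terms)) return(character())
  unknown <- setdiff(terms, graph@termIds)
  if (length(unknown))
    stop("unknown term: ", paste(head(unknown, 5), collapse = ", "))
  unique(c(terms, unlist(graph@ancestors[terms], use.names = FALSE)))
}

#' Depth of the deepest term shared by two annotation sets
#'
#' Both sets are ancestor-closed, intersected, and the maximum term depth of
#' the intersection returned.  Symmetric in its arguments.  A pair sharing
#' only namespace roots scores 0; an empty annotation set also scores 0
#' (nothing below the root is shared), with the `empty` attribute flagging
#' that case.
#'
#' @param graph an [OntologyGraph-class].
#' @param annots_a,annots_b character vectors of term ids.
#' @return integer depth, with attribute `empty` = TRUE when either input
#'   set was empty.
#' @export
deepestSharedDepth <- function(graph, annots_a, annots_b) {
  if (!length(annots_a) || !length(annots_b))
    return(structure(0L, empty = TRUE))
  shared <- intersect(ancestralClosure(graph, annots_a),
                      ancestralClosure(graph, annots_b))
  if (!length(shared)) return(0L)
  max(graph@depth[shared])
}

#' Classify a protein as PUF or PKF from its annotation depth
#'
#' A protein of unknown function (PUF) either has no annotation at all or is
#' annotated only to a depth of less than two, i.e. carries nothing more
#' informative than an ontology root or its immediate children.  Ancestral
#' closure cannot raise the maximum depth, so the rule is closure-invariant.
#'
#' @param graph an [OntologyGraph-class].
#' @param protein_terms character vector of the protein's term ids.
#' @param min_depth strict lower bound on max depth for PKF status (default 2).
#' @return `"PUF"` or `"PKF"`.
#' @export
classifyPuf <- function(graph, protein_terms, min_depth = 2L) {
  if (!length(protein_terms)) return("PUF")
  unknown <- setdiff(protein_terms, graph@termIds)
  if (length(unknown))
    stop("unknown term: ", paste(head(unknown, 5), collapse = ", "))
  if (max(graph@depth[protein_terms]) < min_depth) "PUF" else "PKF"
}

#' Build an AnnotationStore from raw assignment rows
#'
#' @param df data.frame with protein_id, term_id and optionally source,
#'   score, via_closure.
#' @param closed logical; whether the rows are already ancestor-closed.
#' @return an [AnnotationStore-class].
#' @export
newAnnotationStore <- function(df, closed = FALSE) {
  if (is.null(df$source)) df$source <- rep(NA_character_, nrow(df))
  if (is.null(df$score)) df$score <- rep(NA_real_, nrow(df))
  if (is.null(df$via_closure)) df$via_closure <- rep(FALSE, nrow(df))
  df <- df[, c("protein_id", "term_id", "source", "score", "via_closure")]
  rownames(df) <- NULL
  new("AnnotationStore", assignments = df, closed = closed)
}

#' Ancestor-close an annotation store
#'
#' Adds one `via_closure` assignment per (protein, missing ancestor), with
#' source `"closure"` and no score.  Idempotent.
#'
#' @param store an [AnnotationStore-class].
#' @param graph an [OntologyGraph-class].
#' @return a closed [AnnotationStore-class].
#' @export
closeStore <- function(store, graph) {
  a <- store@assignments
  sets <- lapply(split(a$term_id, a$protein_id), unique)
  extra <- lapply(names(sets), function(p) {
    anc <- setdiff(ancestralClosure(graph, sets[[p]]), sets[[p]])
    if (!length(anc)) return(NULL)
    data.frame(protein_id = p, term_id = anc, source = "closure",
               score = NA_real_, via_closure = TRUE)
  })
  extra <- do.call(rbind, extra)
  out <- if (is.null(extra)) a else rbind(a, extra)
  new("AnnotationStore", assignments = out, closed = TRUE)
}

#' Merge per-source annotation tables into one closed store
#'
#' Takes one table per source (columns protein_id, term_id, optional score),
#' drops score-bearing assignments not strictly above `netgo_cutoff`, drops
#' assignments to terms absent from the ontology with a warning, unions
#' across sources keeping per-source provenance, and ancestor-closes the
#' result.  Per-term source-intersection counts remain computable from the
#' provenance column.
#'
#' @param source_tables named list of data.frames.
#' @param graph an [OntologyGraph-class].
#' @param netgo_cutoff strict lower bound applied to non-missing scores
#'   (default 0.9).
#' @return a closed [AnnotationStore-class].
#' @export
mergeAnnotationSources <- function(source_tables, graph, netgo_cutoff = 0.9) {
  stopifnot(length(source_tables) > 0, !is.null(names(source_tables)))
  rows <- lapply(names(source_tables), function(src) {
    tb <- source_tables[[src]]
    score <- if (is.null(tb$score)) rep(NA_real_, nrow(tb)) else tb$score
    keep <- is.na(score) | score > netgo_cutoff
    tb <- tb[keep, , drop = FALSE]
    score <- score[keep]
    if (!nrow(tb)) return(NULL)
    data.frame(protein_id = tb$protein_id, term_id = tb$term_id,
               source = src, score = score, via_closure = FALSE)
  })
  merged <- do.call(rbind, rows)
  if (is.null(merged) || !nrow(merged)) stop("no assignments survive filtering")
  bad <- !(merged$term_id %in% graph@termIds)
  if (any(bad)) {
    warning(sum(bad), " assignment(s) dropped: term not in ontology (e.g. ",
            merged$term_id[bad][1], ")")
    merged <- merged[!bad, , drop = FALSE]
  }
  # one row per (protein, term, source); provenance = distinct source rows
  merged <- unique(merged)
  closeStore(newAnnotationStore(merged, closed = FALSE), graph)
}

#' Count per-term source support
#'
#' For each term, in how many distinct sources any direct (non-closure)
#' assignment of that term appears.
#'
#' @param store an [AnnotationStore-class].
#' @return named integer vector, term -> number of supporting sources.
#' @export
termSourceCounts <- function(store) {
  a <- store@assignments[!store@assignments$via_closure, ]
  vapply(split(a$source, a$term_id), function(s) length(unique(s)), integer(1))
}

#' Read an annotation table (TSV dialect)
#'
#' Expects columns protein_id, term_id and optionally source and score
#' (blank score allowed).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readAnnotationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "term_id") %in% names(df)))
  df
}

#' Write an AnnotationStore as TSV
#' @param store an [AnnotationStore-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeAnnotationStore <- function(store, path) {
  write.table(store@assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
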