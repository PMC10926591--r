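# Structural arm: TM-filtered structure-search hits, global-alignment and
# taxonomy predictors, hit sets for the shared transfer engine.

#' @useDynLib puffin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

aminoAlphabet <- function() c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                              "I", "L", "K", "M", "F", "P", "S", "T", "W",
                              "Y", "V", "X")

#' Filter structure-search hits by TM-score
#'
#' Retains hits with TM-score strictly greater than the cutoff and removes
#' self-hits.
#'
#' @param hits data.frame with at least query_id, hit_id, tm_score.
#' @param tm_cutoff strict lower bound (default 0.3).
#' @return the filtered data.frame.
#' @export
filterStructureHits <- function(hits, tm_cutoff = 0.3) {
  stopifnot(all(hits$tm_score >= 0 & hits$tm_score <= 1))
  hits[hits$tm_score > tm_cutoff & hits$query_id != hits$hit_id, ,
       drop = FALSE]
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Optimal global alignment under a substitution matrix and affine gap
#' penalties (a gap of length L costs `gap_open + (L-1) * gap_extend`).
#' Tie-breaking is deterministic: diagonal, then up, then left.  Percent
#' identity is identical aligned residue pairs over the alignment length;
#' percent non-gap is the fraction of columns with residues on both rows.
#'
#' @param seq_a,seq_b character strings over the 20 amino acids plus X.
#' @param substitution_matrix a named scoring matrix (default
#'   `Biostrings::BLOSUM62`).
#' @param gap_open,gap_extend positive gap penalties (defaults 11, 1).
#' @return list of class `AlignmentStats`: score, alignment_length,
#'   pct_identity, pct_nongap, aligned_a, aligned_b (gapped strings).
#' @examples
#' globalAlign("ACDE", "ACE")$pct_nongap
#' @export
globalAlign <- function(seq_a, seq_b, substitution_matrix = NULL,
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  if (is.null(substitution_matrix)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    substitution_matrix <- get("BLOSUM62", envir = environment())
  }
  alpha <- aminoAlphabet()
  toIdx <- function(s, nm) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- which(!(ch %in% alpha))
    if (length(bad))
      stop("character '", ch[bad[1]], "' at position ", bad[1],
           " of ", nm, " is outside the amino-acid alphabet")
    match(ch, rownames(substitution_matrix))
  }
  ia <- toIdx(seq_a, "seq_a"); ib <- toIdx(seq_b, "seq_b")
  res <- nw_align_cpp(ia, ib, substitution_matrix, gap_open, gap_extend)
  ca <- strsplit(toupper(seq_a), "")[[1]]
  cb <- strsplit(toupper(seq_b), "")[[1]]
  ga <- ifelse(res$pos_a == 0, "-", ca[pmax(res$pos_a, 1)])
  gb <- ifelse(res$pos_b == 0, "-", cb[pmax(res$pos_b, 1)])
  len <- length(ga)
  both <- res$pos_a > 0 & res$pos_b > 0
  ident <- sum(both & ga == gb)
  out <- list(score = res$score, alignment_length = len,
              pct_identity = 100 * ident / len,
              pct_nongap = 100 * sum(both) / len,
              aligned_a = paste(ga, collapse = ""),
              aligned_b = paste(gb, collapse = ""))
  class(out) <- "AlignmentStats"
  out
}

#' @export
print.AlignmentStats <- function(x, ...) {
  cat("Global alignment: score", x$score, " length", x$alignment_length, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  cat("  identity ", round(x$pct_identity, 1), "%, non-gap ",
      round(x$pct_nongap, 1), "%\n", sep = "")
  invisible(x)
}

#' Taxonomic ranks used for lineage comparison
#' @return character vector, most specific first.
#' @export
taxonomicRanks <- function() c("species", "genus", "family", "order",
                               "class", "phylum", "superkingdom")

#' Rank of the most specific shared taxonomic level
#'
#' Compares two lineages ordered most-specific-first (species, genus,
#' family, order, class, phylum, superkingdom) and returns the rank index
#' of the most specific level at which they agree: genus = 1, family = 2,
#' and so on up to superkingdom = 6.  Two lineages agreeing at the species
#' level score 0, and lineages sharing no level score 7 (one beyond
#' superkingdom).  Smaller is more similar.
#'
#' @param lineage_a,lineage_b character vectors of length 7 in the
#'   [taxonomicRanks()] order.
#' @return integer in 0..7.
#' @export
taxonomicRankSimilarity <- function(lineage_a, lineage_b) {
  k <- length(taxonomicRanks())
  if (length(lineage_a) != k || length(lineage_b) != k ||
      anyNA(lineage_a) || anyNA(lineage_b))
    stop("malformed lineage: expected ", k, " non-missing ranks (",
         paste(taxonomicRanks(), collapse = ", "), ")")
  same <- which(lineage_a == lineage_b)
  if (!length(same)) return(7L)
  min(same) - 1L
}

#' Read a structure-hit table
#'
#' TSV with columns query_id, hit_id, tm_score, rmsd, hit_sequence,
#' lineage (semicolon-joined, most specific first) and terms (pipe-joined
#' term ids; may be empty).
#'
#' @param path file path.
#' @return data.frame with list-columns `lineage` and `terms`.
#' @export
readStructureHits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "hit_id", "tm_score", "rmsd", "hit_sequence",
            "lineage", "terms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$lineage <- strsplit(df$lineage, ";", fixed = TRUE)
  df$terms <- lapply(strsplit(df$terms, "|", fixed = TRUE),
                     function(x) x[nzchar(x)])
  df
}

#' Write a structure-hit table
#' @param hits data.frame with list-columns `lineage` and `terms`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructureHits <- function(hits, path) {
  out <- hits
  out$lineage <- vapply(hits$lineage, paste, character(1), collapse = ";")
  out$terms <- vapply(hits$terms, paste, character(1), collapse = "|")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read query protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readQuerySequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Build structural-arm hit sets with alignment and taxonomy predictors
#'
#' For each TM-filtered hit, computes the global-alignment percent identity
#' and percent non-gap against the query sequence and the taxonomic rank
#' similarity between the query's lineage and the hit's.  The per-hit
#' similarity-score map is {tm_score, rmsd, pct_identity, pct_nongap,
#' tax_rank}; hit annotations are ancestor-closed against the ontology
#' (terms the ontology does not know are dropped with a warning).  The
#' result feeds [runTermTransfer()] exactly like the GBA hit sets.
#'
#' @param hits filtered data.frame from [filterStructureHits()] with
#'   list-columns `lineage` and `terms`.
#' @param query_seqs named character vector of query protein sequences.
#' @param query_lineage character(7) lineage of the study organism.
#' @param graph an [OntologyGraph-class].
#' @param gap_open,gap_extend alignment gap penalties.
#' @return named list of hit sets (see [buildHitSets()] for the shape).
#' @export
buildStructuralHitSets <- function(hits, query_seqs, query_lineage, graph,
                                   gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  unknown_seen <- FALSE
  queries <- unique(hits$query_id)
  out <- lapply(queries, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    qs <- query_seqs[[q]]
    if (is.null(qs) || is.na(qs)) stop("no sequence for query ", q)
    stats <- lapply(seq_len(nrow(h)), function(i) {
      al <- globalAlign(qs, h$hit_sequence[i], substitution_matrix = sub,
                        gap_open = gap_open, gap_extend = gap_extend)
      c(tm_score = h$tm_score[i], rmsd = h$rmsd[i],
        pct_identity = al$pct_identity, pct_nongap = al$pct_nongap,
        tax_rank = as.numeric(
          taxonomicRankSimilarity(query_lineage, h$lineage[[i]])))
    })
    hitdf <- cbind(data.frame(hit_id = h$hit_id),
                   as.data.frame(do.call(rbind, stats)))
    ann <- lapply(h$terms, function(tt) {
      known <- intersect(tt, graph@termIds)
      if (length(known) < length(tt)) unknown_seen <<- TRUE
      if (!length(known)) character() else ancestralClosure(graph, known)
    })
    list(query = q, hits = hitdf, annotations = ann)
  })
  if (unknown_seen)
    warning("some hit annotation terms were not in the ontology and were dropped")
  names(out) <- queries
  out
}
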