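# Shared transfer engine: hits -> candidate (protein, term) scores ->
# FDR-calibrated, closure-propagated annotations.

#' Build per-query HitSets from a hit network
#'
#' A query's hits are its network neighbours, each carrying the edge's
#' similarity-score map and the hit protein's ancestor-closed known
#' annotation set.  Hits never include the query itself.
#'
#' @param network a [HitNetwork-class].
#' @param store a closed [AnnotationStore-class] of known annotations (the
#'   source of transferable terms).
#' @param queries protein ids to build hit sets for; default all nodes.
#' @param measures similarity measure columns to carry; default every edge
#'   feature column.
#' @return named list of hit sets, each a list with `query`, `hits`
#'   (data.frame: hit_id + measure columns) and `annotations` (list of
#'   closed term sets, parallel to hits).
#' @export
buildHitSets <- function(network, store, queries = NULL, measures = NULL) {
  e <- network@edges
  if (is.null(queries)) queries <- network@nodes
  if (is.null(measures))
    measures <- setdiff(names(e),
                        c("protein_a", "protein_b", "target_depth",
                          "predicted_depth"))
  sets <- proteinTermSets(store)
  out <- lapply(queries, function(q) {
    ia <- e$protein_a == q
    ib <- e$protein_b == q
    hit_id <- c(e$protein_b[ia], e$protein_a[ib])
    hits <- rbind(e[ia, measures, drop = FALSE], e[ib, measures, drop = FALSE])
    hits <- cbind(data.frame(hit_id = hit_id), hits)
    rownames(hits) <- NULL
    ann <- lapply(hit_id, function(h) {
      s <- sets[[h]]
      if (is.null(s)) character() else s
    })
    list(query = q, hits = hits, annotations = ann)
  })
  names(out) <- queries
  out
}

#' Candidate terms of a hit set
#'
#' A term is only assessed for a query if it appears among the annotations
#' of the query's hits; the candidate set is the union of hit annotation
#' sets.
#'
#' @param hit_set one element of [buildHitSets()] output.
#' @return character vector of candidate term ids (possibly empty).
#' @export
enumerateCandidates <- function(hit_set)
  unique(unlist(hit_set$annotations, use.names = FALSE))

#' Summary-statistic features for one (query, term) candidate
#'
#' Restricts the hit set to hits annotated with the term and computes, for
#' each similarity measure, the registry's statistics over that collection
#' (default: count, sum, max, mean; the count is shared across measures and
#' emitted once as `n_hits`).  Invariant to hit ordering.
#'
#' @param hit_set one element of [buildHitSets()] output.
#' @param term candidate term id.
#' @param stats statistic names among count, sum, max, mean.
#' @return named numeric vector of summary features.
#' @export
summarizeHits <- function(hit_set, term,
                          stats = c("count", "sum", "max", "mean")) {
  has <- vapply(hit_set$annotations, function(s) term %in% s, logical(1))
  if (!any(has)) stop("no hit annotated with ", term)
  m <- hit_set$hits[has, setdiff(names(hit_set$hits), "hit_id"),
                    drop = FALSE]
  out <- c()
  if ("count" %in% stats) out <- c(out, n_hits = nrow(m))
  for (col in names(m)) {
    v <- m[[col]]
    if ("sum" %in% stats) out[paste0(col, "_sum")] <- sum(v)
    if ("max" %in% stats) out[paste0(col, "_max")] <- max(v)
    if ("mean" %in% stats) out[paste0(col, "_mean")] <- mean(v)
  }
  out
}

#' Enumerate and featurize all candidates of a hit-set collection
#'
#' Vectorized equivalent of calling [summarizeHits()] for every candidate
#' term of every query (the unit tests assert the equivalence).
#'
#' @param hit_sets output of [buildHitSets()] (or the structural-arm
#'   builder).
#' @param stats statistic registry passed to [summarizeHits()].
#' @return data.frame: protein, term, plus summary-feature columns.
#' @export
candidateTable <- function(hit_sets, stats = c("count", "sum", "max", "mean")) {
  blocks <- lapply(hit_sets, function(hs) {
    terms <- enumerateCandidates(hs)
    if (!length(terms)) return(NULL)
    mcols <- setdiff(names(hs$hits), "hit_id")
    X <- as.matrix(hs$hits[, mcols, drop = FALSE])
    # hit x term incidence
    I <- vapply(terms, function(t)
      vapply(hs$annotations, function(s) t %in% s, logical(1)),
      logical(nrow(X)))
    I <- matrix(I, nrow = nrow(X))
    cnt <- colSums(I)
    sums <- crossprod(I, X)
    out <- matrix(NA_real_, length(terms), 0)
    if ("count" %in% stats) out <- cbind(out, n_hits = cnt)
    for (j in seq_along(mcols)) {
      v <- X[, j]
      cols <- NULL
      if ("sum" %in% stats)
        out <- cbind(out, sums[, j])
      if ("max" %in% stats)
        out <- cbind(out, vapply(seq_along(terms), function(ti)
          max(v[I[, ti]]), numeric(1)))
      if ("mean" %in% stats)
        out <- cbind(out, sums[, j] / cnt)
    }
    nm <- if ("count" %in% stats) "n_hits" else character()
    for (m in mcols)
      nm <- c(nm, paste0(m, "_", intersect(c("sum", "max", "mean"), stats)))
    colnames(out) <- nm
    list(protein = rep(hs$query, length(terms)), term = terms, feats = out)
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks))
    return(data.frame(protein = character(), term = character()))
  out <- data.frame(protein = unlist(lapply(blocks, `[[`, "protein")),
                    term = unlist(lapply(blocks, `[[`, "term")),
                    do.call(rbind, lapply(blocks, `[[`, "feats")))
  rownames(out) <- NULL
  out
}

#' Label candidates for positive/unlabeled training
#'
#' Applies the labeling precedence: a candidate is unlabeled if its protein
#' is a test protein, if its protein is a PUF, or if the term is deeper
#' than the deepest term in the protein's known annotation; otherwise it is
#' positive when the protein is annotated with the term and negative when
#' not.  Finally a seeded random fraction of the remaining labeled training
#' candidates is relabeled unlabeled (`fdr_holdout`) for the FDR-control
#' procedure, with the true label retained privately in `true_label`.
#'
#' @param candidates data.frame from [candidateTable()].
#' @param store a closed [AnnotationStore-class] of known annotations.
#' @param graph an [OntologyGraph-class].
#' @param puf_set character vector of PUF ids.
#' @param test_set character vector of held-out protein ids.
#' @param holdout_fraction fraction of labeled training candidates diverted
#'   to the FDR holdout (default 0.1).
#' @param seed integer seed for the holdout draw.
#' @return `candidates` with columns `label` (positive/negative/unlabeled),
#'   `unlabeled_reason` (test_protein/puf/deeper_than_known/fdr_holdout/
#'   none) and `true_label` (private; NA where unknowable).
#' @export
labelCandidates <- function(candidates, store, graph, puf_set, test_set,
                            holdout_fraction = 0.1, seed = 1L) {
  depths <- termDepth(graph)
  sets <- proteinTermSets(store)
  maxd <- vapply(sets, function(s) max(depths[s]), numeric(1))

  n <- nrow(candidates)
  label <- rep("negative", n)
  reason <- rep("none", n)
  known <- candidates$protein %in% names(sets)
  is_pos <- logical(n)
  idx <- which(known)
  is_pos[idx] <- mapply(function(p, t) t %in% sets[[p]],
                        candidates$protein[idx], candidates$term[idx])
  label[is_pos] <- "positive"
  true_label <- ifelse(known, label, NA_character_)

  deeper <- known &
    unname(depths[candidates$term]) > ifelse(known, maxd[candidates$protein], Inf)
  is_puf <- candidates$protein %in% puf_set
  is_test <- candidates$protein %in% test_set

  label[deeper] <- "unlabeled"; reason[deeper] <- "deeper_than_known"
  label[is_puf] <- "unlabeled"; reason[is_puf] <- "puf"
  label[is_test] <- "unlabeled"; reason[is_test] <- "test_protein"
  # candidates deeper than known have no trustworthy truth value
  true_label[deeper | is_puf] <- NA_character_

  set.seed(seed)
  eligible <- which(label != "unlabeled")
  n_hold <- round(holdout_fraction * length(eligible))
  hold <- if (n_hold > 0) sample(eligible, n_hold) else integer()
  label[hold] <- "unlabeled"; reason[hold] <- "fdr_holdout"

  candidates$label <- label
  candidates$unlabeled_reason <- reason
  candidates$true_label <- true_label
  candidates
}

#' Feature columns of a candidate table
#' @keywords internal
candidateFeatureCols <- function(candidates)
  setdiff(names(candidates),
          c("protein", "term", "label", "unlabeled_reason", "true_label",
            "score"))

#' Train the candidate classifier on labeled candidates
#'
#' A random-forest probability classifier fit on positive/negative
#' candidates only; every unlabeled stratum (test proteins, PUFs,
#' deeper-than-known, FDR holdout) is excluded from fitting and scored
#' afterwards.  Emits a continuous confidence in \[0, 1\].
#'
#' @param candidates labeled candidate table from [labelCandidates()].
#' @param num_trees number of trees (default 500).
#' @param seed integer seed.
#' @return a `ranger` probability forest.
#' @export
trainCandidateClassifier <- function(candidates, num_trees = 500, seed = 1L) {
  train <- candidates[candidates$label %in% c("positive", "negative"), ]
  if (!nrow(train)) stop("no labeled candidates to train on")
  y <- factor(train$label, levels = c("negative", "positive"))
  if (length(unique(y)) < 2) stop("single-class training data")
  x <- train[, candidateFeatureCols(candidates), drop = FALSE]
  ranger::ranger(x = x, y = y, probability = TRUE, num.trees = num_trees,
                 seed = seed, num.threads = 1)
}

#' Score candidates with a trained classifier
#'
#' @param scorer `ranger` probability forest.
#' @param candidates candidate table.
#' @return `candidates` with a `score` column in \[0, 1\].
#' @export
scoreCandidates <- function(scorer, candidates) {
  x <- candidates[, candidateFeatureCols(candidates), drop = FALSE]
  p <- predict(scorer, data = x, num.threads = 1)$predictions
  candidates$score <- p[, "positive"]
  candidates
}

#' Calibrate a score threshold to a target FDR on the holdout
#'
#' Scans every observed score value t and computes the empirical false
#' discovery rate FP/(FP+TP) among holdout candidates scoring at least t;
#' the threshold is the smallest observed score whose FDR is at or below
#' the target (maximizing calls subject to the bound).  If no observed
#' score qualifies, the threshold is +Inf (no calls) with a warning.  The
#' realized calibration FDR at the chosen threshold is at most the target
#' by construction, which is asserted.
#'
#' @param scores numeric scores of the FDR-holdout candidates.
#' @param labels their private true labels, "positive"/"negative".
#' @param target target FDR in (0, 1), default 0.01.
#' @return an object of class `FDRCalibration`: list with target,
#'   threshold, realized_fdr, n_calls, precision, recall.
#' @export
calibrateFdr <- function(scores, labels, target = 0.01) {
  stopifnot(length(scores) == length(labels), target > 0, target <= 1)
  if (!length(scores)) stop("empty calibration holdout")
  pos <- labels == "positive"
  if (!any(pos)) stop("calibration holdout has no positives")
  ths <- sort(unique(scores))
  fdr <- vapply(ths, function(t) {
    called <- scores >= t
    fp <- sum(called & !pos); tp <- sum(called & pos)
    if (fp + tp == 0) 0 else fp / (fp + tp)
  }, numeric(1))
  ok <- which(fdr <= target)
  if (!length(ok)) {
    warning("no observed threshold achieves the target FDR; no calls made")
    res <- list(target = target, threshold = Inf, realized_fdr = NA_real_,
                n_calls = 0L, precision = NA_real_, recall = 0)
    class(res) <- "FDRCalibration"
    return(res)
  }
  thr <- ths[min(ok)]
  called <- scores >= thr
  fp <- sum(called & !pos); tp <- sum(called & pos)
  realized <- if (fp + tp == 0) 0 else fp / (fp + tp)
  stopifnot(realized <= target)   # holds by construction
  res <- list(target = target, threshold = thr, realized_fdr = realized,
              n_calls = sum(called), precision = 1 - realized,
              recall = tp / sum(pos))
  class(res) <- "FDRCalibration"
  res
}

#' @export
print.FDRCalibration <- function(x, ...) {
  cat("FDR calibration: target", x$target, "\n")
  cat("  threshold:", x$threshold, " calls:", x$n_calls, "\n")
  cat("  realized FDR:", x$realized_fdr, " precision:", x$precision,
      " recall:", x$recall, "\n")
  invisible(x)
}

#' Accept candidates and propagate ancestors into an annotation store
#'
#' Candidates scoring at or above the threshold are accepted; every
#' ancestor term necessitated by the ontology is added, inheriting the
#' maximum score over its accepting descendants (directly accepted terms
#' keep their own score).  The result is ancestor-closed by construction.
#'
#' @param candidates scored candidate table.
#' @param threshold acceptance threshold (from [calibrateFdr()]).
#' @param graph an [OntologyGraph-class].
#' @param arm provenance label, e.g. "gba" or "structural".
#' @return a closed [AnnotationStore-class]; empty if nothing passes.
#' @export
finalizeAnnotations <- function(candidates, threshold, graph, arm = "gba") {
  acc <- candidates[!is.na(candidates$score) & candidates$score >= threshold, ]
  if (!nrow(acc))
    return(newAnnotationStore(
      data.frame(protein_id = character(), term_id = character(),
                 source = character(), score = numeric(),
                 via_closure = logical()), closed = TRUE))
  rows <- lapply(split(acc, acc$protein), function(d) {
    # collapse duplicate accepted terms by max score
    direct <- tapply(d$score, d$term, max)
    inherit <- list()
    for (t in names(direct)) {
      anc <- graph@ancestors[[t]]
      for (a in anc) inherit[[a]] <- max(inherit[[a]] %||% -Inf, direct[[t]])
    }
    added <- setdiff(names(inherit), names(direct))
    data.frame(
      protein_id = d$protein[1],
      term_id = c(names(direct), added),
      source = arm,
      score = c(unname(direct), unlist(inherit[added], use.names = FALSE)),
      via_closure = c(rep(FALSE, length(direct)), rep(TRUE, length(added))))
  })
  newAnnotationStore(do.call(rbind, rows), closed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union of the two arms' predicted annotation stores
#'
#' Per-protein set union of predictions; assignments made by both arms keep
#' both provenance rows.  The union of two closed stores is closed.
#'
#' @param store_gba,store_structural closed [AnnotationStore-class] objects.
#' @return combined closed [AnnotationStore-class].
#' @export
unionArms <- function(store_gba, store_structural) {
  stopifnot(store_gba@closed, store_structural@closed)
  a <- rbind(store_gba@assignments, store_structural@assignments)
  a <- unique(a)
  newAnnotationStore(a, closed = TRUE)
}

#' Run the full transfer engine on a hit-set collection
#'
#' Enumerates and featurizes candidates, labels them, trains the
#' classifier, scores everything, calibrates the FDR threshold on the
#' deliberately unlabeled holdout, and emits the closed predicted store.
#' Also reports the realized FDR/precision/recall on the test-protein
#' candidates (whose truth is known but never trained on).
#'
#' @param hit_sets output of [buildHitSets()] or
#'   [buildStructuralHitSets()].
#' @param store closed known-annotation store.
#' @param graph ontology.
#' @param puf_set,test_set protein id vectors.
#' @param target_fdr target FDR (default 0.01).
#' @param holdout_fraction FDR-holdout fraction (default 0.1).
#' @param num_trees classifier forest size.
#' @param seed integer seed.
#' @param arm provenance label.
#' @param stats summary-statistic registry.
#' @return list: candidates (scored, labeled), scorer, calibration,
#'   predicted (closed store), test_metrics (list with realized_fdr,
#'   precision, recall over test candidates).
#' @export
runTermTransfer <- function(hit_sets, store, graph, puf_set, test_set,
                            target_fdr = 0.01, holdout_fraction = 0.1,
                            num_trees = 500, seed = 1L, arm = "gba",
                            stats = c("count", "sum", "max", "mean")) {
  emptyResult <- function(cands, why) {
    warning("no term calls possible: ", why)
    cal <- list(target = target_fdr, threshold = Inf,
                realized_fdr = NA_real_, n_calls = 0L,
                precision = NA_real_, recall = 0)
    class(cal) <- "FDRCalibration"
    list(candidates = cands, scorer = NULL, calibration = cal,
         predicted = finalizeAnnotations(
           data.frame(protein = character(), term = character(),
                      score = numeric()), Inf, graph, arm = arm),
         test_metrics = list(realized_fdr = NA_real_,
                             precision = NA_real_, recall = NA_real_))
  }
  cands <- candidateTable(hit_sets, stats)
  if (!nrow(cands))
    return(emptyResult(cands, "hit network contributed no annotated hits"))
  cands <- labelCandidates(cands, store, graph, puf_set, test_set,
                           holdout_fraction = holdout_fraction, seed = seed)
  scorer <- trainCandidateClassifier(cands, num_trees = num_trees, seed = seed)
  cands <- scoreCandidates(scorer, cands)

  hold <- cands$unlabeled_reason == "fdr_holdout"
  if (!any(hold) || !any(cands$true_label[hold] == "positive"))
    return(emptyResult(cands, "calibration holdout has no positives"))
  cal <- calibrateFdr(cands$score[hold], cands$true_label[hold],
                      target = target_fdr)

  test <- cands$unlabeled_reason == "test_protein" & !is.na(cands$true_label)
  tm <- list(realized_fdr = NA_real_, precision = NA_real_, recall = NA_real_)
  if (any(test) && is.finite(cal$threshold)) {
    sc <- cands$score[test]; tl <- cands$true_label[test]
    called <- sc >= cal$threshold
    fp <- sum(called & tl == "negative"); tp <- sum(called & tl == "positive")
    tm$realized_fdr <- if (fp + tp > 0) fp / (fp + tp) else NA_real_
    tm$precision <- if (fp + tp > 0) tp / (fp + tp) else NA_real_
    tm$recall <- tp / sum(tl == "positive")
  }
  predicted <- finalizeAnnotations(cands, cal$threshold, graph, arm = arm)
  list(candidates = cands, scorer = scorer, calibration = cal,
       predicted = predicted, test_metrics = tm)
}
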