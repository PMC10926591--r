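# End-to-end runners for the two arms on a synthetic (or file-loaded)
# dataset.

#' Run the guilt-by-association arm end to end
#'
#' From the merged public annotations: classify PUFs, hold out a fraction
#' of PKFs, assemble pair features, train the pair-depth regressor on
#' untainted pairs, threshold predictions into the hit network, and run
#' the shared transfer engine with FDR calibration.
#'
#' @param sim a `SyntheticData` object (or any list with the same
#'   elements: graph, public_store, proteins, pufs, pkfs, channels).
#' @param target_fdr target FDR for term calls (default 0.01).
#' @param holdout_fraction FDR-holdout fraction (default 0.1).
#' @param test_fraction held-out protein fraction (default 0.1).
#' @param hit_cutoff strict predicted-depth cutoff for hits (default 6).
#' @param num_trees random-forest size for both models (default 500).
#' @param seed integer seed.
#' @return list: split, features, regressor, pair_eval (ROC + AUC on
#'   test-tainted pairs), network, transfer (the [runTermTransfer()]
#'   output), predicted (closed store).
#' @export
runGbaArm <- function(sim, target_fdr = 0.01, holdout_fraction = 0.1,
                      test_fraction = 0.1, hit_cutoff = 6,
                      num_trees = 500, seed = 1L) {
  graph <- sim$graph
  store <- sim$public_store
  split <- splitProteins(sim$pkfs, fraction = test_fraction, seed = seed)

  features <- assemblePairFeatures(sim$channels, sim$proteins)
  features <- pairTargets(features, graph, store)

  train_df <- buildPairTrainingSet(features, split$test, split$train)
  regressor <- trainPairRegressor(train_df, num_trees = num_trees,
                                  seed = seed)
  network <- predictHits(regressor, features, hit_cutoff = hit_cutoff,
                         nodes = sim$proteins)

  # evaluate on annotated pairs touching the test set (never trained on)
  ann <- c(split$train, split$test)
  test_pairs <- features$protein_a %in% ann & features$protein_b %in% ann &
    (features$protein_a %in% split$test | features$protein_b %in% split$test)
  cols <- pairFeatureCols(features)
  test_scores <- predict(regressor,
                         data = features[test_pairs, cols, drop = FALSE],
                         num.threads = 1)$predictions
  pair_eval <- evaluatePairModel(test_scores,
                                 features$target_depth[test_pairs],
                                 cutoff = hit_cutoff)

  hit_sets <- buildHitSets(network, store)
  hit_sets <- Filter(function(h) nrow(h$hits) > 0, hit_sets)
  transfer <- runTermTransfer(hit_sets, store, graph,
                              puf_set = sim$pufs, test_set = split$test,
                              target_fdr = target_fdr,
                              holdout_fraction = holdout_fraction,
                              num_trees = num_trees, seed = seed,
                              arm = "gba")
  list(split = split, features = features, regressor = regressor,
       pair_eval = pair_eval, network = network, transfer = transfer,
       predicted = transfer$predicted)
}

#' Run the structural-similarity arm end to end
#'
#' TM-filters the structure-search hits, computes alignment and taxonomy
#' predictors, and runs the shared transfer engine with the structural
#' statistic registry.
#'
#' @param sim a `SyntheticData` object (needs structure_hits, sequences,
#'   query_lineage, graph, public_store, pufs, pkfs).
#' @param split the train/test split shared with the GBA arm; computed
#'   from `seed` when NULL.
#' @param tm_cutoff strict TM-score filter (default 0.3).
#' @inheritParams runGbaArm
#' @return list: split, hit_sets, transfer, predicted.
#' @export
runStructuralArm <- function(sim, split = NULL, target_fdr = 0.01,
                             holdout_fraction = 0.1, test_fraction = 0.1,
                             tm_cutoff = 0.3, num_trees = 500, seed = 1L) {
  graph <- sim$graph
  store <- sim$public_store
  if (is.null(split))
    split <- splitProteins(sim$pkfs, fraction = test_fraction, seed = seed)
  hits <- filterStructureHits(sim$structure_hits, tm_cutoff = tm_cutoff)
  hit_sets <- buildStructuralHitSets(hits, sim$sequences,
                                     sim$query_lineage, graph)
  transfer <- runTermTransfer(hit_sets, store, graph,
                              puf_set = sim$pufs, test_set = split$test,
                              target_fdr = target_fdr,
                              holdout_fraction = holdout_fraction,
                              num_trees = num_trees, seed = seed,
                              arm = "structural")
  list(split = split, hit_sets = hit_sets, transfer = transfer,
       predicted = transfer$predicted)
}

#' Restrict an annotation store to a protein subset
#' @param store an [AnnotationStore-class].
#' @param proteins protein ids to keep.
#' @return an [AnnotationStore-class] with the same closure status.
#' @export
subsetStore <- function(store, proteins) {
  a <- store@assignments
  newAnnotationStore(a[a$protein_id %in% proteins, , drop = FALSE],
                     closed = store@closed)
}

#' Run both arms, union their predictions and evaluate against the truth
#'
#' @param sim a `SyntheticData` object.
#' @inheritParams runGbaArm
#' @return list: gba, structural, combined (union store), evaluation
#'   (realized FDR/recall on the masked ground truth, PUF predictions
#'   only).
#' @export
runPipeline <- function(sim, target_fdr = 0.01, holdout_fraction = 0.1,
                        test_fraction = 0.1, hit_cutoff = 6,
                        num_trees = 500, seed = 1L) {
  gba <- runGbaArm(sim, target_fdr = target_fdr,
                   holdout_fraction = holdout_fraction,
                   test_fraction = test_fraction, hit_cutoff = hit_cutoff,
                   num_trees = num_trees, seed = seed)
  struct <- runStructuralArm(sim, split = gba$split, target_fdr = target_fdr,
                             holdout_fraction = holdout_fraction,
                             num_trees = num_trees, seed = seed)
  combined <- unionArms(gba$predicted, struct$predicted)
  evaluation <- evaluateAgainstTruth(subsetStore(combined, sim$truth$masked),
                                     sim$truth, sim$graph)
  list(gba = gba, structural = struct, combined = combined,
       evaluation = evaluation)
}
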