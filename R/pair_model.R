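# Pair-depth regression: learn deepest-shared-GO-depth, threshold into hits.

#' Split annotated proteins into train and test sets
#'
#' Holds out a fraction of annotated (PKF) proteins for all machine-learning
#' steps.  A pair is test-tainted (and excluded from training) if either of
#' its proteins is a test protein.
#'
#' @param annotated_proteins character vector of PKF ids.
#' @param fraction fraction held out (default 0.1).
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
splitProteins <- function(annotated_proteins, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (length(annotated_proteins) < 10)
    stop("need at least 10 annotated proteins to split")
  set.seed(seed)
  n_test <- max(1L, round(fraction * length(annotated_proteins)))
  test <- sample(annotated_proteins, n_test)
  list(train = setdiff(annotated_proteins, test), test = test)
}

#' Oversampling multiplicity for pair training targets
#'
#' Pairs with shared term depth strictly greater than six are oversampled
#' twofold and those strictly deeper than eight fourfold (the fourfold
#' factor replaces the twofold one for its stratum).
#'
#' @param depths integer vector of target depths.
#' @return integer multiplicities (1, 2 or 4).
#' @export
oversampleMultiplicity <- function(depths) {
  stopifnot(all(depths >= 0))
  m <- rep(1L, length(depths))
  m[depths > 6] <- 2L
  m[depths > 8] <- 4L
  m
}

#' Replicate training pairs according to the oversampling rule
#'
#' @param pair_df data.frame of training pairs with a `target_depth` column.
#' @return the same data.frame with rows repeated per
#'   [oversampleMultiplicity()].
#' @export
oversamplePairs <- function(pair_df) {
  m <- oversampleMultiplicity(pair_df$target_depth)
  pair_df[rep(seq_len(nrow(pair_df)), m), , drop = FALSE]
}

#' Attach deepest-shared-depth targets to a pair feature table
#'
#' @param features data.frame from [assemblePairFeatures()].
#' @param graph an [OntologyGraph-class].
#' @param store a closed [AnnotationStore-class] of known annotations.
#' @return `features` with an integer `target_depth` column (0 when either
#'   protein has no annotation).
#' @export
pairTargets <- function(features, graph, store) {
  sets <- proteinTermSets(store)
  features$target_depth <- mapply(function(a, b) {
    sa <- sets[[a]]; sb <- sets[[b]]
    if (is.null(sa) || is.null(sb)) return(0L)
    as.integer(deepestSharedDepth(graph, sa, sb))
  }, features$protein_a, features$protein_b)
  features
}

#' Feature column names of a pair table
#' @param features pair feature data.frame.
#' @return character vector excluding ids and targets.
#' @keywords internal
pairFeatureCols <- function(features)
  setdiff(names(features),
          c("protein_a", "protein_b", "target_depth", "predicted_depth"))

#' Train the random-forest pair-depth regressor
#'
#' Fits a random forest regression of the deepest-shared-term depth on the
#' pair similarity measures, after oversampling deep pairs
#' ([oversamplePairs()]).  Pairs touching a test protein must be excluded
#' by the caller ([buildPairTrainingSet()] does this).
#'
#' @param train_df training pairs with feature columns and `target_depth`.
#' @param num_trees number of trees (default 500).
#' @param mtry features per split (default sqrt of feature count).
#' @param seed integer seed; fits are deterministic under it.
#' @return a `ranger` regression object.
#' @export
trainPairRegressor <- function(train_df, num_trees = 500, mtry = NULL,
                               seed = 1L) {
  if (!nrow(train_df)) stop("empty training set")
  cols <- pairFeatureCols(train_df)
  dat <- oversamplePairs(train_df)
  x <- dat[, cols, drop = FALSE]
  ranger::ranger(x = x, y = dat$target_depth, num.trees = num_trees,
                 mtry = mtry, seed = seed, num.threads = 1)
}

#' Build the pair training set, excluding test-tainted pairs
#'
#' @param features pair feature table with `target_depth`.
#' @param test_proteins character vector of held-out protein ids.
#' @param train_proteins character vector of training protein ids; training
#'   pairs must have both ends in this set.
#' @return data.frame of untainted training pairs.
#' @export
buildPairTrainingSet <- function(features, test_proteins, train_proteins) {
  keep <- features$protein_a %in% train_proteins &
          features$protein_b %in% train_proteins
  stopifnot(!any(features$protein_a[keep] %in% test_proteins),
            !any(features$protein_b[keep] %in% test_proteins))
  features[keep, , drop = FALSE]
}

#' Predict pair depths and threshold into a hit network
#'
#' Every scored pair with predicted deepest-shared depth strictly greater
#' than the cutoff becomes an undirected edge carrying the pair's feature
#' vector.  PUFs and test proteins are scored (never trained on).
#'
#' @param regressor a fitted `ranger` object from [trainPairRegressor()].
#' @param features pair feature table over the scoring universe.
#' @param hit_cutoff strict depth cutoff (default 6).
#' @param nodes node universe; default all proteins in `features`.
#' @return a [HitNetwork-class].
#' @export
predictHits <- function(regressor, features, hit_cutoff = 6,
                        nodes = NULL) {
  cols <- pairFeatureCols(features)
  pred <- predict(regressor, data = features[, cols, drop = FALSE],
                  num.threads = 1)$predictions
  features$predicted_depth <- pred
  if (is.null(nodes))
    nodes <- sort(unique(c(features$protein_a, features$protein_b)))
  edges <- features[pred > hit_cutoff &
                    features$protein_a != features$protein_b, , drop = FALSE]
  rownames(edges) <- NULL
  new("HitNetwork", nodes = nodes, edges = edges, hitCutoff = hit_cutoff)
}

#' ROC curve and AUC by the trapezoid rule
#'
#' Truth is binarized as `true depth > cutoff`.  The full threshold sweep
#' over observed scores yields ROC points; AUC is the trapezoid-rule area.
#' With a single truth class the AUC is undefined and returned as NA.
#'
#' @param scores numeric predicted depths.
#' @param truth_depths integer true depths.
#' @param cutoff binarization cutoff (default 6).
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
evaluatePairModel <- function(scores, truth_depths, cutoff = 6) {
  labels <- truth_depths > cutoff
  if (length(unique(labels)) < 2)
    return(list(roc = data.frame(threshold = numeric(), fpr = numeric(),
                                 tpr = numeric()),
                auc = NA_real_))
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels); N <- sum(!labels)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels) / P, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & !labels) / N, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = ths, fpr = fpr, tpr = tpr), auc = auc)
}
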