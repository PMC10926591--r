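# Within-species pairwise similarity measures feeding the pair model.

# canonical unordered-pair key
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\036")

#' Default registry of pair similarity measures
#'
#' The pair model consumes 20 measures: nine computed or consumed directly
#' by this package (motif weighted-Jaccard distance, sequence bitscore,
#' operon co-membership, orthogroup species-intersection size, tree-distance
#' metric, mean Spearman co-expression, co-expression presence/absence
#' Jaccard distance, max-normalized TM-score, RMSD), the STRING combined
#' score, and ten retained STRING sub-scores (co-expression and experiments
#' are excluded; their transferred variants are kept).  Each entry records
#' the fill value used when a pair has no evidence in that channel: 0 for
#' numeric similarity channels, 1 for the two distance-type channels.
#'
#' @return data.frame with columns `feature` and `fill`.
#' @export
defaultFeatureRegistry <- function() {
  string_sub <- c("neighborhood", "fusion", "cooccurence", "homology",
                  "coexpression_transferred", "experiments_transferred",
                  "database", "database_transferred",
                  "textmining", "textmining_transferred")
  data.frame(
    feature = c("motif_jaccard", "bitscore", "operon", "orthogroup_overlap",
                "tree_distance", "mean_spearman", "coexpr_jaccard",
                "tm_max", "rmsd", "string_combined",
                paste0("string_", string_sub)),
    fill = c(1, 0, 0, 0, 0, 0, 1, 0, 0, 0, rep(0, length(string_sub)))
  )
}

#' Shannon information weight of binary sequence features
#'
#' The weight of feature f carried by n_f of N proteins is
#' `-log2(n_f / N)`: rare features are up-weighted, universal features get
#' weight 0.
#'
#' @param feature_matrix binary protein x feature matrix (0/1), with
#'   dimnames.
#' @return named numeric vector, feature -> weight in bits.
#' @export
shannonWeights <- function(feature_matrix) {
  stopifnot(nrow(feature_matrix) > 0, ncol(feature_matrix) > 0,
            all(feature_matrix %in% c(0, 1)))
  nf <- colSums(feature_matrix)
  if (any(nf == 0))
    stop("feature carried by zero proteins: ",
         colnames(feature_matrix)[nf == 0][1])
  -log2(nf / nrow(feature_matrix))
}

#' Weighted Jaccard distance between two feature sets
#'
#' `1 - sum(w over intersection) / sum(w over union)`.  When the union has
#' total weight 0 (only universal, zero-weight features), the vectors are
#' indistinguishable under the weighting and the distance is defined as 0.
#'
#' @param features_a,features_b character vectors of feature ids.
#' @param weights named numeric vector covering the feature universe.
#' @return distance in \[0, 1\].
#' @export
weightedJaccardDistance <- function(features_a, features_b, weights) {
  features_a <- unique(features_a); features_b <- unique(features_b)
  u <- union(features_a, features_b)
  unknown <- setdiff(u, names(weights))
  if (length(unknown)) stop("feature without weight: ", unknown[1])
  wu <- sum(weights[u])
  if (wu == 0) return(0)
  wi <- sum(weights[intersect(features_a, features_b)])
  1 - wi / wu
}

#' Construct a label-free quantification experiment
#'
#' @param intensities non-negative protein x sample matrix with dimnames.
#' @param sample_condition named character, sample -> condition.
#' @param id experiment identifier.
#' @return an object of class `QuantExperiment` (list-based).
#' @export
quantExperiment <- function(intensities, sample_condition, id = "exp") {
  stopifnot(is.matrix(intensities), all(intensities >= 0),
            !is.null(rownames(intensities)), !is.null(colnames(intensities)))
  if (!all(colnames(intensities) %in% names(sample_condition)))
    stop("unmapped sample(s): ",
         setdiff(colnames(intensities), names(sample_condition))[1])
  conds <- unique(sample_condition[colnames(intensities)])
  if (length(conds) < 2) stop("experiment needs >= 2 conditions")
  structure(list(id = id, intensities = intensities,
                 sample_condition = sample_condition[colnames(intensities)]),
            class = "QuantExperiment")
}

#' Condition-level profiles of a quantification experiment
#'
#' Nonzero intensities are averaged per condition; conditions where a
#' protein was never observed are zero-imputed.
#'
#' @param experiment a `QuantExperiment`.
#' @return protein x condition matrix.
#' @export
conditionProfiles <- function(experiment) {
  m <- experiment$intensities
  conds <- unique(experiment$sample_condition)
  prof <- sapply(conds, function(cc) {
    sub <- m[, experiment$sample_condition == cc, drop = FALSE]
    apply(sub, 1, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  })
  prof <- matrix(prof, nrow = nrow(m),
                 dimnames = list(rownames(m), conds))
  prof
}

#' Proteomic co-expression features for protein pairs
#'
#' Per experiment, proteins are reduced to condition-level profiles
#' ([conditionProfiles()]) and the Spearman correlation of the two profiles
#' is taken; a pair's correlation in an experiment missing either protein is
#' 0, as is an undefined correlation from a constant profile.  The mean
#' over experiments is the `mean_spearman` feature.  The presence/absence
#' Jaccard distance is computed on the concatenated condition-level presence
#' vectors (profile value > 0) across all experiments; a pair observed
#' nowhere gets distance 1.
#'
#' @param experiments list of `QuantExperiment` objects.
#' @param pairs data.frame with columns protein_a, protein_b.
#' @return data.frame: protein_a, protein_b, mean_spearman, coexpr_jaccard.
#' @export
coexpressionFeatures <- function(experiments, pairs) {
  stopifnot(length(experiments) >= 1)
  n <- nrow(pairs)
  rho_sum <- numeric(n)
  pres_a <- pres_b <- NULL
  for (ex in experiments) {
    prof <- conditionProfiles(ex)
    # Spearman over all quantified proteins at once, then pair lookup
    suppressWarnings(rho <- cor(t(prof), method = "spearman"))
    rho[is.na(rho)] <- 0
    ia <- match(pairs$protein_a, rownames(prof))
    ib <- match(pairs$protein_b, rownames(prof))
    ok <- !is.na(ia) & !is.na(ib)
    r <- numeric(n)
    r[ok] <- rho[cbind(ia[ok], ib[ok])]
    rho_sum <- rho_sum + r
    pa <- matrix(FALSE, n, ncol(prof))
    pb <- matrix(FALSE, n, ncol(prof))
    pa[ok, ] <- prof[ia[ok], , drop = FALSE] > 0
    pb[ok, ] <- prof[ib[ok], , drop = FALSE] > 0
    pres_a <- cbind(pres_a, pa)
    pres_b <- cbind(pres_b, pb)
  }
  inter <- rowSums(pres_a & pres_b)
  uni <- rowSums(pres_a | pres_b)
  jac <- ifelse(uni == 0, 1, 1 - inter / uni)
  data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
             mean_spearman = rho_sum / length(experiments),
             coexpr_jaccard = jac)
}

#' Trim a predicted structure by per-residue confidence
#'
#' Residues are trimmed from both termini up to (but not including) the
#' first residue with pLDDT strictly greater than the cutoff; interior
#' low-confidence residues are untouched.  The structure is kept only if
#' the remaining stretch is strictly longer than `min_retained_length`.
#'
#' @param plddt numeric vector of per-residue pLDDT values in \[0, 100\],
#'   ordered N- to C-terminus.
#' @param plddt_cutoff confidence cutoff (default 70).
#' @param min_retained_length strict minimum retained length (default 30).
#' @return list with `kept` (logical), and when any residue passes the
#'   cutoff, `from`, `to` (1-based bounds of the retained stretch) and
#'   `plddt` (the retained values).
#' @export
trimStructure <- function(plddt, plddt_cutoff = 70, min_retained_length = 30) {
  stopifnot(length(plddt) >= 1, all(plddt >= 0 & plddt <= 100),
            plddt_cutoff >= 0, plddt_cutoff <= 100, min_retained_length > 0)
  above <- which(plddt > plddt_cutoff)
  if (!length(above)) return(list(kept = FALSE))
  from <- min(above); to <- max(above)
  kept <- (to - from + 1L) > min_retained_length
  list(kept = kept, from = from, to = to, plddt = plddt[from:to])
}

#' Read per-residue pLDDT from an AlphaFold-style PDB file
#'
#' pLDDT is stored in the B-factor column; one value per residue is taken
#' from the CA atoms.
#'
#' @param path PDB file path.
#' @return numeric vector of pLDDT values in residue order.
#' @export
readResidueConfidence <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  ca$b[order(ca$resno)]
}

#' Max-normalized TM-score feature for a structure pair
#'
#' A TM alignment yields two scores, one normalized by each protein's
#' length; the pair feature is their maximum, alongside the RMSD.
#' Order-invariant.
#'
#' @param tm_norm_by_a,tm_norm_by_b TM-scores in \[0, 1\].
#' @param rmsd non-negative RMSD in Angstroms.
#' @return named numeric vector `c(tm_max=, rmsd=)`.
#' @export
tmPairFeature <- function(tm_norm_by_a, tm_norm_by_b, rmsd) {
  if (any(c(tm_norm_by_a, tm_norm_by_b) < 0 | c(tm_norm_by_a, tm_norm_by_b) > 1))
    stop("TM-score outside [0, 1]")
  stopifnot(rmsd >= 0)
  c(tm_max = max(tm_norm_by_a, tm_norm_by_b), rmsd = rmsd)
}

#' Orthogroup species-intersection size for a protein pair
#'
#' Each protein belongs to at most one orthogroup carrying a species set;
#' the feature is the size of the intersection of the two species sets, 0
#' when either protein has no orthogroup.
#'
#' @param orthogroups list with `membership` (named character, protein ->
#'   orthogroup) and `species` (named list, orthogroup -> species ids).
#' @param protein_a,protein_b protein ids.
#' @return integer intersection size.
#' @export
orthogroupOverlap <- function(orthogroups, protein_a, protein_b) {
  oa <- orthogroups$membership[protein_a]
  ob <- orthogroups$membership[protein_b]
  if (is.na(oa) || is.na(ob)) return(0L)
  length(intersect(orthogroups$species[[oa]], orthogroups$species[[ob]]))
}

#' Read a quantification experiment from CSV plus a sample map
#'
#' The CSV holds the protein x sample intensity matrix (row names =
#' protein ids); the sample map TSV has columns `sample` and `condition`.
#'
#' @param csv_path intensity matrix CSV.
#' @param map_path sample map TSV.
#' @param id experiment identifier.
#' @return a `QuantExperiment`.
#' @export
readQuantExperiment <- function(csv_path, map_path, id = basename(csv_path)) {
  m <- as.matrix(utils::read.csv(csv_path, row.names = 1, check.names = FALSE))
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  quantExperiment(m, setNames(map$condition, map$sample), id = id)
}

#' Read a STRING-style link table
#'
#' Expects whitespace- or tab-separated columns protein1, protein2, one
#' column per sub-score and combined_score, on STRING's 0-1000 integer
#' scale; scores are rescaled to \[0, 1\] on load.
#'
#' @param path file path.
#' @return data.frame with rescaled scores.
#' @export
readStringLinks <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("protein1", "protein2") %in% names(df)))
  num <- setdiff(names(df), c("protein1", "protein2"))
  df[num] <- lapply(df[num], function(v) v / 1000)
  df
}

#' Select STRING sub-scores for the pair model
#'
#' Retains the combined score and all sub-scores except the excluded ones
#' (by default co-expression and experiments, whose transferred variants
#' are both kept).  Pairs absent from the table implicitly score 0 in every
#' retained channel (applied at assembly time).
#'
#' @param string_table data.frame from [readStringLinks()].
#' @param excluded character vector of sub-score base names to drop.
#' @return data.frame: protein1, protein2, combined_score and retained
#'   sub-scores.
#' @export
selectStringScores <- function(string_table,
                               excluded = c("coexpression", "experiments")) {
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(string_table))
  if (length(miss))
    stop("malformed STRING table, missing columns: ",
         paste(miss, collapse = ", "))
  sub <- setdiff(names(string_table), need)
  keep <- sub[!(sub %in% excluded)]   # exact names only: transferred kept
  string_table[, c(need[1:2], "combined_score", keep), drop = FALSE]
}

#' Assemble the full pair feature table
#'
#' Builds one named similarity vector per unordered protein pair from all
#' evidence channels, registry-complete, symmetric in pair order.  Channels
#' are optional; pairs missing from a channel receive that channel's
#' registry fill value.  Ids present in a channel but not in the universe
#' are dropped with a warning.
#'
#' @param channels list with any of: `motifs` (list with binary `matrix` and
#'   optional `weights`), `bitscore`, `operon`, `tree_distance` (each a
#'   data.frame protein_a, protein_b, value), `orthogroups` (see
#'   [orthogroupOverlap()]), `quant` (list of `QuantExperiment`),
#'   `structure_tm` (data.frame protein_a, protein_b, tm_a, tm_b, rmsd),
#'   `string` (data.frame from [selectStringScores()]).
#' @param universe character vector of protein ids to pair up.
#' @param pairs optional data.frame (protein_a, protein_b) restricting the
#'   output; default all `n(n-1)/2` pairs.
#' @param registry feature registry, see [defaultFeatureRegistry()].
#' @return data.frame: protein_a, protein_b, plus one column per registry
#'   feature.
#' @export
assemblePairFeatures <- function(channels, universe, pairs = NULL,
                                 registry = defaultFeatureRegistry()) {
  stopifnot(length(universe) >= 2)
  if (is.null(pairs)) {
    idx <- utils::combn(sort(universe), 2)
    pairs <- data.frame(protein_a = idx[1, ], protein_b = idx[2, ])
  } else {
    a <- pmin(pairs$protein_a, pairs$protein_b)
    b <- pmax(pairs$protein_a, pairs$protein_b)
    pairs <- data.frame(protein_a = a, protein_b = b)
  }
  out <- pairs
  key <- pairKey(pairs$protein_a, pairs$protein_b)
  fill <- setNames(registry$fill, registry$feature)
  for (f in registry$feature) out[[f]] <- fill[[f]]

  dropForeign <- function(df, cols) {
    ids <- unlist(df[cols], use.names = FALSE)
    bad <- !(ids %in% universe)
    if (any(bad)) {
      warning(sum(bad), " channel id(s) outside universe dropped (e.g. ",
              ids[bad][1], ")")
      ok <- rowSums(matrix(bad, nrow = nrow(df))) == 0
      df <- df[ok, , drop = FALSE]
    }
    df
  }
  lookupPair <- function(df) match(key, pairKey(df$protein_a, df$protein_b))

  # simple pair-value channels
  for (ch in c("bitscore", "operon", "tree_distance")) {
    if (is.null(channels[[ch]])) next
    df <- dropForeign(channels[[ch]], c("protein_a", "protein_b"))
    m <- lookupPair(df)
    out[[ch]][!is.na(m)] <- df$value[m[!is.na(m)]]
  }
  if (!is.null(channels$motifs)) {
    mat <- channels$motifs$matrix
    foreign <- setdiff(rownames(mat), universe)
    if (length(foreign)) {
      warning(length(foreign), " motif protein(s) outside universe dropped")
      mat <- mat[!(rownames(mat) %in% foreign), , drop = FALSE]
    }
    w <- channels$motifs$weights
    if (is.null(w)) w <- shannonWeights(mat)
    feats <- apply(mat, 1, function(r) colnames(mat)[r > 0], simplify = FALSE)
    out$motif_jaccard <- mapply(function(a, b) {
      fa <- feats[[a]]; fb <- feats[[b]]
      if (is.null(fa) || is.null(fb)) return(1)
      weightedJaccardDistance(fa, fb, w)
    }, pairs$protein_a, pairs$protein_b)
  }
  if (!is.null(channels$orthogroups)) {
    og <- channels$orthogroups
    out$orthogroup_overlap <- mapply(function(a, b)
      orthogroupOverlap(og, a, b), pairs$protein_a, pairs$protein_b)
  }
  if (!is.null(channels$quant)) {
    cf <- coexpressionFeatures(channels$quant, pairs)
    out$mean_spearman <- cf$mean_spearman
    out$coexpr_jaccard <- cf$coexpr_jaccard
  }
  if (!is.null(channels$structure_tm)) {
    df <- dropForeign(channels$structure_tm, c("protein_a", "protein_b"))
    m <- lookupPair(df)
    hit <- !is.na(m)
    out$tm_max[hit] <- pmax(df$tm_a[m[hit]], df$tm_b[m[hit]])
    out$rmsd[hit] <- df$rmsd[m[hit]]
  }
  if (!is.null(channels$string)) {
    df <- channels$string
    names(df)[names(df) == "protein1"] <- "protein_a"
    names(df)[names(df) == "protein2"] <- "protein_b"
    df <- dropForeign(df, c("protein_a", "protein_b"))
    a <- pmin(df$protein_a, df$protein_b); b <- pmax(df$protein_a, df$protein_b)
    m <- match(key, pairKey(a, b))
    hit <- !is.na(m)
    out$string_combined[hit] <- df$combined_score[m[hit]]
    for (col in setdiff(names(df),
                        c("protein_a", "protein_b", "combined_score"))) {
      reg_col <- paste0("string_", col)
      if (reg_col %in% registry$feature)
        out[[reg_col]][hit] <- df[[col]][m[hit]]
    }
  }
  out
}
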