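# Synthetic inputs with planted functional structure and masked ground
# truth, so every pipeline stage is testable offline.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for the synthetic data generator
#'
#' Presets fix the study conditions: `strong` plants a nearly clean
#' monotone relationship between true functional similarity and every
#' evidence channel, `noisy` attenuates it and raises channel noise, and
#' `null` removes it entirely (channels independent of the truth).  All
#' counts and rates are overridable.
#'
#' @param preset one of "strong", "noisy", "null".
#' @param seed integer seed; generation is fully deterministic under it.
#' @param n_proteins number of proteins.
#' @param n_terms ontology size across the three namespaces.
#' @param max_depth maximum ontology depth (>= 9 so the deep oversampling
#'   strata are exercised).
#' @param n_families number of planted functional families.
#' @param puf_fraction fraction of proteins masked to roots (the PUFs).
#' @param alpha signal strength in \[0, 1\] coupling channel scores to the
#'   pair's true deepest-shared depth.
#' @param noise_sd channel noise standard deviation.
#' @param tm_coupling coupling of structure-search hit annotations to the
#'   query truth as TM-score grows.
#' @param source_dropout per-source annotation dropout rate.
#' @param n_foreign size of the foreign protein pool for structure hits.
#' @param hits_per_query mean structure-search hits per query.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(preset = c("strong", "noisy", "null"),
                            seed = 1L,
                            n_proteins = NULL, n_terms = 150L,
                            max_depth = 9L, n_families = NULL,
                            puf_fraction = 0.2,
                            alpha = NULL, noise_sd = NULL,
                            tm_coupling = NULL,
                            source_dropout = 0.25,
                            n_foreign = 120L,
                            hits_per_query = 5) {
  preset <- match.arg(preset)
  def <- switch(preset,
    strong = list(n_proteins = 250L, n_families = 25L, alpha = 1.0,
                  noise_sd = 0.08, tm_coupling = 1.0),
    noisy  = list(n_proteins = 160L, n_families = 20L, alpha = 0.5,
                  noise_sd = 0.25, tm_coupling = 0.5),
    null   = list(n_proteins = 160L, n_families = 20L, alpha = 0.0,
                  noise_sd = 0.25, tm_coupling = 0.0))
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    n_proteins = n_proteins %||% def$n_proteins,
    n_terms = n_terms, max_depth = max_depth,
    n_families = n_families %||% def$n_families,
    puf_fraction = puf_fraction,
    alpha = alpha %||% def$alpha,
    noise_sd = noise_sd %||% def$noise_sd,
    tm_coupling = tm_coupling %||% def$tm_coupling,
    source_dropout = source_dropout,
    n_foreign = as.integer(n_foreign),
    hits_per_query = hits_per_query)
  stopifnot(cfg$n_proteins > 0, cfg$n_terms > 0, cfg$alpha >= 0,
            cfg$puf_fraction > 0, cfg$puf_fraction < 1, cfg$max_depth >= 9)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a random three-namespace ontology DAG
#'
#' Each namespace is organized as a set of separate chains descending from
#' its root, so that the deep parts of different branches share no
#' ancestors below the top levels (mirroring how distinct biological
#' processes occupy distinct deep subtrees).  Leftover term budget is
#' attached as branch-local leaves.  Occasional second parents are drawn
#' from the top two levels only, guaranteeing diamonds without collapsing
#' deep branches into one another.  The deepest chain of the largest
#' namespace reaches `max_depth` exactly, and depth equals the
#' construction level because every term keeps a parent one level up.
#'
#' @param config a `SyntheticConfig` (the global seed is NOT set here;
#'   [simulateData()] seeds once for the whole dataset).
#' @return list: `graph` (an [OntologyGraph-class]), `term_count`,
#'   `edge_count`, `diamond`.
#' @export
makeOntology <- function(config) {
  ns_names <- c("biological_process", "molecular_function",
                "cellular_component")
  ns_share <- c(0.6, 0.3, 0.1)
  n_chains <- c(10L, 5L, 2L)
  n <- config$n_terms
  sizes <- pmax(c(round(ns_share[1:2] * n),
                  n - sum(round(ns_share[1:2] * n))), config$max_depth + 2)

  ids <- character(); namespace <- character()
  parents <- list(); level <- integer()
  diamond_placed <- FALSE
  counter <- 0L
  newId <- function() {
    counter <<- counter + 1L
    sprintf("T:%04d", counter)
  }
  for (k in seq_along(ns_names)) {
    maxd <- if (k == 1) config$max_depth else min(config$max_depth, 6L)
    root <- newId()
    ids <- c(ids, root); namespace[root] <- ns_names[k]
    parents[[root]] <- character(); level[root] <- 0L
    budget <- sizes[k] - 1L
    ns_terms <- root
    # chains: the first reaches maxd, the rest random depths
    depths <- c(maxd, pmin(maxd, 3L + rpois(n_chains[k] - 1L, 3)))
    for (ci in seq_len(n_chains[k])) {
      if (budget <= 0) break
      prev <- root
      for (d in seq_len(depths[ci])) {
        if (budget <= 0) break
        t <- newId()
        ids <- c(ids, t); namespace[t] <- ns_names[k]
        parents[[t]] <- prev; level[t] <- d
        ns_terms <- c(ns_terms, t)
        prev <- t
        budget <- budget - 1L
      }
    }
    # leftover budget: leaves under random existing terms (branch-local)
    while (budget > 0) {
      host <- sample(ns_terms[level[ns_terms] < maxd], 1L)
      t <- newId()
      ids <- c(ids, t); namespace[t] <- ns_names[k]
      parents[[t]] <- host; level[t] <- level[host] + 1L
      ns_terms <- c(ns_terms, t)
      budget <- budget - 1L
    }
    # diamonds: second parents from the top two levels only
    shallow <- ns_terms[level[ns_terms] %in% c(1L, 2L)]
    deeper <- ns_terms[level[ns_terms] >= 3L]
    for (t in deeper) {
      cand <- shallow[level[shallow] < level[t] &
                        !(shallow %in% parents[[t]])]
      if (length(cand) && (runif(1) < 0.2 || (k == 1 && !diamond_placed))) {
        parents[[t]] <- c(parents[[t]], sample(cand, 1L))
        diamond_placed <- TRUE
      }
    }
  }
  graph <- makeOntologyGraph(ids, namespace[ids], parents)
  list(graph = graph, term_count = length(ids),
       edge_count = sum(lengths(parents)), diamond = diamond_placed)
}

#' Write an OntologyGraph as an OBO 1.2 file
#'
#' @param graph an [OntologyGraph-class].
#' @param path output path.
#' @param n_obsolete number of obsolete decoy terms to append (they must
#'   be ignored by the loader).
#' @return invisibly, the path.
#' @export
writeOntologyObo <- function(graph, path, n_obsolete = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in graph@termIds) {
    pl <- graph@parents[[t]]
    block <- c("[Term]", paste0("id: ", t), paste0("name: synthetic ", t),
               paste0("namespace: ", graph@namespace[[t]]),
               if (length(pl)) paste0("is_a: ", pl), "")
    writeLines(block, con)
  }
  for (i in seq_len(n_obsolete)) {
    writeLines(c("[Term]", sprintf("id: T:OBS%02d", i),
                 "name: obsolete decoy",
                 "namespace: biological_process",
                 "is_obsolete: true", ""), con)
  }
  invisible(path)
}

#' Generate the annotated proteome, source tables and masked ground truth
#'
#' Each protein joins a functional family anchored at a deep term; its true
#' annotation is the ancestor closure of the family anchor plus a few
#' random extra terms.  Four overlapping source tables are emitted with
#' per-source dropout, one of them score-bearing (NetGO-like, scores in
#' \[0.5, 1\] so some fail the 0.9 filter).  A `puf_fraction` subset of
#' proteins is masked to its namespace roots (making them PUFs by the
#' depth-below-two rule) while the truth is retained for the evaluator.
#'
#' @param config a `SyntheticConfig`.
#' @param graph the [OntologyGraph-class] from [makeOntology()].
#' @return list: `truth` (GroundTruth: truth_store, masked, family,
#'   lengths), `source_tables` (named list of data.frames),
#'   `public_store` (merged + closed), `proteins`, `pufs`, `pkfs`.
#' @export
makeProteome <- function(config, graph) {
  n <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(n))
  depths <- termDepth(graph)
  deep_terms <- names(depths)[depths >= 6]
  deepest_terms <- names(depths)[depths >= 9]
  anchors <- c(sample(deepest_terms, min(5, length(deepest_terms))),
               sample(deep_terms, config$n_families,
                      replace = length(deep_terms) < config$n_families))
  anchors <- anchors[seq_len(config$n_families)]
  family <- sample(seq_len(config$n_families), n, replace = TRUE)

  true_sets <- lapply(seq_len(n), function(i) {
    extra <- sample(graph@termIds, rpois(1, 2))
    ancestralClosure(graph, unique(c(anchors[family[i]], extra)))
  })
  names(true_sets) <- proteins

  masked <- sort(sample(proteins, round(config$puf_fraction * n)))
  public_sets <- true_sets
  for (p in masked) {
    ns <- unique(graph@namespace[true_sets[[p]]])
    public_sets[[p]] <- unname(graph@roots[ns])
  }

  # direct (pre-closure) assignments feed the source tables
  direct_sets <- lapply(proteins, function(p) {
    s <- public_sets[[p]]
    # report the deepest terms; parents are implied by closure
    keep <- vapply(s, function(t)
      !any(t %in% unlist(graph@ancestors[setdiff(s, t)], use.names = FALSE)),
      logical(1))
    s[keep]
  })
  names(direct_sets) <- proteins
  base <- data.frame(
    protein_id = rep(proteins, lengths(direct_sets)),
    term_id = unlist(direct_sets, use.names = FALSE))

  src_names <- c("biocyc", "pgdb", "uniprot", "netgo")
  source_tables <- lapply(src_names, function(s) {
    keep <- runif(nrow(base)) > config$source_dropout
    tb <- base[keep, , drop = FALSE]
    if (s == "netgo") tb$score <- runif(nrow(tb), 0.5, 1)
    rownames(tb) <- NULL
    tb
  })
  names(source_tables) <- src_names
  public_store <- suppressWarnings(
    mergeAnnotationSources(source_tables, graph, netgo_cutoff = 0.9))

  # protein lengths: masked proteins drawn shorter, echoing the tendency
  # of unknown-function proteins to be short
  lengths_aa <- integer(n); names(lengths_aa) <- proteins
  is_masked <- proteins %in% masked
  lengths_aa[is_masked] <- pmax(50L, round(stats::rlnorm(sum(is_masked),
                                                         log(110), 0.35)))
  lengths_aa[!is_masked] <- pmax(50L, round(stats::rlnorm(sum(!is_masked),
                                                          log(250), 0.35)))

  truth_store <- newAnnotationStore(data.frame(
    protein_id = rep(proteins, lengths(true_sets)),
    term_id = unlist(true_sets, use.names = FALSE),
    source = "truth", score = NA_real_, via_closure = FALSE), closed = TRUE)

  pufs <- proteins[vapply(proteins, function(p)
    classifyPuf(graph, proteinTerms(public_store, p)) == "PUF", logical(1)) |
    !(proteins %in% proteinIds(public_store))]

  list(truth = list(truth_store = truth_store, masked = masked,
                    family = setNames(family, proteins),
                    lengths = lengths_aa, anchors = anchors),
       source_tables = source_tables, public_store = public_store,
       proteins = proteins, pufs = pufs, pkfs = setdiff(proteins, pufs))
}

#' Generate all within-species similarity channels
#'
#' Every channel score is a channel-appropriate transform of
#' `alpha * s + noise`, where `s` is the pair's true deepest-shared depth
#' scaled to \[0, 1\]: binary for operon co-membership, sparse
#' \[0, 1\]-scaled link lists for STRING, rank-preserving latent condition
#' profiles shared within families for the quantification matrices, and
#' pLDDT profiles with low-confidence termini for the structures.  At
#' `alpha = 0` every channel is independent of the truth.
#'
#' @param config a `SyntheticConfig`.
#' @param graph the ontology.
#' @param proteome output of [makeProteome()].
#' @return list: `channels` (ready for [assemblePairFeatures()]),
#'   `structures` (per-protein pLDDT vectors), `sequences` (named
#'   character), `pair_signal` (data.frame protein_a, protein_b, depth, s).
#' @export
makeSimilarityChannels <- function(config, graph, proteome) {
  proteins <- proteome$proteins
  n <- length(proteins)
  al <- config$alpha; nsd <- config$noise_sd
  depths <- termDepth(graph)
  sets <- proteinTermSets(proteome$truth$truth_store)

  idx <- utils::combn(proteins, 2)
  pairs <- data.frame(protein_a = idx[1, ], protein_b = idx[2, ])
  d <- mapply(function(a, b) {
    sh <- intersect(sets[[a]], sets[[b]])
    if (!length(sh)) 0L else max(depths[sh])
  }, pairs$protein_a, pairs$protein_b)
  s <- d / config$max_depth
  np <- nrow(pairs)

  sig <- function() clamp(al * s + rnorm(np, 0, nsd), 0, 1)

  # bitscore: DIAMOND-like sparse table
  bit_raw <- sig()
  bit_keep <- bit_raw > 0.2
  bitscore <- data.frame(protein_a = pairs$protein_a[bit_keep],
                         protein_b = pairs$protein_b[bit_keep],
                         value = round(50 + 450 * bit_raw[bit_keep], 1))

  # operon co-membership: binary, only deep pairs likely
  p_op <- stats::plogis(10 * (al * s - 0.8))
  op_flag <- rbinom(np, 1, p_op)
  operon <- data.frame(protein_a = pairs$protein_a[op_flag == 1],
                       protein_b = pairs$protein_b[op_flag == 1],
                       value = rep(1, sum(op_flag == 1)))

  # orthogroups: same family -> same orthogroup when signal present
  n_og <- config$n_families
  og_pool <- sprintf("OG%03d", seq_len(n_og))
  species_pool <- sprintf("sp%02d", 1:40)
  og_species <- lapply(og_pool, function(o)
    sample(species_pool, 10 + rpois(1, 10)))
  names(og_species) <- og_pool
  fam <- proteome$truth$family
  take_fam <- runif(n) < clamp(0.2 + 0.75 * al, 0, 1)
  membership <- ifelse(take_fam, og_pool[fam[proteins]],
                       sample(og_pool, n, replace = TRUE))
  names(membership) <- proteins
  orthogroups <- list(membership = membership, species = og_species)

  # tree distance: Robinson-Foulds-like, small means similar
  tree_distance <- data.frame(
    protein_a = pairs$protein_a, protein_b = pairs$protein_b,
    value = clamp(1 - al * s + rnorm(np, 0, nsd), 0, 2))

  # STRING: sparse link list, sub-scores on the 0-1000 scale
  reg <- defaultFeatureRegistry()
  sub_cols <- sub("^string_", "", grep("^string_", reg$feature, value = TRUE))
  comb <- sig()
  str_keep <- comb > 0.15
  string <- data.frame(protein1 = pairs$protein_a[str_keep],
                       protein2 = pairs$protein_b[str_keep])
  string$combined_score <- comb[str_keep]
  for (sc in sub_cols) {
    u <- runif(1, 0.5, 1)
    string[[sc]] <- clamp(u * al * s[str_keep] +
                            rnorm(sum(str_keep), 0, nsd), 0, 1)
  }
  # also emit the two excluded sub-scores so the exclusion rule is exercised
  string$coexpression <- clamp(rnorm(sum(str_keep), 0.2, 0.1), 0, 1)
  string$experiments <- clamp(rnorm(sum(str_keep), 0.2, 0.1), 0, 1)

  # motif matrix: family-private features plus background features
  n_bg <- 30L
  feat_ids <- c(sprintf("FAM%03d_%d", rep(seq_len(config$n_families), each = 3),
                        rep(1:3, config$n_families)),
                sprintf("BG%03d", seq_len(n_bg)))
  mat <- matrix(0L, n, length(feat_ids),
                dimnames = list(proteins, feat_ids))
  p_member <- clamp(0.05 + 0.8 * al, 0, 0.9)
  for (i in seq_len(n)) {
    fam_feats <- sprintf("FAM%03d_%d", fam[proteins[i]], 1:3)
    mat[i, fam_feats] <- rbinom(3, 1, p_member)
    other <- setdiff(grep("^FAM", feat_ids, value = TRUE), fam_feats)
    mat[i, other] <- rbinom(length(other), 1, 0.02)
    mat[i, grep("^BG", feat_ids)] <- rbinom(n_bg, 1, 0.1)
  }
  mat <- mat[, colSums(mat) > 0, drop = FALSE]

  # quant experiments: latent family profiles shared by similar proteins
  n_exp <- 3L
  n_cond <- c(5L, 6L, 5L)
  quant <- vector("list", n_exp)
  for (e in seq_len(n_exp)) {
    fam_prof <- matrix(stats::rlnorm(config$n_families * n_cond[e], 0, 1),
                       config$n_families, n_cond[e])
    ind_prof <- matrix(stats::rlnorm(n * n_cond[e], 0, 1), n, n_cond[e])
    prof <- al * fam_prof[fam[proteins], , drop = FALSE] +
      (1 - al) * ind_prof
    present <- runif(n) > 0.2
    samp_per_cond <- 2L
    m <- matrix(0, sum(present), n_cond[e] * samp_per_cond)
    rownames(m) <- proteins[present]
    cond_lab <- rep(sprintf("c%d", seq_len(n_cond[e])), each = samp_per_cond)
    colnames(m) <- sprintf("s%02d", seq_along(cond_lab))
    for (j in seq_len(ncol(m))) {
      cc <- as.integer(sub("c", "", cond_lab[j]))
      v <- prof[present, cc] * exp(rnorm(sum(present), 0, 0.2))
      v[runif(sum(present)) < 0.1] <- 0   # sample-level dropout
      m[, j] <- v
    }
    quant[[e]] <- quantExperiment(m, setNames(cond_lab, colnames(m)),
                                  id = sprintf("exp%d", e))
  }

  # sequences and structures with pLDDT profiles
  aa <- aminoAlphabet()[1:20]
  lens <- proteome$truth$lengths
  sequences <- vapply(proteins, function(p)
    paste(sample(aa, lens[[p]], replace = TRUE), collapse = ""), character(1))
  structures <- lapply(proteins, function(p) {
    L <- lens[[p]]
    lead <- rpois(1, 3); tail <- rpois(1, 3)
    pl <- clamp(rnorm(L, 82, 6), 0, 100)
    if (lead > 0) pl[seq_len(min(lead, L))] <- clamp(rnorm(min(lead, L), 50, 5), 0, 100)
    if (tail > 0) pl[L - seq_len(min(tail, L)) + 1] <-
        clamp(rnorm(min(tail, L), 50, 5), 0, 100)
    if (runif(1) < 0.03) pl[] <- clamp(rnorm(L, 55, 5), 0, 100)  # rejected
    pl
  })
  names(structures) <- proteins

  # within-species TM table over kept structures
  kept <- vapply(structures, function(pl) trimStructure(pl)$kept, logical(1))
  kp <- pairs$protein_a %in% proteins[kept] &
        pairs$protein_b %in% proteins[kept]
  tm_a <- clamp(al * s + rnorm(np, 0, nsd), 0, 1)
  tm_b <- clamp(tm_a + rnorm(np, 0, 0.04), 0, 1)
  structure_tm <- data.frame(
    protein_a = pairs$protein_a[kp], protein_b = pairs$protein_b[kp],
    tm_a = tm_a[kp], tm_b = tm_b[kp],
    rmsd = clamp(8 * (1 - al * s[kp]) + rnorm(sum(kp), 0, 1), 0.3, 15))

  channels <- list(
    motifs = list(matrix = mat),
    bitscore = bitscore, operon = operon, tree_distance = tree_distance,
    orthogroups = orthogroups, quant = quant,
    structure_tm = structure_tm, string = selectStringScores(string))

  list(channels = channels, structures = structures, sequences = sequences,
       pair_signal = data.frame(pairs, depth = d, s = s))
}

#' Generate structure-search hit tables from a foreign protein pool
#'
#' Hits are drawn from a synthetic foreign pool; with probability growing
#' in the drawn TM-score (scaled by `tm_coupling`), a hit's annotations
#' are taken from the query's true annotation set (always including the
#' query's deepest true term), otherwise from a random foreign protein.
#' Hit sequences are mutated copies of the query with identity correlated
#' to TM; lineages share a random number of levels with the query so all
#' taxonomic ranks are exercised.  TM-scores at or below 0.3 occur and
#' must be removed by the arm's filter.
#'
#' @param config a `SyntheticConfig`.
#' @param graph the ontology.
#' @param proteome output of [makeProteome()].
#' @param sequences named character vector of query sequences.
#' @return list: `hits` (data.frame with list-columns lineage, terms),
#'   `query_lineage` (character(7)).
#' @export
makeStructureHits <- function(config, graph, proteome, sequences) {
  proteins <- proteome$proteins
  depths <- termDepth(graph)
  sets <- proteinTermSets(proteome$truth$truth_store)
  aa <- aminoAlphabet()[1:20]

  # foreign pool annotations
  foreign <- sprintf("F%04d", seq_len(config$n_foreign))
  f_sets <- lapply(foreign, function(f)
    ancestralClosure(graph, sample(graph@termIds, 2 + rpois(1, 2))))
  names(f_sets) <- foreign

  ranks <- taxonomicRanks()
  query_lineage <- c("putida_like", "PseudoGenus", "PseudoFam", "PseudoOrd",
                     "GammaClass", "ProteoPhylum", "Bacteria")
  randLineage <- function(n_shared) {
    lin <- paste0("tax_", sample(letters, 7, replace = TRUE),
                  sample(999, 7))
    if (n_shared > 0)
      lin[(7 - n_shared + 1):7] <- query_lineage[(7 - n_shared + 1):7]
    lin
  }

  rows <- lapply(proteins, function(q) {
    nh <- 1 + rpois(1, config$hits_per_query)
    qs <- sequences[[q]]
    qchars <- strsplit(qs, "")[[1]]
    qset <- sets[[q]]
    deepest <- qset[which.max(depths[qset])]
    do.call(rbind, lapply(seq_len(nh), function(i) {
      tm <- round(runif(1, 0.1, 0.98), 3)
      # annotation-truth coupling rises steeply with TM (a high-TM analog
      # near-certainly shares function when coupling is strong); exactly
      # zero coupling probability when tm_coupling is 0 (null preset)
      coupled <- runif(1) < config$tm_coupling *
        stats::plogis(30 * (tm - 0.40))
      if (coupled && config$tm_coupling > 0) {
        terms <- unique(c(deepest, sample(qset, min(3, length(qset)))))
        terms <- ancestralClosure(graph, terms)
      } else {
        terms <- f_sets[[sample(foreign, 1)]]
      }
      # functional analogs are homologs (identity tracks TM); uncoupled
      # matches are remote folds with additionally divergent sequence
      base_mut <- 1 - 0.9 * tm
      mut_rate <- if (coupled) base_mut else
        min(0.9, base_mut + 0.4 * config$tm_coupling)
      mut <- runif(length(qchars)) < mut_rate
      hchars <- qchars
      hchars[mut] <- sample(aa, sum(mut), replace = TRUE)
      if (runif(1) < 0.3) {   # occasional deletion so alignments gap
        dl <- sample(length(hchars) %/% 4, 1)
        st <- sample(length(hchars) - dl, 1)
        hchars <- hchars[-(st:(st + dl - 1))]
      }
      data.frame(query_id = q, hit_id = sample(foreign, 1),
                 tm_score = tm,
                 rmsd = round(clamp(8 * (1 - tm) + rnorm(1, 0, 0.8),
                                    0.3, 15), 2),
                 hit_sequence = paste(hchars, collapse = ""),
                 lineage = I(list(randLineage(sample(0:7, 1)))),
                 terms = I(list(terms)))
    }))
  })
  list(hits = do.call(rbind, rows), query_lineage = query_lineage)
}

#' Generate a complete in-memory synthetic dataset
#'
#' Seeds once and produces, deterministically, the ontology, the annotated
#' proteome with four source tables and masked ground truth, every
#' within-species similarity channel and the structure-search hit table.
#'
#' @param config a `SyntheticConfig` from [syntheticConfig()].
#' @return list of class `SyntheticData` with elements graph, onto_meta,
#'   truth, source_tables, public_store, proteins, pufs, pkfs, channels,
#'   structures, sequences, pair_signal, structure_hits, query_lineage,
#'   config.
#' @export
simulateData <- function(config) {
  set.seed(config$seed)
  onto <- makeOntology(config)
  proteome <- makeProteome(config, onto$graph)
  chan <- makeSimilarityChannels(config, onto$graph, proteome)
  sh <- makeStructureHits(config, onto$graph, proteome, chan$sequences)
  out <- c(list(graph = onto$graph,
                onto_meta = onto[c("term_count", "edge_count", "diamond")]),
           proteome,
           chan,
           list(structure_hits = sh$hits, query_lineage = sh$query_lineage,
                config = config))
  class(out) <- "SyntheticData"
  out
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits the OBO ontology, per-source annotation TSVs, pair-score TSVs,
#' a STRING-style link table, quantification CSVs with sample maps, a
#' motif matrix TSV, CA-only PDB files with pLDDT in the B-factor column,
#' a FASTA of query sequences, the structure-hit TSV, the ground truth
#' (for the evaluator only) and a manifest JSON recording the
#' configuration and file checksums.  Byte-identical across runs with the
#' same config.
#'
#' @param sim a `SyntheticData` object (or a `SyntheticConfig`, which is
#'   simulated first).
#' @param outdir output directory (created).
#' @param write_pdb also write per-protein PDB files (default TRUE).
#' @return invisibly, the manifest as a list.
#' @export
simulateDataset <- function(sim, outdir, write_pdb = TRUE) {
  if (inherits(sim, "SyntheticConfig")) sim <- simulateData(sim)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)

  writeOntologyObo(sim$graph, fp("ontology.obo"), n_obsolete = 2L)
  for (s in names(sim$source_tables))
    write.table(sim$source_tables[[s]], fp(sprintf("annotations_%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (ch in c("bitscore", "operon", "tree_distance"))
    write.table(sim$channels[[ch]], fp(paste0(ch, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  str_out <- sim$channels$string
  num <- setdiff(names(str_out), c("protein_a", "protein_b",
                                   "protein1", "protein2"))
  str_out[num] <- lapply(str_out[num], function(v) as.integer(round(v * 1000)))
  write.table(str_out, fp("string_links.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mm <- sim$channels$motifs$matrix
  write.table(data.frame(protein_id = rep(rownames(mm), ncol(mm)),
                         feature_id = rep(colnames(mm), each = nrow(mm)),
                         present = as.integer(mm))[as.logical(mm), 1:2],
              fp("motif_features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  og <- sim$channels$orthogroups
  write.table(data.frame(protein_id = names(og$membership),
                         orthogroup = unname(og$membership)),
              fp("orthogroup_membership.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(
      orthogroup = rep(names(og$species), lengths(og$species)),
      species = unlist(og$species, use.names = FALSE)),
    fp("orthogroup_species.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (e in seq_along(sim$channels$quant)) {
    q <- sim$channels$quant[[e]]
    utils::write.csv(as.data.frame(q$intensities),
                     fp(sprintf("quant_%d.csv", e)))
    write.table(data.frame(sample = names(q$sample_condition),
                           condition = unname(q$sample_condition)),
                fp(sprintf("samples_%d.tsv", e)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sim$channels$structure_tm, fp("structure_tm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seqs <- sim$sequences
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fp("sequences.fasta"))
  if (write_pdb) {
    dir.create(fp("pdb"), showWarnings = FALSE)
    for (p in names(sim$structures))
      writeSyntheticPdb(sim$structures[[p]], fp("pdb", paste0(p, ".pdb")))
  }
  writeStructureHits(sim$structure_hits, fp("structure_hits.tsv"))
  # ground truth: for the evaluator only, never a pipeline input
  writeAnnotationStore(sim$truth$truth_store, fp("ground_truth.tsv"))
  writeLines(sim$truth$masked, fp("masked_proteins.txt"))

  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(config = unclass(sim$config),
                   files = as.list(tools::md5sum(fp(files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Write a CA-only PDB file with pLDDT in the B-factor column
#'
#' @param plddt numeric vector of per-residue pLDDT values.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSyntheticPdb <- function(plddt, path) {
  n <- length(plddt)
  # simple extended-chain coordinates; geometry is irrelevant here
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), seq_len(n), 3.8 * seq_len(n), 0, 0, 1.00, plddt)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Evaluate a predicted annotation store against the masked ground truth
#'
#' A prediction is false when the term is absent from the protein's closed
#' true annotation set.  Recall is measured over the masked proteins' true
#' terms at depth >= 2 (roots and near-roots are uninformative).  A
#' per-depth breakdown accompanies the totals.
#'
#' @param predicted_store a closed [AnnotationStore-class] of predictions.
#' @param truth GroundTruth list (element `truth` of [simulateData()]
#'   output).
#' @param graph the ontology.
#' @param proteins restrict evaluation to these proteins (default: the
#'   masked set).
#' @return list: fdr, recall, n_predictions, n_false, per_depth
#'   (data.frame depth, n_pred, n_false, n_true_terms, n_recovered),
#'   flagged (TRUE when there were no predictions to assess).
#' @export
evaluateAgainstTruth <- function(predicted_store, truth, graph,
                                 proteins = truth$masked) {
  depths <- termDepth(graph)
  true_sets <- proteinTermSets(truth$truth_store)
  pa <- unique(predicted_store@assignments[, c("protein_id", "term_id")])
  pa <- pa[pa$protein_id %in% proteins, , drop = FALSE]

  if (!nrow(pa)) {
    return(list(fdr = NA_real_, recall = 0, n_predictions = 0L,
                n_false = 0L, per_depth = NULL, flagged = TRUE))
  }
  is_false <- !mapply(function(p, t) t %in% true_sets[[p]],
                      pa$protein_id, pa$term_id)
  dp <- unname(depths[pa$term_id])

  truth_rows <- do.call(rbind, lapply(proteins, function(p) {
    tt <- true_sets[[p]]
    tt <- tt[depths[tt] >= 2]
    if (!length(tt)) return(NULL)
    data.frame(protein_id = p, term_id = tt)
  }))
  pred_key <- paste(pa$protein_id, pa$term_id)
  recovered <- paste(truth_rows$protein_id, truth_rows$term_id) %in% pred_key
  td <- unname(depths[truth_rows$term_id])

  per_depth <- merge(
    aggregate(cbind(n_pred = rep(1, nrow(pa)), n_false = is_false),
              by = list(depth = dp), FUN = sum),
    aggregate(cbind(n_true_terms = rep(1, nrow(truth_rows)),
                    n_recovered = recovered),
              by = list(depth = td), FUN = sum),
    by = "depth", all = TRUE)

  list(fdr = sum(is_false) / nrow(pa),
       recall = sum(recovered) / nrow(truth_rows),
       n_predictions = nrow(pa), n_false = sum(is_false),
       per_depth = per_depth, flagged = FALSE)
}
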