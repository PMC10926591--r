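smallCfg <- function(preset = "strong", seed = 5, ...)
  syntheticConfig(preset, seed = seed, n_proteins = 60, n_terms = 80,
                  n_foreign = 40, ...)

test_that("generation is fully deterministic under the seed", {
  s1 <- simulateData(smallCfg())
  s2 <- simulateData(smallCfg())
  expect_identical(s1$pair_signal, s2$pair_signal)
  expect_identical(annotationTable(s1$truth$truth_store),
                   annotationTable(s2$truth$truth_store))
  expect_identical(s1$channels$structure_tm, s2$channels$structure_tm)
  expect_identical(s1$structure_hits$hit_sequence,
                   s2$structure_hits$hit_sequence)
  s3 <- simulateData(smallCfg(seed = 6))
  expect_false(identical(s1$pair_signal$depth, s3$pair_signal$depth))
})

test_that("written datasets are byte-identical across runs", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- smallCfg(seed = 11)
  m1 <- simulateDataset(cfg, d1, write_pdb = FALSE)
  m2 <- simulateDataset(cfg, d2, write_pdb = FALSE)
  expect_identical(unname(unlist(m1$files)), unname(unlist(m2$files)))
})

test_that("written dataset files round-trip through the package readers", {
  d <- file.path(tempdir(), "simRT")
  unlink(d, recursive = TRUE)
  cfg <- smallCfg(seed = 31)
  sim <- simulateData(cfg)
  simulateDataset(sim, d, write_pdb = TRUE)

  g <- loadOntology(file.path(d, "ontology.obo"))
  expect_setequal(termIds(g), termIds(sim$graph))

  ann <- readAnnotationTable(file.path(d, "annotations_netgo.tsv"))
  expect_setequal(names(ann), c("protein_id", "term_id", "score"))
  expect_equal(nrow(ann), nrow(sim$source_tables$netgo))

  strl <- readStringLinks(file.path(d, "string_links.txt"))
  expect_true(all(strl$combined_score >= 0 & strl$combined_score <= 1))

  q <- readQuantExperiment(file.path(d, "quant_1.csv"),
                           file.path(d, "samples_1.tsv"))
  expect_equal(q$intensities, sim$channels$quant[[1]]$intensities,
               tolerance = 1e-12)

  seqs <- readQuerySequences(file.path(d, "sequences.fasta"))
  expect_identical(seqs[names(sim$sequences)], sim$sequences)

  hits <- readStructureHits(file.path(d, "structure_hits.tsv"))
  expect_equal(nrow(hits), nrow(sim$structure_hits))
  expect_identical(hits$terms[[1]], sim$structure_hits$terms[[1]])

  p1 <- names(sim$structures)[1]
  expect_equal(readResidueConfidence(file.path(d, "pdb", paste0(p1, ".pdb"))),
               round(sim$structures[[p1]], 2), tolerance = 0.005)
  unlink(d, recursive = TRUE)
})

test_that("synthetic ontology reaches max depth, has a diamond, round-trips", {
  set.seed(3)
  onto <- makeOntology(syntheticConfig("strong", seed = 3))
  d <- termDepth(onto$graph)
  expect_equal(max(d), 9)
  expect_true(onto$diamond)
  expect_true(any(vapply(onto$graph@parents, length, integer(1)) > 1))
  # acyclicity is enforced by construction (topological sort succeeds)
  expect_s4_class(onto$graph, "OntologyGraph")

  f <- tempfile(fileext = ".obo")
  writeOntologyObo(onto$graph, f, n_obsolete = 2)
  back <- loadOntology(f)
  expect_equal(length(termIds(back)), onto$term_count)
  expect_equal(sum(lengths(back@parents)), onto$edge_count)
  expect_identical(termDepth(back)[termIds(onto$graph)],
                   termDepth(onto$graph))
})

test_that("masked proteins are PUFs and unmasked deep proteins are PKFs", {
  sim <- simulateData(smallCfg())
  g <- sim$graph
  for (p in sim$truth$masked[1:5])
    expect_equal(classifyPuf(g, proteinTerms(sim$public_store, p)), "PUF")
  expect_true(all(sim$truth$masked %in% sim$pufs))
  # the truth of a masked protein is deep (anchored at depth >= 6)
  deep <- vapply(sim$truth$masked, function(p)
    max(termDepth(g)[proteinTerms(sim$truth$truth_store, p)]), numeric(1))
  expect_true(all(deep >= 6))
  pkf_sample <- setdiff(sim$pkfs, sim$truth$masked)[1:5]
  for (p in pkf_sample)
    expect_equal(classifyPuf(g, proteinTerms(sim$public_store, p)), "PKF")
})

test_that("merged store matches set algebra over the emitted source tables", {
  sim <- simulateData(smallCfg())
  direct <- annotationTable(sim$public_store)
  direct <- direct[!direct$via_closure, ]
  for (src in names(sim$source_tables)) {
    tb <- sim$source_tables[[src]]
    if (!is.null(tb$score)) tb <- tb[tb$score > 0.9, ]
    got <- direct[direct$source == src, ]
    expect_setequal(paste(got$protein_id, got$term_id),
                    unique(paste(tb$protein_id, tb$term_id)))
  }
})

test_that("null preset channels are independent of the planted truth", {
  sim <- simulateData(smallCfg("null", seed = 21))
  s <- sim$pair_signal$s
  # dense channel: tree distance should not track shared depth
  expect_lt(abs(cor(sim$channels$tree_distance$value, s,
                    method = "spearman")), 0.06)
  tm <- sim$channels$structure_tm
  key_all <- paste(sim$pair_signal$protein_a, sim$pair_signal$protein_b)
  s_tm <- s[match(paste(tm$protein_a, tm$protein_b), key_all)]
  expect_lt(abs(cor(pmax(tm$tm_a, tm$tm_b), s_tm, method = "spearman")),
            0.06)
})

test_that("strong preset plants a monotone channel-depth relationship", {
  sim <- simulateData(smallCfg("strong", seed = 22))
  s <- sim$pair_signal$s
  expect_lt(cor(sim$channels$tree_distance$value, s, method = "spearman"),
            -0.8)
  tm <- sim$channels$structure_tm
  key_all <- paste(sim$pair_signal$protein_a, sim$pair_signal$protein_b)
  s_tm <- s[match(paste(tm$protein_a, tm$protein_b), key_all)]
  expect_gt(cor(pmax(tm$tm_a, tm$tm_b), s_tm, method = "spearman"), 0.8)
})

test_that("same-family pairs co-express more than unrelated pairs at high alpha", {
  sim <- simulateData(smallCfg("strong", seed = 23))
  fam <- sim$truth$family
  ps <- sim$pair_signal
  same <- fam[ps$protein_a] == fam[ps$protein_b]
  cf <- coexpressionFeatures(sim$channels$quant, ps[, 1:2])
  expect_gt(mean(cf$mean_spearman[same]), mean(cf$mean_spearman[!same]) + 0.3)
})

test_that("high-TM structure hits share the query's deepest term under coupling", {
  sim <- simulateData(syntheticConfig("strong", seed = 24, n_proteins = 80,
                                      n_terms = 100))
  hits <- sim$structure_hits
  depths <- termDepth(sim$graph)
  sets <- proteinTermSets(sim$truth$truth_store)
  hi <- which(hits$tm_score > 0.9)
  share <- vapply(hi, function(i) {
    q <- sets[[hits$query_id[i]]]
    deepest <- q[which.max(depths[q])]
    deepest %in% hits$terms[[i]]
  }, logical(1))
  expect_gt(mean(share), 0.9)
  # low-TM hits exist and are removed by the arm's filter
  expect_true(any(hits$tm_score <= 0.3))
  expect_true(all(filterStructureHits(hits)$tm_score > 0.3))
  # lineages exercise every rank level
  q_lin <- sim$query_lineage
  ranks <- vapply(seq_len(nrow(hits)), function(i)
    taxonomicRankSimilarity(q_lin, hits$lineage[[i]]), integer(1))
  expect_gt(length(unique(ranks)), 5)
})

test_that("structures expose trimmable low-confidence termini", {
  sim <- simulateData(smallCfg(seed = 25))
  trims <- lapply(sim$structures, trimStructure)
  kept <- vapply(trims, `[[`, logical(1), "kept")
  expect_gt(mean(kept), 0.7)          # most structures survive
  expect_lt(mean(kept), 1)            # some are rejected
  # trimming removed low-confidence leading residues where present
  first_kept <- which(kept)[1]
  tr <- trims[[first_kept]]
  expect_true(all(tr$plddt[1] > 70))
})

test_that("truth evaluation scores FDR and depth-limited recall correctly", {
  g <- chainGraph(4)
  truth_store <- closeStore(newAnnotationStore(data.frame(
    protein_id = c("m1", "m2"), term_id = c("c4", "c3"))), g)
  truth <- list(truth_store = truth_store, masked = c("m1", "m2"))

  # predictions identical to the truth: FDR 0, recall 1
  ev <- evaluateAgainstTruth(truth_store, truth, g)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$recall, 1)

  # root-adjacent predictions only: recall 0 at depth >= 2
  shallow <- closeStore(newAnnotationStore(data.frame(
    protein_id = c("m1", "m2"), term_id = c("c1", "c1"))), g)
  ev2 <- evaluateAgainstTruth(shallow, truth, g)
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$fdr, 0)            # c1/root are in the closed truth

  # hand-built mixture: m1 gets c4 chain (all true) plus nothing false;
  # m2 gets c4 (false: truth is c3) -> closure adds nothing false deeper
  mix <- closeStore(newAnnotationStore(data.frame(
    protein_id = c("m1", "m2"), term_id = c("c4", "c4"))), g)
  ev3 <- evaluateAgainstTruth(mix, truth, g)
  # m1: c4,c3,c2,c1,root all true (5); m2: c4 false, others true (5 preds, 1 false)
  expect_equal(ev3$n_predictions, 10L)
  expect_equal(ev3$n_false, 1L)
  expect_equal(ev3$fdr, 0.1)
  # true deep terms: m1 {c4,c3,c2}, m2 {c3,c2}; recovered: all of m1's,
  # and m2's c3,c2 via closure of the false c4
  expect_equal(ev3$recall, 1)
  # empty predictions are flagged
  empty <- newAnnotationStore(data.frame(protein_id = character(),
                                         term_id = character()),
                              closed = TRUE)
  ev4 <- evaluateAgainstTruth(empty, truth, g)
  expect_true(ev4$flagged)
  expect_equal(ev4$recall, 0)
})
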