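test_that("Shannon weights are -log2 of carrier frequency", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("p", 1:4), c("f_all", "f2", "f1")))
  m[, "f_all"] <- 1L
  m[1:2, "f2"] <- 1L
  m[1, "f1"] <- 1L
  w <- shannonWeights(m)
  expect_equal(unname(w[c("f_all", "f2", "f1")]), c(0, 1, 2))
  m2 <- m; m2[, "f1"] <- 0L
  expect_error(shannonWeights(m2), "zero proteins")
})

test_that("weighted Jaccard distance: bounds, worked case, degenerate case", {
  w <- c(f1 = 1, f2 = 2, f3 = 0)
  expect_equal(weightedJaccardDistance(c("f1", "f2", "f3"), c("f1", "f3"), w),
               2 / 3)
  expect_equal(weightedJaccardDistance(c("f1", "f2"), c("f1", "f2"), w), 0)
  expect_equal(weightedJaccardDistance("f1", "f2", w), 1)
  # all-zero weights: vectors indistinguishable under the weighting
  expect_equal(weightedJaccardDistance("f3", "f3", w), 0)
  # equals unweighted Jaccard when all weights equal
  we <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(weightedJaccardDistance(c("a", "b"), c("b", "c"), we),
               1 - 1 / 3)
  # symmetry and bounds on random sets
  set.seed(1)
  wr <- setNames(runif(6), letters[1:6])
  for (i in 1:10) {
    a <- sample(letters[1:6], sample(1:4, 1))
    b <- sample(letters[1:6], sample(1:4, 1))
    d1 <- weightedJaccardDistance(a, b, wr)
    expect_equal(d1, weightedJaccardDistance(b, a, wr))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

makeExp <- function(mat, id = "e1") {
  # one sample per condition
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  quantExperiment(mat, setNames(paste0("c", seq_len(ncol(mat))),
                                colnames(mat)), id)
}

test_that("condition profiles average nonzero intensities and zero-impute", {
  m <- matrix(c(0, 4, 2, 0, 0, 0), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  e <- quantExperiment(m, setNames(rep(c("c1", "c2", "c3"), each = 2),
                                   colnames(m)), "e")
  prof <- conditionProfiles(e)
  expect_equal(unname(prof["p1", ]), c(4, 2, 0))
})

test_that("co-expression features follow the zero rules and presence Jaccard", {
  m <- rbind(A = c(1, 2, 3), B = c(3, 2, 1))
  pairs <- data.frame(protein_a = "A", protein_b = "B")
  cf <- coexpressionFeatures(list(makeExp(m)), pairs)
  expect_equal(cf$mean_spearman, -1)

  # absent protein: zero correlation
  pairs2 <- data.frame(protein_a = "A", protein_b = "Zz")
  cf2 <- coexpressionFeatures(list(makeExp(m)), pairs2)
  expect_equal(cf2$mean_spearman, 0)
  expect_equal(cf2$coexpr_jaccard, 1)

  # presence in {1,2} vs {2,3} of 3 conditions: distance 2/3
  m3 <- rbind(A = c(5, 5, 0), B = c(0, 5, 5))
  cf3 <- coexpressionFeatures(list(makeExp(m3)), pairs)
  expect_equal(cf3$coexpr_jaccard, 2 / 3)

  # rank-based: invariant to monotone transformation of intensities
  m4 <- rbind(A = c(1, 5, 2, 8), B = c(2, 6, 1, 9))
  cf4a <- coexpressionFeatures(list(makeExp(m4)), pairs)
  cf4b <- coexpressionFeatures(list(makeExp(m4^3)), pairs)
  expect_equal(cf4a$mean_spearman, cf4b$mean_spearman)

  # constant profile maps undefined correlation to zero
  m5 <- rbind(A = c(2, 2, 2), B = c(1, 2, 3))
  expect_equal(coexpressionFeatures(list(makeExp(m5)), pairs)$mean_spearman, 0)

  # correlations averaged across experiments
  cfm <- coexpressionFeatures(list(makeExp(m), makeExp(m4)), pairs)
  expect_equal(cfm$mean_spearman,
               (cf$mean_spearman + cf4a$mean_spearman) / 2)
})

test_that("experiments with fewer than two conditions are rejected at load", {
  m <- matrix(1, 1, 2, dimnames = list("p", c("s1", "s2")))
  expect_error(quantExperiment(m, c(s1 = "c1", s2 = "c1")), ">= 2 conditions")
})

test_that("structure trimming respects strict boundaries", {
  r <- trimStructure(c(rep(50, 5), rep(80, 35)))
  expect_true(r$kept)
  expect_equal(length(r$plddt), 35)
  expect_equal(r$from, 6)

  expect_false(trimStructure(rep(60, 40))$kept)

  r3 <- trimStructure(c(rep(80, 25), rep(60, 10)))
  expect_false(r3$kept)          # 25 retained is not > 30
  expect_equal(r3$to - r3$from + 1, 25)

  # interior low-confidence residues untouched; output contiguous
  pl <- c(40, 80, 50, 50, 80, 40)
  r4 <- trimStructure(pl, min_retained_length = 2)
  expect_equal(r4$plddt, pl[2:5])
})

test_that("pLDDT round-trips through PDB B-factors", {
  pl <- c(45.5, 80.25, 91, 60.75)
  f <- tempfile(fileext = ".pdb")
  writeSyntheticPdb(pl, f)
  expect_equal(readResidueConfidence(f), pl)
})

test_that("TM pair feature is the max normalization, order-invariant", {
  expect_equal(unname(tmPairFeature(0.5, 0.7, 2.1)), c(0.7, 2.1))
  expect_equal(unname(tmPairFeature(0.4, 0.4, 1)), c(0.4, 1))
  expect_equal(tmPairFeature(0.5, 0.7, 2.1), tmPairFeature(0.7, 0.5, 2.1))
  expect_error(tmPairFeature(1.2, 0.5, 1), "TM-score")
})

test_that("orthogroup overlap is the species-set intersection size", {
  og <- list(membership = c(a = "og1", b = "og2", c = "og1"),
             species = list(og1 = c("s1", "s2", "s3"),
                            og2 = c("s2", "s3", "s4")))
  expect_equal(orthogroupOverlap(og, "a", "b"), 2L)
  expect_equal(orthogroupOverlap(og, "a", "c"), 3L)   # same orthogroup
  expect_equal(orthogroupOverlap(og, "a", "zz"), 0L)  # no orthogroup
})

test_that("STRING sub-score selection drops only the excluded channels", {
  df <- data.frame(protein1 = "a", protein2 = "b", combined_score = 0.9,
                   coexpression = 0.5, coexpression_transferred = 0.4,
                   experiments = 0.3, experiments_transferred = 0.2,
                   textmining = 0.1)
  out <- selectStringScores(df)
  expect_false(any(c("coexpression", "experiments") %in% names(out)))
  expect_true(all(c("coexpression_transferred", "experiments_transferred",
                    "textmining", "combined_score") %in% names(out)))
  expect_error(selectStringScores(df[, -3]), "combined_score")
})

test_that("STRING link loader rescales the 0-1000 integer scale", {
  f <- tempfile()
  writeLines(c("protein1\tprotein2\tcombined_score\ttextmining",
               "a\tb\t900\t150"), f)
  df <- readStringLinks(f)
  expect_equal(df$combined_score, 0.9)
  expect_equal(df$textmining, 0.15)
})

test_that("pair feature assembly is registry-complete, symmetric, filled", {
  universe <- c("a", "b", "c", "d")
  channels <- list(
    bitscore = data.frame(protein_a = "a", protein_b = "b", value = 300),
    operon = data.frame(protein_a = "b", protein_b = "a", value = 1))
  ft <- assemblePairFeatures(channels, universe)
  expect_equal(nrow(ft), choose(4, 2))
  reg <- defaultFeatureRegistry()
  expect_true(all(reg$feature %in% names(ft)))

  ab <- ft[ft$protein_a == "a" & ft$protein_b == "b", ]
  expect_equal(ab$bitscore, 300)
  expect_equal(ab$operon, 1)   # reversed order in input still matches

  # evidence-free pair gets the registry fill values
  cd <- ft[ft$protein_a == "c" & ft$protein_b == "d", ]
  fills <- setNames(reg$fill, reg$feature)
  for (f in reg$feature) expect_equal(cd[[f]], unname(fills[f]))

  # querying with swapped pair order yields the identical vector
  ft2 <- assemblePairFeatures(channels, universe,
                              pairs = data.frame(protein_a = "b",
                                                 protein_b = "a"))
  expect_equal(ft2[, reg$feature], ab[, reg$feature],
               ignore_attr = TRUE)

  # foreign ids are dropped with a warning
  channels$bitscore <- rbind(channels$bitscore,
                             data.frame(protein_a = "zz", protein_b = "a",
                                        value = 5))
  expect_warning(assemblePairFeatures(channels, universe), "outside universe")
})
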