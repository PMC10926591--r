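test_that("candidate terms are the union of hit annotations", {
  hs <- list(query = "q",
             hits = data.frame(hit_id = c("P1", "P2"), tm = c(0.5, 0.6)),
             annotations = list(c("X", "Y"), c("Y", "Z")))
  expect_setequal(enumerateCandidates(hs), c("X", "Y", "Z"))
  hs$annotations <- list(character(), character())
  expect_length(enumerateCandidates(hs), 0)
})

test_that("hit summaries compute count/sum/max/mean over term-bearing hits", {
  hs <- tinyHitSet()   # h1: tm .6, h2: tm .8; both annotated with X; Z on h2
  sX <- summarizeHits(hs, "X")
  expect_equal(unname(sX["n_hits"]), 2)
  expect_equal(unname(sX["tm_sum"]), 1.4)
  expect_equal(unname(sX["tm_max"]), 0.8)
  expect_equal(unname(sX["tm_mean"]), 0.7)
  sZ <- summarizeHits(hs, "Z")
  expect_equal(unname(sZ["n_hits"]), 1)
  expect_equal(unname(sZ[c("tm_sum", "tm_max", "tm_mean")]), rep(0.8, 3))
  # invariant to hit ordering
  hs_rev <- hs
  hs_rev$hits <- hs$hits[2:1, ]
  hs_rev$annotations <- hs$annotations[2:1]
  expect_equal(summarizeHits(hs_rev, "X"), sX)
  expect_error(summarizeHits(hs, "nope"), "no hit annotated")
})

test_that("vectorized candidate table equals per-candidate summaries", {
  set.seed(11)
  hit_sets <- lapply(1:5, function(i) {
    nh <- sample(1:6, 1)
    list(query = paste0("q", i),
         hits = data.frame(hit_id = paste0("h", seq_len(nh)),
                           tm = runif(nh), rmsd = runif(nh, 0, 8)),
         annotations = replicate(nh, sample(LETTERS[1:6], sample(1:3, 1)),
                                 simplify = FALSE))
  })
  names(hit_sets) <- paste0("q", 1:5)
  ct <- candidateTable(hit_sets)
  for (r in sample(nrow(ct), 10, replace = TRUE)) {
    hs <- hit_sets[[ct$protein[r]]]
    ref <- summarizeHits(hs, ct$term[r])
    expect_equal(unlist(ct[r, names(ref)]), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("candidate labeling applies the precedence rules and holdout", {
  g <- chainGraph(6)   # root -> c1 ... c6
  st <- closeStore(newAnnotationStore(data.frame(
    protein_id = c("pk", "pt"), term_id = c("c4", "c6"))), g)
  cands <- data.frame(
    protein = c("pk", "pk", "pk", "puf1", "pt"),
    term = c("c4", "c2", "c6", "c3", "c5"),
    n_hits = 1)
  out <- labelCandidates(cands, st, g, puf_set = "puf1", test_set = "pt",
                         holdout_fraction = 0, seed = 1)
  # pk annotated with c4 (and closure ancestors): positive
  expect_equal(out$label[1], "positive")
  expect_equal(out$label[2], "positive")    # c2 is an ancestor of c4
  # c6 deeper than pk's deepest known term (depth 4)
  expect_equal(out$unlabeled_reason[3], "deeper_than_known")
  expect_equal(out$unlabeled_reason[4], "puf")
  expect_equal(out$unlabeled_reason[5], "test_protein")
  # test-protein candidates keep their private truth
  expect_equal(out$true_label[5], "positive")

  # holdout: drawn only from labeled training candidates, truth retained
  cands2 <- data.frame(protein = "pk", term = rep(c("c1", "c2", "c3"), 20),
                       n_hits = 1)
  out2 <- labelCandidates(cands2, st, g, character(), character(),
                          holdout_fraction = 0.25, seed = 2)
  hold <- out2$unlabeled_reason == "fdr_holdout"
  expect_equal(sum(hold), round(0.25 * nrow(cands2)))
  expect_true(all(!is.na(out2$true_label[hold])))
  expect_identical(out2, labelCandidates(cands2, st, g, character(),
                                         character(), 0.25, seed = 2))
})

test_that("classifier trains on labeled strata only and separates signal", {
  set.seed(3)
  n <- 300
  cands <- data.frame(protein = paste0("p", 1:n), term = "t",
                      n_hits = rpois(n, 3) + 1,
                      tm_max = runif(n))
  truth <- cands$tm_max > 0.5
  cands$label <- ifelse(truth, "positive", "negative")
  cands$unlabeled_reason <- "none"
  cands$true_label <- cands$label
  hold <- sample(n, 60)
  cands$label[hold] <- "unlabeled"
  cands$unlabeled_reason[hold] <- "fdr_holdout"

  m <- trainCandidateClassifier(cands, num_trees = 100, seed = 1)
  sc <- scoreCandidates(m, cands)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # separable: holdout positives rank above holdout negatives
  hp <- sc$score[hold][sc$true_label[hold] == "positive"]
  hn <- sc$score[hold][sc$true_label[hold] == "negative"]
  expect_gt(min(hp), max(hn) - 0.2)
  expect_gt(mean(hp), mean(hn) + 0.5)
  # determinism
  sc2 <- scoreCandidates(trainCandidateClassifier(cands, 100, seed = 1),
                         cands)
  expect_identical(sc$score, sc2$score)
  # single-class data is an error
  one <- cands; one$label[one$label == "negative"] <- "positive"
  expect_error(trainCandidateClassifier(one), "single-class")
})

test_that("label-independent features give chance-level holdout ranking", {
  aucs <- vapply(1:6, function(seed) {
    set.seed(seed)
    n <- 600
    cands <- data.frame(protein = paste0("p", 1:n), term = "t",
                        f1 = runif(n), f2 = runif(n))
    cands$label <- sample(c("positive", "negative"), n, TRUE)
    cands$unlabeled_reason <- "none"
    cands$true_label <- cands$label
    hold <- sample(n, 150)
    cands$label[hold] <- "unlabeled"
    cands$unlabeled_reason[hold] <- "fdr_holdout"
    m <- trainCandidateClassifier(cands, num_trees = 80, seed = seed)
    sc <- scoreCandidates(m, cands)
    evaluatePairModel(sc$score[hold],
                      ifelse(sc$true_label[hold] == "positive", 7, 0),
                      cutoff = 6)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("FDR calibration matches the worked example and edge cases", {
  cal <- calibrateFdr(c(0.9, 0.85, 0.8),
                      c("positive", "negative", "positive"), target = 0.01)
  expect_equal(cal$threshold, 0.9)
  expect_equal(cal$realized_fdr, 0)
  expect_equal(cal$n_calls, 1L)

  # all-positive holdout: threshold is the minimum score
  cal2 <- calibrateFdr(c(0.2, 0.5), c("positive", "positive"), 0.01)
  expect_equal(cal2$threshold, 0.2)
  expect_equal(cal2$realized_fdr, 0)
  expect_equal(cal2$recall, 1)

  # vacuous target: every call allowed
  cal3 <- calibrateFdr(c(0.3, 0.1), c("negative", "positive"), 1)
  expect_equal(cal3$threshold, 0.1)

  # unreachable target: no calls, warning
  expect_warning(
    cal4 <- calibrateFdr(c(0.9, 0.8), c("negative", "positive"), 0.01),
    "no observed threshold")
  expect_equal(cal4$threshold, Inf)
  expect_equal(cal4$n_calls, 0L)

  expect_error(calibrateFdr(numeric(), character(), 0.01), "empty")
  expect_error(calibrateFdr(0.5, "negative", 0.01), "no positives")
})

test_that("FDR calibration equals a brute-force scan on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    sc <- round(runif(n), 2)    # force ties
    lb <- ifelse(runif(n) < pmin(1, sc + 0.2), "positive", "negative")
    if (!any(lb == "positive")) next
    tgt <- sample(c(0.05, 0.1, 0.3), 1)
    ref <- bruteCalThreshold(sc, lb, tgt)
    cal <- suppressWarnings(calibrateFdr(sc, lb, tgt))
    expect_equal(cal$threshold, ref)
    if (is.finite(ref)) expect_lte(cal$realized_fdr, tgt)
  }
})

test_that("finalized annotations are ancestor-closed with inherited scores", {
  g <- diamondGraph()
  cands <- data.frame(protein = c("q", "q", "r"),
                      term = c("Z", "X", "W"),
                      score = c(0.95, 0.4, 0.9))
  st <- finalizeAnnotations(cands, threshold = 0.9, g, arm = "gba")
  # q: Z accepted -> closure Z,X,W,Y,root present
  expect_setequal(proteinTerms(st, "q"), c("Z", "X", "W", "Y", "root"))
  a <- annotationTable(st)
  # ancestors inherit the accepting descendant's score
  expect_equal(a$score[a$protein_id == "q" & a$term_id == "X"], 0.95)
  expect_true(a$via_closure[a$protein_id == "q" & a$term_id == "X"])
  expect_false(a$via_closure[a$protein_id == "q" & a$term_id == "Z"])
  # r: W accepted -> W, Y, root
  expect_setequal(proteinTerms(st, "r"), c("W", "Y", "root"))
  # output equals its own closure
  reclosed <- closeStore(st, g)
  expect_setequal(with(annotationTable(reclosed), paste(protein_id, term_id)),
                  with(a, paste(protein_id, term_id)))
  # nothing above threshold: empty store
  empty <- finalizeAnnotations(cands, threshold = Inf, g)
  expect_equal(nrow(annotationTable(empty)), 0)
})

test_that("arm union is a per-protein set union with dual provenance", {
  g <- diamondGraph()
  s1 <- finalizeAnnotations(
    data.frame(protein = "q", term = "X", score = 0.9), 0.5, g, "gba")
  s2 <- finalizeAnnotations(
    data.frame(protein = "q", term = "W", score = 0.8), 0.5, g, "structural")
  u <- unionArms(s1, s2)
  expect_setequal(proteinTerms(u, "q"), c("X", "W", "Y", "root"))
  # disjoint stores: assignment counts add
  s3 <- finalizeAnnotations(
    data.frame(protein = "z", term = "Y", score = 0.8), 0.5, g, "structural")
  expect_equal(nrow(annotationTable(unionArms(s1, s3))),
               nrow(annotationTable(s1)) + nrow(annotationTable(s3)))
  # identical stores: union equals either
  expect_equal(nrow(annotationTable(unionArms(s1, s1))),
               nrow(annotationTable(s1)))
  # overlapping assignment keeps both arms in provenance
  s4 <- finalizeAnnotations(
    data.frame(protein = "q", term = "X", score = 0.7), 0.5, g, "structural")
  u2 <- annotationTable(unionArms(s1, s4))
  expect_setequal(u2$source[u2$term_id == "X" & !u2$via_closure],
                  c("gba", "structural"))
})
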