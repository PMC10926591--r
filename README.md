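# puffin

Predicting Gene Ontology (GO) annotations for **proteins of unknown
function (PUFs)** by integrating many weak sources of protein similarity,
with honest false-discovery-rate control. The package is aimed at
computational biologists annotating a single microbial proteome who have
heterogeneous evidence — sequence motifs, bitscores, operon calls,
orthology, co-expression from label-free proteomics, structure alignments,
STRING sub-scores — and want term-level predictions with a calibrated
error rate, plus the downstream statistics to interpret them.

## The method

A protein is a PUF when its annotation reaches a GO depth below 2 (nothing
more informative than an ontology root), where depth(t) is the number of
edges on the longest path from the namespace root to t. Prediction runs in
two arms that share one transfer engine:

**Guilt-by-association arm (within species).** For every protein pair, a
~20-dimensional similarity vector is assembled and a random-forest
regressor predicts the pair's functional similarity, defined as

> d(a, b) = max { depth(t) : t ∈ cl(A(a)) ∩ cl(A(b)) }

the depth of the deepest shared term between the ancestor-closed
annotation sets. Deep training pairs are oversampled (2× for d > 6, 4× for
d > 8). Pairs with predicted d > 6 become edges of the **hit network**.

**Structural arm (between species).** Structure-search hits with TM-score
> 0.3 are kept; each hit carries TM-score, RMSD, global-alignment percent
identity and percent non-gap (Needleman–Wunsch, affine gaps), and the rank
of the most specific shared taxonomic level (genus = 1, family = 2, …).

**Term transfer.** A term is a candidate for a query only if it annotates
one of the query's hits. Each (protein, term) candidate is summarized by
statistics (count, sum, max, mean) of every similarity measure over the
hits carrying the term, and scored by a random-forest classifier trained
on positive/negative candidates only — candidates are left unlabeled if
the protein is held out, is a PUF, or the term is deeper than the
protein's deepest known annotation, and a random 10% of labeled training
candidates is deliberately unlabeled for FDR control. The score threshold
is the smallest observed score whose holdout FDR = FP/(FP+TP) is ≤ 1%.
Accepted terms are propagated to all ancestors. Final annotations are the
union of the two arms.

**Downstream.** Functional coherence of a protein set S is its binary
partition modularity Q = Σ_c [e_c/m − γ(d_c/2m)²] at resolution γ = 0.81,
compared against 1000 size-matched random sets and GO-term partitions.
Enrichment of terms in PUF predictions vs PKF annotations uses a Bayesian
hierarchical binomial model with log odds ratios partially pooled across
term depths; a second conjugate model converts PKF term frequencies into
expected PUF counts. Distributional contrasts (e.g. protein length) use
bootstrap quantile–quantile bands (500 resamples).

Everything is exercised offline by a synthetic-data generator that plants
functional families, couples every evidence channel to the true deepest
shared depth with preset strength (`strong`, `noisy`, `null`), masks a
fraction of proteins to roots (making them PUFs), and retains the truth so
realized FDR and recall are measurable.

## Worked example

```r
library(puffin)

sim <- simulateData(syntheticConfig("strong", seed = 7))
res <- runPipeline(sim, target_fdr = 0.01, num_trees = 200, seed = 7)

res$gba$pair_eval$auc
#> [1] 0.9993144
res$gba$transfer$calibration
#> FDR calibration: target 0.01
#>   threshold: 0.982119  calls: 138
#>   realized FDR: 0.007246377  precision: 0.9927536  recall: 0.458194
res$evaluation$fdr      # against the masked ground truth, PUFs only
#> [1] 0.00127551
res$evaluation$recall   # masked true terms at depth >= 2 recovered
#> [1] 0.8548644
```

The pair model separates deep-sharing pairs almost perfectly (AUC 0.999),
the calibrated threshold keeps the holdout FDR under the 1% target
(0.72%), and on the masked ground truth the union of both arms recovers
85% of informative terms at a realized FDR of 0.13%. Under the `null`
preset the same pipeline returns chance-level AUC (≈ 0.5) and makes
essentially no calls — the calibration machinery protects against pure
noise.

Network and enrichment follow-ups: a planted functional family behaves as
a community of the hit network, beating all 1000 size-matched random
partitions (Q = 0.190 vs a null maximum of 0.181 on the run above), and
the per-term count table feeds the Bayesian models:

```r
net <- res$gba$network
fams <- split(names(sim$truth$family), sim$truth$family)
fam <- fams[[which.max(lengths(fams))]]      # largest planted family
q_fam <- modularityScore(net, fam, resolution = 0.81)
q_null <- randomPartitionNull(net, length(fam), n_reps = 1000, seed = 1)

counts <- buildTermCounts(subsetStore(res$combined, sim$pufs),
                          subsetStore(sim$public_store, sim$pkfs),
                          sim$graph, min_obs = 4)
ors <- fitEnrichmentModel(counts, seed = 1)   # posterior odds ratios
```

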