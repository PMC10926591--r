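---
title: "Annotating proteins of unknown function: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating proteins of unknown function: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In most microbial proteomes a substantial fraction of proteins carries no
informative Gene Ontology (GO) annotation. `puffin` defines a **protein of
unknown function (PUF)** structurally: a protein whose ancestor-closed
annotation set contains no term deeper than 1, where the depth of a term
is the number of edges on the *longest* path from its namespace root
(`termDepth()`). The three GO namespaces are treated equivalently, each
root at depth 0. Because ancestral closure can only add ancestors — never
deepen the maximum — the PUF rule is invariant to whether it is evaluated
before or after closure, and `classifyPuf()` accepts either.

Annotations are merged from several sources (`mergeAnnotationSources()`),
with score-bearing sources filtered to scores *strictly* above 0.9, and
ancestor-closed under the true-path rule. Both `is_a` and `part_of` edges
are used by default: GO's propagation convention includes `part_of`, and
the flag `include_part_of` exposes the choice. Per-assignment provenance
is retained so source-overlap summaries remain computable.

# The two-arm prediction model

## Pair similarity and the hit network

The guilt-by-association arm learns the **deepest shared term depth**
`d(a,b) = max depth over cl(A(a)) ∩ cl(A(b))` for protein pairs, from a
registry of ~20 similarity measures (`defaultFeatureRegistry()`): a
Shannon-weighted Jaccard distance over sequence-motif vectors, sequence
bitscore, operon co-membership, orthogroup species-overlap, a
tree-distance metric, mean per-experiment Spearman co-expression, a
presence/absence Jaccard distance, the max-normalized TM-score with RMSD,
and the STRING combined score plus ten retained sub-scores (co-expression
and experiments excluded; their transferred variants kept). Deepest-shared
depth is computed on ancestor-closed sets — the only reading under which
parent propagation of predictions is coherent — and a pair involving an
unannotated protein scores 0 (flagged), so every pair is scoreable.

Missing evidence is filled per channel: 0 for similarity-type channels
(matching the explicit zero rules for absent proteins in co-expression
and for pairs absent from STRING's sparse link lists) and 1 for the two
distance-type channels. Shannon weights use log base 2; a weighted
Jaccard over a zero-weight union is defined as 0 (the vectors are
indistinguishable under the weighting). Undefined Spearman correlations
(constant profiles) map to 0; ties use average ranks. Presence is defined
at the condition level, after nonzero-mean averaging and zero imputation.

A random-forest regressor (500 trees by default; `mtry` and size exposed)
is trained on pairs whose two proteins are both in the training split —
pairs touching a held-out protein are excluded *by construction* in
`buildPairTrainingSet()`, which asserts the exclusion. Deep pairs are
oversampled with total multiplicities 1/2/4 (the fourfold factor replaces
the twofold for its stratum — each rule states the factor for its own
stratum). Pairs with predicted depth strictly above 6 become edges of the
`HitNetwork`; PUFs and test proteins are scored but never trained on.

## Term transfer with FDR calibration

Both arms share one engine. A term is a candidate for a query only if it
annotates at least one hit; each candidate is summarized by count, sum,
max and mean of every similarity measure over the hits carrying the term
(the registry is an argument; sum and max are always present because the
model design summarizes measures like TM-scores exactly that way). The
classifier is a random-forest probability machine trained on
positive/negative candidates only. "Semi-supervised" is operationalized as
positive/unlabeled-aware training: the unlabeled strata (held-out
proteins, PUFs, candidates deeper than the protein's deepest known term,
and a seeded random 10% of labeled training candidates) are excluded from
fitting and used for calibration and prediction; no self-training loop is
implemented because none is specified.

`calibrateFdr()` scans every observed score `t` and selects the smallest
one whose holdout FDR `FP/(FP+TP)` at `score ≥ t` is at or below the
target (1% by default), maximizing calls subject to the bound; thresholds
are restricted to observed scores for reproducibility, and the realized
calibration FDR is asserted `≤` target on every run. Accepted terms are
propagated to all ancestors, which inherit the maximum score over their
accepting descendants (an artifact-plumbing choice; only the terms'
presence is scientifically required). The FDR holdout is sampled over
candidates, not proteins, matching the calibration unit. Final
annotations are the per-protein union of the arms with per-arm
provenance; a consensus weighting is deliberately out of scope.

The realized FDR on *independent* test proteins typically exceeds the
calibration target — the holdout is drawn from training-protein
candidates, and candidates deeper than a protein's known annotation are
excluded from calibration but not from prediction. The package reports
both numbers rather than hiding the gap; on the noisy synthetic preset
the test-set FDR is roughly 2–6× the 1% target while the holdout FDR
stays below it.

## The structural arm

Structure-search hits are filtered at TM-score strictly above 0.3 and
self-hits removed. Predictors per hit: TM-score and RMSD (taken from the
hit table verbatim; no superposition is recomputed), global-alignment
percent identity and percent non-gap, and the taxonomic rank of the most
specific shared lineage level (species = 0, genus = 1 … superkingdom = 6,
7 when nothing is shared; 0 and 7 extend the published genus-first scale
at both ends and are documented in `taxonomicRankSimilarity()`).

The aligner is an affine-gap Needleman–Wunsch (Gotoh) in C++ with BLOSUM62
defaults and gap open 11 / extend 1, the conventional NWalign parameters;
a gap of length L costs `open + (L-1)·extend`. Tie-breaking is fixed
(diagonal, then up, then left) so percent identity — identical pairs over
alignment length, the conservative denominator — and percent non-gap are
deterministic. Tests verify the scores against exhaustive alignment
enumeration (lengths ≤ 6) and against an independent aligner.

# Network modularity

Functional coherence of a set S is the generalized binary-partition
modularity `Q = Σ_c [e_c/m − γ(d_c/2m)²]` over S and its complement,
unweighted (hits are links; predicted depth is not used as a weight),
at resolution γ = 0.81 by default — the resolution is a plain config
scalar here; the procedure that selected it for the original analysis is
out of scope. Null references are size-matched uniform node subsets
(seeded), and GO-term partitions for terms annotated to strictly more
than a configurable count of network proteins (the published threshold,
400, refers to a proteome-scale network; the count is taken within the
network's nodes, the only choice that keeps partitions well defined).
Unannotated nodes participate in partitions — PUFs must.

# Bayesian enrichment models

Both downstream models are **reconstructions**: the original analysis
states only that Stan models produced depth-adjusted odds ratios and
PKF-frequency-prior expected counts. The forms here are the simplest
models satisfying those constraints, isolated behind `fitEnrichmentModel()`
and `fitExpectedCountModel()` so alternatives can be swapped.

*Odds ratios.* Per term t with depth d(t):
`k_g,t ~ Binomial(n_g, p_g,t)`, `logit(p_pkf,t) = α_t`,
`logit(p_puf,t) = α_t + β_t`, `β_t ~ N(μ_d(t), σ)`, `μ_d ~ N(μ₀, τ)`,
with weakly informative priors (N(0, sd 2) on α_t and μ₀; half-t(3) on σ
and τ). The reported enrichment is `OR_t = exp(β_t)` with posterior
median and 0.1/0.9 quantiles, plus effective sample size and split-R̂
(computed in-package; fits are flagged when R̂ > 1.05). Terms need at
least 4 observations in both groups (inclusive, "at least"); the binary
sequence-feature variant (`buildBinaryCounts()`) uses 6 and a single
pooled depth level. The analysis assumes predicted annotations are an
unbiased sample of true PUF annotations; this is documented, not tested.

*Expected counts.* `p_t ~ Beta(k_pkf+1, n_pkf−k_pkf+1)` as prior,
`k_puf ~ Binomial(n_puf, p_t)`, reported as `total_pufs · p_t`. The model
is conjugate, so the closed-form posterior
`Beta(k_pkf+k_puf+1, n_pkf−k_pkf+n_puf−k_puf+1)` serves as an exact
oracle for the MCMC in the tests.

*Bootstrap QQ.* Both samples are resampled with replacement (500 times by
default), quantile curves evaluated on 99 equally spaced quantiles, and a
pointwise 95% band formed on the quantile differences; the verdict is
"excluded" only when the identity line lies outside the band at *every*
grid point. Constant samples give "indeterminate".

# What the synthetic data emulates — and what it does not

`simulateData()` generates every input the pipeline reads: a
three-namespace ontology laid out as branch-local chains (so deep
closures of distinct functional families do not overlap, mirroring how
distinct processes occupy distinct deep GO subtrees), with guaranteed
diamonds and maximum depth 9 so the deep oversampling strata are
exercised; an annotated proteome organized into functional families
anchored at deep terms; four overlapping source tables with dropout and a
score-bearing source straddling the 0.9 filter; and all similarity
channels as channel-appropriate transforms of `α·s + noise`, where `s` is
the pair's true deepest-shared depth scaled to [0, 1]. Co-expression
comes from latent condition profiles shared within families, so the
planted signal survives rank transformation; structures carry pLDDT
profiles with low-confidence termini; structure-search hits couple their
annotations to the query's truth with probability rising steeply in
TM-score, and uncoupled hits get additionally divergent sequences
(structure-only analogs lack sequence homology). A `puf_fraction` of
proteins is masked to its namespace roots — masking, not deletion,
mirrors "annotated only with an uninformative root" — with the truth
retained for the evaluator alone.

Presets fix the study conditions: `strong` (α = 1, noise SD 0.08, 250
proteins, 150 terms, 25 families), `noisy` (α = 0.5, SD 0.25, 160
proteins) and `null` (α = 0; every channel provably independent of the
truth). The planted signal deliberately flows *through* the
deepest-shared-depth quantity that the pair model regresses, so parameter
recovery is a fair test rather than a tautology — the features are noisy
transforms of the target, never the target itself.

What passing tests on these data do **not** show: real annotation sources
are biased and incomplete in correlated ways; real similarity channels
have heavy-tailed, non-monotone relationships to functional similarity;
real ontologies are far larger and their annotation depths unevenly
distributed; and real structural hits come from a shared evolutionary
history rather than an independent foreign pool. The synthetic results
validate the machinery — calibration logic, closure handling, leakage
control, statistical calibration — not the biological effect sizes.

# Numerical and scale choices

Desk-scale problem sizes keep the full suite fast: presets of 160–250
proteins and 120–150 terms, random forests of 120–200 trees in tests
(the function default stays 500), MCMC with 2 chains and 500–4000
post-adaptation draws, 200 simulation-based-calibration replicates, and
1000 random partitions for the modularity null. Determinism: every
stochastic step takes a seed; ranger runs single-threaded with a fixed
seed; JAGS chains get explicit RNG seeds; dataset generation is
byte-identical under a fixed config (tested).

Degenerate inputs are handled explicitly rather than by accident: an
edgeless network makes modularity an error; an empty annotation set gives
deepest-shared depth 0 with a flag; a calibration holdout with no
qualifying threshold yields +∞ (no calls) with a warning, and the
pipeline runners degrade to an empty prediction store when the hit
network contributes no candidates — required for the null preset to run
end to end. AUC with a single truth class is reported as NA, not a
number.

# Known limitations

The candidate classifier is global over (protein, term) candidates; a
per-term model family is not implemented (the summary-feature design
implies the global reading). Calibration transfers imperfectly from the
holdout to independent proteins, as reported above — this is a property
of the published design that the package surfaces rather than repairs.
The Bayesian models are reconstructions, not the original Stan programs.
The aligner assumes the 20-letter alphabet plus X; selenocysteine and
ambiguity codes beyond X are rejected by design.
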