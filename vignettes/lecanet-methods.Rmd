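---
title: "Methods: from multi-species co-elution evidence to an ancestral interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-species co-elution evidence to an ancestral interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lecanet)
library(dplyr)
```

## The problem

Stable protein complexes leave a biochemical fingerprint in co-fractionation
mass spectrometry (CFMS): when a native lysate is separated into fractions,
members of the same complex co-elute, so their per-fraction peptide-spectral-
match (PSM) profiles correlate. A single separation is far too noisy to call
individual protein-protein interactions (PPIs), but integrating many
orthogonal separations across deeply diverged species gives strong
statistical power — and restricts the resulting network to interactions old
enough to be conserved across the eukaryotic tree. `lecanet` implements that
inference chain at orthogroup (OG) resolution:

1. **Ancestral gene content.** Dollo parsimony on a 0/1 presence/absence
   matrix over a rooted species tree: each orthogroup arises once (at the
   last common ancestor of its carriers) and can only be lost thereafter.
   Orthogroups whose gain node is the root are called ancestral
   (LECA-age) families.
2. **Elution assembly.** Per-experiment elution tables are collapsed to
   orthogroups, concatenated, and filtered to strongly observed rows
   (grand total >= 150 PSMs, inclusive).
3. **Pair evidence.** For each candidate pair, per-experiment co-elution
   statistics (Pearson, noise-regularized Pearson, Spearman, Euclidean and
   Bray-Curtis on L1-normalized profiles, co-apex, lagged cross-correlation,
   and an exact hypergeometric co-detection tail) are aggregated across
   experiments (mean/max of similarities, mean/min of dissimilarities),
   alongside co-purification counts, Jaccard indices, and hypergeometric
   overlap scores from purification-style evidence.
4. **Supervised scoring.** Classifiers trained on known complexes with
   complex-withheld splits score every candidate pair in [0, 1]; a
   false-discovery-rate threshold calibrated on held-out labeled pairs
   (default 10%) defines the accepted network.
5. **Complex detection.** A from-first-principles walktrap community
   detection on the score-weighted graph, recursively re-applied to produce
   a nested complex hierarchy, each level evaluated against reference
   complexes by per-cluster precision and recall.
6. **Conservation breadth.** Each accepted interaction is annotated with
   the number of eukaryotic supergroups (Amorphea, Excavata, TSAR,
   Archaeplastida) whose species supply supporting evidence.
7. **Disease prioritization.** Cross-validated guilt-by-association:
   degree-normalized neighbor voting with leave-one-out AUROC per disease
   gene set, a random-set null, an AUROC >= 0.7 flag, and ranked candidate
   genes for flagged diseases.

## Models and estimators

### Dollo parsimony

For a presence pattern \(S\) (the set of carrier species), the gain node is
the LCA of \(S\); the loss count is the number of maximal subtrees below the
gain node without carriers. `infer_dollo()` computes both with clade
bitmasks; a pattern confined to one species gains at that leaf (degenerate
LCA), never the root. Polytomies are handled by the same definitions. The
test suite checks the implementation against an exhaustive enumeration of
all single-gain/arbitrary-loss scenarios on every 6-leaf pattern, and
against `ape`'s MRCA as an independent LCA oracle.

### Classifiers and score calibration

Three families are provided: extremely randomized trees (`ranger` with the
extra-trees split rule), a linear max-margin SVM (`e1071`; the default and
final model), and an L2-regularized logistic linear model trained by
stochastic gradient descent (implemented in the package; fixed learning-rate
decay, seeded shuffling). Features are standardized internally. Linear
margins are mapped to [0, 1] by explicit Platt scaling — a logistic
regression of the training labels on the decision values — rather than
libsvm's internal cross-validated variant, which draws on a process-global
random state and would break run-to-run reproducibility. The in-sample
Platt fit can be slightly optimistic about calibration of the probabilities
themselves; the downstream FDR threshold is calibrated on *held-out* pairs,
so network acceptance does not inherit that optimism.

Labels come from reference complexes: positives are within-complex pairs;
negatives are sampled cross-complex pairs (excluding any pair sharing a
complex). Complexes sharing members are merged into leakage groups, whole
groups are assigned to train or test (target test share of pairs within
+-5 percentage points, straddling pairs discarded), and training negatives
are downsampled per group stratum to a fixed negative:positive ratio
(default 5). This is the package's concrete reading of "stratified,
complex-withheld" evaluation: group-level withholding removes shared-protein
leakage, and per-stratum downsampling keeps any one large complex from
dominating the loss. The test fold keeps its natural imbalance.

The FDR estimator is the precision complement on held-out labeled pairs:
raw FDR at threshold \(s\) is FP/(TP+FP) among pairs scoring >= \(s\);
q-values are the running minimum of raw FDR from the bottom of the ranking
(hence monotone in score); the operating threshold is the *smallest* score
whose q-value meets the target — the most inclusive acceptance set still
within the target. No decoys are used; the estimator matches the available
supervision.

### Walktrap

`walktrap()` implements the random-walk community algorithm directly on a
dense per-component representation: transition probabilities proportional
to edge weights, vertices represented by their `walk_length`-step walk
distributions (default 4), squared community distance given by the
degree-normalized Euclidean distance between size-averaged community
distributions, and agglomerative merging of the adjacent pair with the
smallest Ward-style variance increase. Ties are broken by the
lexicographically smallest pair of community labels (a community is
labelled by its smallest member), making the merge sequence deterministic.
The returned partition is the dendrogram cut with maximal *weighted*
modularity, since edges are classifier confidences. Components are
processed independently; their cuts are selected against global modularity,
which is separable by component. The hierarchy is produced by recursive
re-application to induced subgraphs (containment is then guaranteed by
construction); selecting multiple cuts of one dendrogram is the documented
alternative, but recursion was chosen precisely because the containment
invariant is structural rather than incidental.

Per-cluster evaluation reports precision = overlap / (cluster members in
the reference universe) and recall = overlap / complex size against the
best-overlap complex (ties to the larger complex, then lexicographic);
level summaries are node-weighted means over clusters that contain
reference members, with unevaluable clusters counted separately.

### Guilt-by-association

Propagation is one-step degree-normalized neighbor voting — the standard
cross-validated GBA estimator: score(g) = (edge weight from g to seeds) /
(total edge weight of g), seeds scored excluding themselves. AUROC is the
midrank Mann-Whitney statistic of held-out genes' scores against all
unannotated nodes, averaged over leave-one-out rounds; it is exact and
deterministic, with no curve interpolation. Random gene sets give AUROC
near 0.5 by construction, which the acceptance suite verifies on a
~500-node planted network (200 sets of 10). Diseases at or above AUROC 0.7
are flagged prediction-worthy; candidates are ranked by full-seed voting
with degree-then-name tie-breaks. An optional degree-matched null samples
random sets from quintile degree bins of a reference set.

## The synthetic-data generator

`simulate_cfms_study()` is first-class, tested code, not a fixture. It
emulates the statistical structure the analysis assumes:

- **Species tree and gene content.** A random rooted binary tree whose
  leaves carry one of four supergroup labels assigned by clade; orthogroup
  presence evolves by single gain (root with probability 0.7, otherwise a
  uniform non-root internal node) and absorbing per-branch loss. Emitted
  patterns are Dollo-consistent by construction.
- **Block-structured co-elution.** Each complex draws one peak centre per
  experiment; members share it up to Gaussian jitter; expected profiles
  are Gaussians scaled to per-OG Gamma-distributed abundances; counts are
  Poisson draws plus Bernoulli single-PSM noise per cell; whole
  orthogroups drop out of an experiment with fixed probability. Peak
  centres are sampled at least two peak widths from the fraction-range
  edges, so edge truncation does not dominate correlations. Poisson (not
  negative binomial) is the default count model — the simplest generative
  model matching integer PSM counts; overdispersion can be emulated by
  widening the abundance distribution.
- **Purification evidence.** Baits drawn from complexes, co-members
  detected with fixed probability, plus low-rate background prey.
- **Disease sets.** round(coherence x set size) genes from one planted
  complex, the rest uniform; size-matched fully random sets are emitted as
  nulls. Degree-matched nulls are available in `random_baseline()`.

Defaults (8 species x 3 separations x 60 fractions, 800 orthogroups, 100
complexes of 3-10 members, abundance 300 PSMs, 1% cell noise, 20% dropout,
10% branch loss) are desk-scale stand-ins for a real multi-species
compendium — orders of magnitude smaller, but with the same block
structure, missingness, and count statistics. What the generator does *not*
model: peptide-level identification, retention-time structure,
chromatography physics, correlated (batch) noise across experiments,
overlapping complex membership, and sequence evolution. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated generative assumptions, not performance on real spectra.

One global seed drives everything; stage-specific substreams are derived by
fixed offsets, so each stage is independently reproducible and the whole
study is byte-identical under a fixed seed.

## Numerical choices and degenerate inputs

- Detection (for hypergeometric binarization) is count >= 1; the
  hypergeometric tail is computed on the log scale (`phyper(..., log.p =
  TRUE)`), so extreme co-detection never underflows to infinity.
- Noise-regularized Pearson adds a single pseudocount and averages plain
  Pearson over 5 seeded Poisson resamples; it converges to the Pearson of
  (counts + 1) as abundance grows.
- All-zero profile blocks are skipped for a pair's statistics in that
  experiment; L1 normalization leaves all-zero blocks at zero; constant
  features get unit scale and are ranked last, flagged.
- Missing evidence is encoded as 0 together with explicit co-observation
  counts, never imputed, so classifiers can learn "absence of evidence".
- q-values applied to unlabeled pairs use constant interpolation from the
  calibration grid (the q of the largest calibrated threshold at or below
  the score), clamped at the ends.
- Walktrap merge ties and cluster naming are resolved lexicographically;
  nodes isolated inside a cluster's induced subgraph become singleton
  subclusters.

## Benchmarks used by the tests

The acceptance suite runs at sizes chosen to make each property measurable
in seconds to a few minutes: the GBA null uses ~540 network nodes and 200
random sets; the FDR benchmark uses the default study (~2,000 positive
pairs, >= 2,000 held-out labeled pairs); Dollo exactness enumerates all 63
non-empty 6-leaf patterns; walktrap optimality is checked on 200 random
connected graphs of 4-9 nodes against an independent replay of the merge
sequence scored with `igraph`'s modularity; recovery, trade-off, leakage,
and disease-recovery checks use planted graphs of 60-250 nodes over 5 seeds
where repetition is required.

Two regimes deserve a note. The *clean* recovery benchmark switches off
every stochastic corruption channel of the generator — cell noise, dropout,
peak jitter, *and* gene loss — because with loss enabled complex members
have heterogeneous species coverage and exact recovery is not a property
even of a perfect pipeline; its evidence graph uses a Pearson floor of 0.9,
below the >= 0.95 within-complex correlation the generator guarantees at
abundance >= 500 but above what chance co-elution of unrelated complexes
sustains across experiments. The *moderate-noise* benchmark keeps all
default noise channels and a 0.5 Pearson floor.

## Known limitations

- The walktrap implementation is dense (O(n^2) memory per component); it
  is comfortable to a few thousand nodes, which matches desk-scale use,
  but would need sparse structures for much larger networks.
- The feature set is a fixed 8-statistic-per-experiment panel with
  mean/max/min aggregation; per-dataset weighting and learned features are
  out of scope.
- FDR calibration assumes the held-out label distribution is
  representative of the candidate space; with reference complexes that
  cover the proteome unevenly the realized FDR on unlabeled pairs can
  differ from the estimate.
- Neighbor voting is one-step; an optional random-walk-with-restart mode
  is deliberately not the default because the cross-validated GBA
  literature this follows uses the one-step estimator and it is exactly
  reproducible.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- simulation_config(
  n_species = 4, n_ogs = 100, n_complexes = 12,
  complex_size_range = c(3, 6), n_fractions_per_experiment = 25,
  n_experiments_per_species = 2, n_diseases = 6, disease_set_size = 4,
  disease_coherence = 1, seed = 61
)
res <- run_pipeline(cfg, min_coobserved = 2)
res$manifest
hierarchy_level_summary(evaluate_hierarchy(res$hierarchy,
                                           res$sim$complexes))
res$gba
```
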