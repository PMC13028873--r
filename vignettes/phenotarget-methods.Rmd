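---
title: "Phenotype-driven herb-target prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven herb-target prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenotarget)
```

## The problem

Medicinal herbs are multi-component mixtures whose chemical composition is
usually unresolved, so structure-based target prediction does not apply. What
every herb does carry is a clinical phenotype profile: the set of symptoms it
is traditionally indicated for. `phenotarget` predicts protein targets from
that profile alone. Because the model never consumes a herb's own interaction
records, it is inductive: it scores herbs with *no* training interactions
(the cold-start case that matters for under-studied natural products).

## The knowledge base

Six entity classes — herbs, traditional (TCM) symptoms, modern-medicine
symptoms, diseases, protein targets, pathways — with four association
matrices forming a phenotype-to-target cascade:

* `M_HT` (herb x TCM symptom, binary),
* `M_TM` (TCM symptom x modern symptom),
* `M_MD` (modern symptom x disease),
* `M_DT` (disease x target).

Herb-target interaction records carry a confidence score and a p-value; they
are supervision labels only and never become graph edges (a leakage guard
asserted in the tests). Protein-protein interactions come in seven
mechanistic categories (binary, complexes, kinase, literature, metabolic,
regulatory, signaling), four of which are directional; pathway annotations
carry one of four origin types (KEGG, GO biological process / molecular
function / cellular component).

Quality control (`qcFilter`) removes symptom-side association records with
confidence below 0.8 and TCM symptoms linked to more than a configurable
fraction of all herbs. The default for that fraction is 0.25: a
symptom touching over a quarter of the pharmacopoeia carries essentially no
discriminative signal. Interaction confidences are kept raw; thresholding
belongs to the dataset recipes.

## The heterogeneous graph

`buildGraph` keeps PPIs with a STRING-style combined score of at least 700
and materializes **19 typed edge sets**: the 7 PPI categories (undirected
ones stored symmetrically under a single label), 4 inverse sets for the
directional categories, 4 annotation sets (target to pathway, one per origin
type) and their 4 inverses; every target additionally receives one
self-loop, kept outside the 19. Edges are unweighted: score filtering, not
score weighting, enforces reliability.

Structural perturbations implement the robustness protocols: `erodeGraph`
removes a fraction of forward edges uniformly (inverse twins follow their
forward edge, so the transpose invariant survives; self-loops are never
removed), `collapsePpiTypes` merges all PPI relations into one homogeneous
relation, and `stripPathways` deletes the pathway layer. Erosion is global
across relations rather than stratified per relation; it models uniform
database incompleteness, and the eroded graph is used for training *and*
scoring within a run — an intact test-time graph would leak precisely the
knowledge whose absence is being simulated.

## The model

For a herb with binary symptom profile $v$ (length $N_s$):

1. **Encoder.** $H_{enc} = \mathrm{ReLU}(W_p v + b_p)$, width
   `dim1` (default 16): the herb's dense pharmacological identity.
2. **Cascade initialization.** Relevance
   $r = N_{DT} N_{MD} N_{TM} v$, where each $N$ is the transposed
   association matrix with rows divided by their nonzero counts (zero rows
   stay zero). Each target starts from $H^{(0)}_t = r_t \cdot H_{enc}$:
   targets unreachable from the herb's symptoms start at zero. Inside the
   network the relevance vector is max-normalized per herb — a scale-free
   choice that preserves the ranking but keeps activations from vanishing
   when the target space grows. The cascade itself carries no learned
   weights.
3. **Typed propagation.** `layerO` outer rounds (default 4), each with
   `layerI` inner layers (default 3). In an inner layer, every PPI-derived
   relation $\rho$ (plus the self-loop) contributes a message
   $m_\rho(t) = \alpha_\rho \cdot W_\rho \,\overline{h}_{N_\rho(t)}$, the
   mean over in-neighbors under $\rho$ transformed by a per-relation,
   per-layer matrix and scaled by a herb-conditioned attention scalar
   $\alpha_\rho = \sigma(w_\rho \cdot H_{enc})$. Messages sum across
   relations through a ReLU. Attention is deliberately a per-relation
   scalar, not per-edge: the herb modulates *relation types*, not
   individual edges.
4. **Pathway fusion.** Target features pool up to pathways (mean over
   member targets, all annotation types pooled, ReLU after a linear map),
   return to targets (mean over annotated pathways, linear map), and gate
   the local features: $C = \sigma(F'_{pw} W_c)$ elementwise,
   $F_{fused} = C \odot F_{target} + F'_{pw}$. The gate multiplies the
   PPI-derived features, exactly as the fusion equation is written, even
   though one could argue the prose intends the pathway term to be gated;
   both readings coincide at $W_c = 0$ and the tests pin the implemented
   form. Unannotated targets receive a zero pathway context.
5. **Re-injection.** Between rounds, $F_{fused}$ is concatenated with the
   target's mean static pathway embedding (width `dim2`, default 8; zero
   when unannotated) and projected back to width `dim1` to seed the next
   round. Parameters are unshared across rounds and inner layers.
6. **Scorer.** $s = W_2\,\mathrm{ReLU}(W_1 e + b_1) + b_2$, probability
   $\sigma(s)$.

Ablation switches: `no_multi_ppis` runs propagation on the collapsed
homogeneous PPI relation; `no_pathways` skips stages 4-5 (a zero block
replaces the pathway embedding in the concatenation); `no_hgcn` bypasses
propagation entirely and scores a linear projection of the cascade features.

Design choices where the architecture was genuinely open: the cascade
algebra is scalar relevance times the herb identity (the cheapest faithful
reading of "propagating the herb embedding through the prior matrices");
aggregation is the arithmetic mean; the nonlinearity is ReLU throughout;
initialization is seeded uniform scaled by fan-in, except square transforms
which start as identity-blended maps ($0.5 I$ plus half-scale uniform
noise) so that early propagation behaves like neighborhood smoothing and
the cascade signal survives the untrained layers. Biases start at zero.

## Training

Triplets (herb, active target, decoy target) with the balanced
cross-entropy objective

$$L = -\tfrac1N \sum_i \log\sigma(s^{(i)}_{act}) +
\log(1-\sigma(s^{(i)}_{dec})),$$

optimized by AdamW (decoupled weight decay on weight matrices and the
pathway embedding table, not biases; the optimizer is implemented in the
package). Decoys are redrawn every epoch from the unobserved space — the
complement of *all* curated interactions of the herb, including records a
dataset recipe filtered out, so known weak interactions are never labeled
negative. The ratio is exactly 1:1. Three strategies: `random` (uniform),
`degree_matched` (log2-binned PPI-degree matching, nearest nonempty bin as
fallback), `pathway_constrained` (decoys sharing a KEGG pathway with the
true target — hard negatives — falling back to random with a warning when
the pool is empty).

Cold-start evaluation partitions *herbs*, never edges: five near-equal
folds; the test fold's herbs have all their interactions masked during
training; the validation fold (the rotating neighbor of the test fold)
drives early stopping on ROC-AUC; each fold is repeated with three
initialization seeds. Herb-level batching computes each herb's forward pass
once per epoch regardless of its triplet count; an optional per-epoch
learning-rate decay (`lrDecay`) stabilizes short annealed runs.

## Metrics

Classification metrics (ROC-AUC via the midrank statistic, PR-AUC as the
step integral, accuracy / precision / recall / F1 at probability 0.5) are
computed on positives plus one fresh decoy each; ranking metrics HR@K and
NDCG@K (K = 10, 20) on the full candidate list minus training positives,
with ties broken by target index. HR@K is the fraction-of-relevant
convention, |relevant ∩ top-K| / min(K, |relevant|), with the binary-hit
convention available behind a flag. The degree baseline scores every target
by its distinct PPI partner count. Stratified reports split held-out
positives by target degree (k < 10 / 10-50 / > 50) or pathway annotation
count (< 3 / 3-20 / > 20; the middle band is closed because only the outer
boundaries are canonical). The paired Wilcoxon signed-rank test drops zero
differences, midranks ties, and uses an exact convolution-based null up to
n = 25 (a dynamic program over doubled midranks, so ties stay exact) and a
tie-corrected normal approximation with continuity correction beyond.
Pathway over-representation is a one-sided hypergeometric tail with
Benjamini-Hochberg adjustment.

## The synthetic knowledge-base generator

Every quantitative claim the package demonstrates — cold-start recovery,
cascade usefulness, the cost of collapsing PPI types, pathway-sparsity
resilience — needs *planted, controllable* signal, so the generator builds
mechanism-structured bases rather than random graphs. `nMechanisms` latent
mechanisms (default 8) partition targets, diseases, symptoms and pathways
(15% of entities carry a second mechanism); herbs draw a dominant primary
mechanism, one third of them a secondary one with weight 0.1-0.4. The
cascade matrices link mechanism-mates with probability 0.25 (0.15 for
disease-target) and cross-mechanism pairs with probability 0.004; nine
tenths of association weights lie in [0.8, 1] so the QC filter has realistic
work. Symptom profiles are drawn from the herb's mixture (8 expected
symptoms per herb) with 2% flip noise. Per-target mechanism affinities are
graded (uniform on [0.5, 1]) so the true herb-target propensity is
continuous; positives are drawn with probability proportional to
propensity raised to a sharpening exponent (default 3), with per-herb
counts following a truncated power law (exponent 1.6, the long tail of
natural-product data) and 5% of records replaced by uniform noise.
Confidences are uniform in the configured band; 5% of p-values exceed 0.05.
PPIs follow a stochastic block model (within-mechanism 0.03, between 0.001);
the kinase category is sampled only within mechanisms — by construction the
most informative relation — while binary edges absorb extra
between-mechanism noise, so collapsing the categories measurably discards
signal. A third of targets are down-sampled to fewer than three pathway
annotations to populate the sparse-annotation stratum.

What the generator does *not* emulate: real STRING score distributions, GO
DAG structure (pathways are flat labels), symptom ontology alignment, or
correlated assay biases. Passing the recovery suite therefore demonstrates
that the implementation learns the structure it claims to learn from data
of this shape — not that it reproduces curated-database performance.

With both noise rates at zero the ranking induced by the true propensity is
the Bayes reference; the proportional-sampling rule keeps a sliver of
overlap between positives and in-mechanism decoys, so its ROC-AUC
approaches 1 only as the sharpening exponent grows. The generator ships
the propensity matrix so tests can use this reference directly.

## Problem sizes and numerical choices

The reference study condition is 200 herbs, 100 TCM symptoms, 60 modern
symptoms, 120 diseases, 800 targets, 60 pathways, 8 mechanisms. On it, the
Bayes reference reaches a ROC-AUC near 0.93, the raw cascade near 0.79, and
the degree baseline near 0.55, leaving a wide window in which propagation
must prove itself. The recovery protocol (also run by
`scripts/acceptance.R`) is 5 cold-start folds x 3 seeds with the
`layerI = 1, layerO = 2` architecture, learning rate 8e-3 annealed by
0.92 per epoch, batch size 150, at most 14 epochs with patience 4 and an
early-stopping burn-in of 4 epochs (the monitor records a best model from
epoch 5, avoiding spuriously lucky pre-convergence epochs; validation
decoys are drawn once per fold so the monitor is deterministic given the
parameters). The erosion and PPI-collapse comparisons run as paired arms
on the first two folds of the same partition. These sizes keep the whole
battery at minutes on one CPU while leaving two full propagate-fuse
rounds. The package default architecture remains
`layerI = 3, layerO = 4` (the published operating point, whose depth
matches the four-hop reasoning radius of the cascade); on the desk-scale
planted bases the shallower protocol sits on the same performance plateau,
and the hyperparameter grid runner reproduces that comparison.

Degenerate inputs are handled conservatively: empty relations are allowed
(with a warning) and contribute zero messages; herbs with empty symptom
profiles encode to $\mathrm{ReLU}(b_p)$ and warn; zero cascade rows stay
zero; single-class metric inputs yield absent AUCs rather than 50. All
randomness — generation, splits, decoys, initialization, batching — is
seeded, and every experiment is reproducible from its seeds; erosion takes
its own seed so robustness curves are comparable across fractions.

## Known limitations

The model is additive over symptoms; synergistic symptom interactions are
outside its function class. Attention is per-relation, not per-edge, so
interpretability traces attribute relation types and pathways, not
individual interactions (pathway attribution uses leave-one-pathway-out
score drops, max-normalized per target — the gate map is per-dimension and
would not align with pathways otherwise). Real-database ingestion is
format-compatible (the TSV dialect round-trips) but identifier mapping to
UniProt or ontology alignment is deliberately out of scope: identifiers are
opaque strings.
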