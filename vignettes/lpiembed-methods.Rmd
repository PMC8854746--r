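---
title: "Heterogeneous network embedding for lncRNA-protein interaction prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lpiembed` casts lncRNA–protein interaction prediction as bipartite link
prediction on typed heterogeneous networks. Its core assumption is the one
that makes network methods work in this domain: molecules with similar
interaction neighbourhoods (or similar sequences) tend to share partners.
The pipeline turns that assumption into features in four stages.

**Similarity layers.** Two independent notions of within-type similarity
are computed. *Jaccard similarity* compares association sets built from
the training interactions: for lncRNAs $i,j$ with partner sets $L_i, L_j$,

$$J(L_i, L_j) = \frac{|L_i \cap L_j|}{|L_i \cup L_j|},$$

and symmetrically for proteins. Edges are kept when $J > 0.5$ for
lncRNA–lncRNA pairs and $J > 0$ for protein–protein pairs, both strict
inequalities. The asymmetry is deliberate: with few proteins and many
lncRNAs, protein association sets are large and almost always overlap
somewhat, so any positive overlap is already informative, while lncRNA
sets are small and need a high bar. *Alignment similarity* consumes
pairwise alignment results in BLAST 12-column tabular form; an edge is
kept when the best e-value over either query/subject orientation is below
$10^{-3}$ (lncRNA) or $10^{-2}$ (protein), again strict.

**Two heterogeneous networks.** Training interaction edges plus the
Jaccard layers form KJNet; training interaction edges plus the alignment
layers form KBNet. Node types (lncRNA, protein) and edge types
(interaction, lnc\_sim, prot\_sim) are explicit. Held-out test
interactions are excluded *before* assembly, so neither the similarity
layers nor the walks can leak test labels — the package asserts this on
every walk corpus (`check_no_leak()`).

**Meta-path embeddings.** Node representations come from skip-gram over
random walks constrained by meta-path schemes. A scheme is a cyclable type
sequence; the two defaults are `LPLPL` (two lncRNAs interacting via a
protein) and `LLPPLL` (similar lncRNAs whose partners are similar
proteins). At walk position $i$ with required next type $t$, the walker
moves to each admissible neighbour with probability
$1/|N_t(v_i)|$ and stops at dead ends. Each scheme is run over each
network, the two corpora of a network are pooled, and one skip-gram model
per network produces a 64-dimensional vector per node. A node's final
feature is the 128-dimensional splice [KJNet vector ‖ KBNet vector]; a
candidate pair is the 256-dimensional concatenation
[lncRNA ‖ protein].

**Classification and evaluation.** An RBF-kernel C-SVM is trained on pair
features (standardised with training statistics only) and evaluated on the
held-out pairs with PRE, REC, SPE, ACC, MCC, F1 and ROC/AUC, where the ROC
uses the SVM's continuous decision values, not hard labels. The protocol
is a 9:1 random split stratified by class, repeated three times with
independently re-sampled negatives, reporting per-repeat metrics and their
mean.

# Tunable parameters

| key | default | meaning / rationale |
|---|---|---|
| `split.ratio` | 0.9 | train fraction of each class; the 9:1 protocol |
| `split.repeats` | 3 | independent split repetitions |
| `jaccard.lnc_threshold` | 0.5 | strict lower bound for lncRNA Jaccard edges |
| `jaccard.prot_threshold` | 0 | strict lower bound for protein Jaccard edges |
| `evalue.lnc_cutoff` | 1e-3 | strict upper bound for lncRNA alignment edges |
| `evalue.prot_cutoff` | 1e-2 | strict upper bound for protein alignment edges |
| `walk.num_walks` | 10 | walks started per scheme-compatible node |
| `walk.length` | 80 | nodes per walk (scheme cycles to this length) |
| `embed.dim` | 64 | per-network embedding dimension |
| `embed.window` | 5 | skip-gram context half-width |
| `embed.epochs` | 5 | skip-gram passes over the corpus |
| `embed.negative` | 5 | negative samples per context pair |
| `svm.C`, `svm.gamma` | 1, "scale" | SVM cost and kernel width |
| `negatives.strategy` | subcellular | negative-sampling default |

The walk and skip-gram defaults follow common practice for
metapath-constrained node embedding (tens of walks of moderate length per
node, small window, a handful of epochs); they are deliberately
conservative and all config-exposed. `gamma = "scale"` is
$1/(d \cdot \widehat{\mathrm{Var}})$ on the standardised training matrix,
which reduces to roughly $1/d$ and avoids hand-tuning the kernel width to
a feature dimension that changes across ablation variants.

# Negative sampling

Known interaction data contain no verified negatives, so class-0 examples
must be constructed, and the construction strongly affects measured
performance. Three strategies are provided, always drawing exactly as many
negatives as there are positives (balanced classes):

- **random** — uniform over all non-positive pairs. Unbiased but noisy:
  some sampled "negatives" are simply undiscovered positives.
- **subcellular** (default) — only pairs whose compartment annotation
  sets are disjoint, on the biological ground that molecules never
  co-located cannot physically interact. These are the most trustworthy
  negatives.
- **distance** — pairs whose shortest-path distance in the prior
  (training-positive) interaction network falls in a band:
  `Distance_3` (= 3 exactly), `Distance_5` (1 < d ≤ 5),
  `Distance_7` (1 < d ≤ 7). In a bipartite graph all finite
  lncRNA–protein distances are odd; unreachable pairs are excluded from
  bounded bands. Candidate sets nest: Distance_3 ⊆ Distance_5 ⊆
  Distance_7.

Distances are computed on the training positives only, and any candidate
that coincides with a known positive (train or test) is excluded, keeping
labels consistent.

# The synthetic benchmark

`generate_planted_network()` produces the package's self-contained test
bed: $n_\ell$ lncRNAs and $n_p$ proteins are assigned round-robin to $k$
blocks (then shuffled), interactions are Bernoulli($p_{within}$) inside a
block and Bernoulli($p_{between}$) across, similarity hits connect
same-type pairs within blocks (flipping across blocks with probability
`sim_noise`), and each block is one subcellular compartment. Defaults are
$150 \times 30$ nodes, $k = 3$, $p_{within} = 0.6$, $p_{between} = 0.02$,
`sim_noise` $= 0.05$ — a desk-scale network (~960 positives) with strong
modular structure, dense enough that every node participates in walks, and
generated in milliseconds. `generate_sequences()` adds block-structured
sequences (one mutated ancestor per block) so the alignment-ingestion path
can be exercised end to end; `identity_hits()` converts pairwise Hamming
identity into monotone pseudo e-values for that purpose and is explicitly
a synthetic stand-in, not an alignment statistic.

What the generator emulates: modular interaction structure (which makes
Jaccard similarity informative), block-consistent sequence similarity, and
localization annotations consistent with the no-shared-compartment
assumption. What it does not emulate: the extreme degree skew of real
interaction databases (thousands of lncRNAs with one or two recorded
partners and a handful of heavily studied proteins), annotation noise, and
study bias. Passing the recovery benchmark therefore shows the machinery
extracts planted structure correctly; it does not certify real-data
accuracy.

One consequence is worth stating plainly. At the benchmark's default
density every lncRNA has ~6 training interactions, so the
interaction-only (KNet) network already embeds the block structure almost
perfectly and the evaluation sits at the benchmark's information-theoretic
ceiling (~0.97 AUC with subcellular negatives). The similarity layers then
have no headroom: across 17 benchmark seeds the full-vs-KNet mean AUC
difference is +0.0001 ± 0.003 — statistically zero. The advantage of
similarity layers materialises on sparse networks, where poorly connected
nodes would otherwise embed badly; users should expect the ablation gap to
grow as mean degree falls, and should not read the dense benchmark's tie
as evidence the layers are useless.

# Numerical and design choices

- **Strict inequalities everywhere.** All similarity thresholds and
  e-value cutoffs are strict (`>` / `<`); boundary values are excluded.
  This matches the natural reading of "more than"/"less than" and is
  covered by boundary tests.
- **Similarity from training data only.** Association sets and the
  similarity graphs are rebuilt per repeat from that repeat's training
  positives. Building them from all data would re-leak the very test
  edges the walk generator removes. A full-data variant can be had by
  passing the complete edge set explicitly, but it is not the default.
- **Either-orientation rule for alignment edges.** Alignment e-values are
  asymmetric; an undirected edge needs a symmetric rule. The default
  keeps the edge when either orientation passes (best-hit convention);
  `require_both = TRUE` gives the max-stringency alternative.
- **Alignment edge weight** is $-\log_{10}(\text{e-value})$, capped at
  300 to keep an e-value of zero finite. Walk transitions are uniform, so
  weights are informational only.
- **Empty-vs-empty Jaccard is 0**, avoiding 0/0; such nodes simply gain
  no similarity edges.
- **Scheme cycling.** Printed schemes are 5–6 types, far shorter than a
  useful walk; since both start and end on the same type, the scheme
  cycles until `walk.length`. Dead-ended walks are kept when they have at
  least two nodes (one context pair), else discarded.
- **Edge-class reading of `LLPPLL`.** Steps between equal types traverse
  similarity edges only, steps between different types interaction edges
  only. Under any other reading the scheme is unrealisable on these
  networks (an interaction edge can never join two lncRNAs).
- **Schemes × networks.** Both schemes run on both heterogeneous
  networks, and each network's corpora are pooled before training — the
  neutral choice absent a stated pairing. (On an interaction-only
  network `LLPPLL` produces no walks and contributes nothing, which is
  the correct degeneration.)
- **Skip-gram implementation.** The embedding trainer is a
  single-threaded skip-gram with negative sampling written in C++
  (unigram$^{3/4}$ negative table, shrinking windows, linear
  learning-rate decay from 0.025, single-precision vectors, tabulated
  sigmoid). Single-threading plus an owned Mersenne-Twister stream makes
  training bit-reproducible for a fixed (corpus, seed) on one platform,
  which the test suite asserts byte-for-byte through serialized corpora,
  features and reports.
- **Zero-vector fallback.** A node appearing in no walk (isolated in the
  training network) receives the zero vector rather than being dropped;
  dropping would silently shrink the evaluable test set. Fallbacks are
  counted and reported.
- **Sub-model feature dimensions.** Single-network variants (KNet, KJNet,
  KBNet) use their one 64-dimensional embedding directly (pair dimension
  128); only the full model splices two networks (pair dimension 256).
  Duplicating a single network's vectors to force 256 would add no
  information.
- **Undefined metrics stay undefined.** A metric with a zero denominator
  (e.g. precision with no predicted positives) is reported as `NA` and
  flagged, except MCC which takes the conventional 0 (flagged). Degenerate
  predictors should be visible, not silently zeroed.
- **AUC** is computed by threshold sweep with tied scores grouped and
  trapezoidal integration, which equals the normalised Mann–Whitney
  U statistic with ties counted ½; the suite checks agreement with an
  exhaustive pairwise oracle to $10^{-12}$.
- **Negatives are re-sampled per repeat** (the protocol is silent on
  this); fixing them once is possible through `split_dataset()` directly.
- **Embedding tables** are written with 6 significant digits, so
  round-trips are exact to a relative $5 \times 10^{-6}$.

# Problem sizes used by the test suite

Unit tests run on fixtures of 6–50 nodes where brute-force enumeration is
the oracle. The end-to-end recovery benchmark uses the generator defaults
($150 \times 30$, three repeats, five seeds) and the Monte-Carlo transition
check uses ~100,000 walk steps on a 20-node fixture — sizes chosen so the
statistical assertions have power while the whole suite stays fast on a
laptop-class single core.

# Known limitations

- The skip-gram trainer is deliberately minimal: no subsampling of
  frequent tokens, no hierarchical softmax, no multithreading. For
  desk-scale networks this is ample; for networks with $10^5$+ nodes a
  dedicated embedding library would be preferable.
- Bit-reproducibility holds within one platform/compiler, not across
  architectures.
- The subcellular strategy trusts its annotation input; incomplete
  compartment annotations make "disjoint" pairs that are merely
  under-annotated.
- The dense planted benchmark cannot exhibit the sub-model ablation
  ordering (see above); demonstrating that ordering requires a sparse
  regime the default benchmark intentionally does not occupy.
- No calibration of SVM scores is attempted; scores are rankings, not
  probabilities.
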