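---
title: "Methods: drug repurposing and mechanism-of-action paths on knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug repurposing and mechanism-of-action paths on knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

`kgmoa` treats drug repurposing as link prediction on a directed biomedical
knowledge graph $\mathcal{G} = \{\mathcal{V}, \mathcal{E}\}$ whose nodes are
typed biological entities (drugs, diseases, genes, pathways, ...) and whose
edges carry semantic predicates. Two coupled models are trained:

* a **pair classifier** that, given a drug $v_i$ and disease $v_j$,
  predicts whether the pair belongs to the *treat*, *not-treat* or
  *unknown* class, with the treat probability $p_{\mathrm{treat}}$ used to
  rank repurposing candidates; and
* a **path-finding agent** that walks the graph from a drug and proposes
  ranked multi-hop paths to a disease as candidate mechanisms of action
  (MOA).

## Graph customization

Raw biomedical graphs contain material that hurts both tasks. The
`kg_customize()` step removes (i) whole node categories irrelevant to
pharmacology, (ii) edges from a configurable low-quality provenance
deny-list or with fewer supporting records than `min_provenance_count`,
(iii) hierarchically redundant edges — when a node pair carries both a
child predicate and its declared ancestor, the less informative ancestor
edge is dropped — and (iv) **every** direct drug–disease edge, in either
direction, so that neither model can learn a one-hop shortcut to the
labels. The filter is idempotent, and the published quality criteria for
individual sources are not reproduced here: the deny-list plus the count
threshold is an explicit, configurable stand-in with the same intent.

## Literature filter

Label sources mined from the literature by NLP carry publication bias and
extraction errors. Pairs from such sources are kept only when they have at
least `min_cooccur` (default 10) shared publications and a normalized
Google distance

$$NGD(c_1,c_2) = \frac{\max(\log \mathcal{N}(c_1), \log \mathcal{N}(c_2)) -
\log \mathcal{N}(c_1,c_2)}{\log N - \min(\log \mathcal{N}(c_1), \log
\mathcal{N}(c_2))}$$

of at most `max_ngd` (default 0.6), both boundaries inclusive. The value
is invariant to the base of the logarithm (the package uses natural logs);
a concept with zero publications makes the quantity undefined and raises
an error rather than passing silently, and zero co-occurrence yields
$+\infty$ (always filtered). The corpus normalizer $N$ is supplied with
the concept–publication map. The filter is a mechanism; the decision of
*which* sources need it stays with the caller.

## Labels and the split

Labeled pairs from several sources are merged by union; a pair labeled
*treat* by one source and *not-treat* by another is dropped and logged —
the sources disagree and keeping either label would inject noise.
*Unknown*-class pairs are negative samples: each unique treat pair
produces one drug-replaced and one disease-replaced pair, resampled until
the candidate appears in neither labeled class (bounded at 100 attempts so
degenerate toy worlds fail loudly). Unknowns are generated **after**
splitting, from training positives only, so no information about held-out
pairs leaks into training; the alternative order is not stated anywhere
authoritative, and this is the conservative choice.

The split is per drug at ratios 8/1/1 (largest-remainder rounding,
train-priority on ties; one-pair drugs go to train, two-pair drugs to
train+test), which guarantees every drug evaluated at validation/test time
was seen in training — the intended use is new indications for *known*
drugs.

## Node embeddings

Each node's attribute text (`name` + `category`) is encoded by a pluggable
text encoder. The default is a seeded feature-hashing encoder — a
deterministic, dependency-free stand-in for a biomedical language model,
which can be dropped in through the same one-string-in, one-vector-out
contract. Attribute vectors are PCA-compressed to 100 dimensions.

Graph embeddings minimize the random-walk skip-gram objective with
negative sampling,
$$L(z_u) = -\log \sigma(z_u^\top z_v) - k \cdot
E_{v_n \sim P_n}\log \sigma(-z_u^\top z_{v_n}),$$
over co-occurrence pairs from fixed-length random walks (defaults: length
8, 10 walks per node, window 5), with $P_n \propto \mathrm{degree}^{0.75}$.
As printed in some sources the second term lacks the negation inside the
sigmoid; the package implements the standard (negated) form — the
non-negated form is not a meaningful objective.

Implementation notes, all visible in `graph_embed_config()`:

* Embeddings are free per-node vectors trained by sequential SGD in
  compiled code, **initialized** from a linear projection of each node's
  attribute vector concatenated with its out-neighborhood mean (one or two
  aggregation rounds). At desk scale this initialization-plus-objective
  carries the neighborhood information that a full inductive
  neighborhood-aggregating encoder would; the inductive encoder mainly
  pays off for unseen nodes, which do not occur here.
* Corpus occurrences of very frequent nodes are subsampled with the usual
  $\sqrt{t/f}$ rule; by default $t$ adapts to 5× the median node frequency
  so only genuinely hub-like nodes are damped.
* Duplicate corpus pairs are aggregated and their multiplicity enters the
  gradient through a log-saturating weight, which keeps very frequent
  pairs from destabilizing the updates.
* The initialization is scaled to small random entries because $z = 0$ is
  a fixed point of the product-form gradient.
* The learning rate decays linearly; around 0.05–0.1 is stable, 0.3
  diverges (caught and reported). The number of negatives $k$ matters at
  small $n$: on tiny graphs large $k$ swamps genuine co-occurrence with
  random repulsion (the acceptance suite uses $k = 3$ on the 60-node
  community fixture and $k = 10$ on the ~3,000-node world).

## The pair classifier

Pair features are the concatenation $[z_{\mathrm{drug}} ;
z_{\mathrm{disease}}]$ (drug first, fixed). The classifier is a random
forest — bagged CART trees, Gini splits, $\lfloor\sqrt{p}\rfloor$ features
per split, probability = mean of per-tree leaf class frequencies —
implemented in compiled code inside the package because no tree-ensemble
package is available in the target environment. Defaults: 1000 trees,
depth ≤ 25, deterministic per-tree RNG streams. A two-class ablation
(treat / not-treat only) is supported via the `classes` argument.

Ranking evaluation replaces the drug (or disease, or both, or a seeded
random 500 + 500 subset repeated 10 times) of each true positive with
every alternative, excluding all known positives and the query pair, and
ranks the positive by descending $p_{\mathrm{treat}}$ with **competition
ranking**: rank = 1 + number of candidates *strictly* above. No tie-break
convention for the positive itself is needed under this rule; within path
ranking (below), ties break lexicographically on the node sequence.

## Demonstration paths

Biologically plausible drug→…→disease paths supervise the agent. The
published extraction procedure is not available in detail, so the package
fixes a concrete one: enumerate all simple paths of ≤ 3 hops whose second
node is a known target of the drug, rank a pair's surplus beyond
`per_pair_cap` (default 50) by the mean NGD of consecutive node pairs
(missing literature support scores worst; lexicographic node-sequence
tie-break), deduplicate. This reproduces the stated ingredients — known
drug–target interactions plus literature closeness — with deterministic
output.

## The MOA agent

The environment state at step $t$ is
$(v_{\mathrm{drug}}, v_t, (v_{t-1}, e_t), \dots)$ with a history of $K$
(node, predicate) tuples padded by a reserved dummy node/predicate
(embedding row 1). The state embedding concatenates attribute embeddings
of all state nodes with one-hot predicate encodings. Actions are the
self-loop (always first) plus out-edges, pruned to the `neighbor_cap`
(default 3000) highest-PageRank neighbors when the out-degree exceeds the
cap. Episodes run exactly $T = 3$ steps; the self-loop is the stay/stop
device.

Four subnetworks share the architecture
$\mathrm{MLP}(X) = BA(BA(XW_1 + b_1)W_2 + b_2)W_3 + b_3$ ($BA$ =
batch-norm + ELU) with separate parameters, and the actor, critic and path
discriminator own separate node/predicate embedding matrices for action
encoding ($a = [e_{\mathrm{pred}} ; e_{\mathrm{node}}]$); the meta-path
discriminator owns a category embedding matrix, with shorter paths padded
by repeating the final category. Terminal reward: 1 for a known treated
disease, $p_{\mathrm{treat}}$ for a disease predicted *treat*, 0 for a
disease predicted otherwise, −1 for a non-disease node. Per-step reward:
$R_t = \alpha_p R_{p,t} + \alpha_m R_{m,t} +
(1-\alpha_p-\alpha_m)\gamma^{T-t}R_{e,T}$ with the discriminator log-odds
rewards clipped at $\varepsilon = 10^{-7}$ before the logarithm.

Training is multistage: behavior cloning of the actor on demonstration
state–action pairs (MSE between the probability vector and the one-hot
demonstration action — probabilities, not logits; demonstrations shorter
than $T$ are padded with self-loop actions, which teaches stopping); $z$
warm-up epochs in which only the discriminators train (actor and critic
provably untouched — the acceptance suite checks bit-identity); then
joint optimization, critic by squared temporal-difference error
(semi-gradient, terminal bootstrap $Q(s_T, \cdot) = 0$), actor by the
TD-weighted log-policy gradient with entropy regularization weight
$\alpha$. Discriminators keep updating each epoch on fresh rollouts, with
actor segments that exactly match a demonstration segment excluded from
the negatives. With $\alpha_p = \alpha_m = 0$ and no demonstrations the
procedure reduces to plain actor–critic with terminal-only shaping — the
"no demonstrations" ablation.

Unstated hyperparameters are package choices, all in `moa_config()`:
history $K = 2$, $\alpha_p = \alpha_m = 0.1$, $\gamma = 0.99$, entropy
weight 0.01, $z = 5$, Adam for the network weights with plain sparse-row
SGD for embedding matrices. Batch-norm uses exponential-moving-average
statistics treated as constants in the backward pass (single-state
forwards never update them); this "frozen-statistics" form is a
deliberate simplification that keeps the manual backpropagation exact.

## Path scoring and evaluation

All simple exactly-3-hop paths between a pair are enumerated (self-loops
are a policy device, not part of a reported mechanism; shorter-hop
evaluation is available via `exact = FALSE`). Each path scores
$\sum_{i=1}^k \delta^{i-1}\log(P_i N_i)$ with $\delta = 0.9$, $P_i$ the
policy probability of the path's $i$-th action and $N_i$ the pruned
action-space size including the self-loop; an action the pruned policy
cannot take scores $-\infty$. A predicted path "matches" a curated
mechanism when all four of its nodes appear anywhere in the curated node
set (order-insensitive), and a pair with several matched paths is scored
by its best (smallest) rank. Metrics: MRR, Hit@K, and the mean percentile
rank with the convention $PR = 100(n - r + 1)/n$ (best rank → 100), which
is documented here because no authoritative formula for the percentile is
printed anywhere.

# The synthetic world

`synth_generate()` emits a world with four categories (Drug, Disease,
Gene, Pathway) whose defaults (~3,100 nodes, ~18,000 edges) were chosen
once, on modeling grounds, to mirror the statistics that make the real
task learnable:

* **Disease gene modules.** Every disease owns a small gene module
  (default 3 genes, dealt from a shuffled deck so modules barely overlap)
  and a pathway; module genes participate in the pathway, the pathway
  associates with the disease, and association edges run in both
  directions as in curated graphs.
* **Treatments with redundant mechanisms.** A treating drug targets
  (default) 2 module genes of its disease, each planting one walkable
  mechanism path drug → gene → pathway → disease, recorded in the
  manifest together with the drug–target table. There are **no** direct
  drug–disease edges (the customized-graph regime).
* **Label concentration.** The 700 treat and 400 not-treat pairs are drawn
  from 100 "active" drugs × 100 "active" diseases, giving ≈ 7 indications
  per studied drug — the same order as real indication databases, and the
  collaborative structure that both the per-drug split and link-prediction
  recovery rely on. Most drugs, as in reality, carry no label.
* **Hub genes.** 25 promiscuous genes connect densely to drugs, diseases
  and each other. They create the many spurious 3-hop routes (and the
  action-space pruning pressure) that characterize real graphs; without
  them every candidate path between a pair would be a planted mechanism
  and path ranking would be trivial.
* **Publication co-occurrence.** Every concept gets solo publications;
  consecutive nodes of planted mechanisms (and treat-pair endpoints) share
  Poisson(25) publications, random background pairs Poisson(2), so the
  NGD filter and the NGD-guided demonstration ranking have a controllable
  true/false-positive structure.

What the generator does **not** emulate: the tens of node categories and
predicates of production graphs, identifier normalization and synonymy,
power-law degree tails beyond the single hub block, textual node names
with semantic content (names are synthetic, so the hashing encoder carries
no transferable signal), and any correlation between literature counts and
node degree. A green test therefore establishes that the *algorithms*
recover planted structure at desk scale — not that the defaults of this
package transfer to a production graph.

# Numerical choices and degenerate inputs

* Probability clipping $\varepsilon = 10^{-7}$ before all log-odds;
  discriminator outputs are therefore always finite.
* PageRank: igraph, damping 0.85; scores sum to 1 within $10^{-9}$.
* PCA pass-through when the input dimension is already ≤ the target, and
  the component count is capped at $n - 1$.
* Exact duplicate edges collapse on load keeping the first-seen source;
  parallel edges with distinct predicates are preserved everywhere.
* Dead-end walks terminate early; isolated nodes contribute no corpus
  pairs and keep their initialization embedding.
* All stages are deterministic given their seeds and single-threaded
  execution; the acceptance suite checks byte-identical regeneration.

# Known limitations

* The RL module is pure R with manual gradients; it is sized for
  desk-scale graphs (thousands of nodes), not production ones.
* The frozen-statistics batch-norm and the non-inductive embedding trainer
  are documented simplifications; both keep the contracts and the
  acceptance properties but differ from a GPU-scale implementation.
* The random forest grows unpruned trees to purity by default; on tiny
  crafted datasets its probabilities saturate quickly, which tests
  account for by construction.
* `evaluate_moa_paths()` enumerates all 3-hop candidate paths per pair,
  which is exponential in degree; it is intended for evaluation at desk
  scale, with the PageRank cap bounding the policy-side action spaces.
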