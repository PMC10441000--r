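# kgmoa

Knowledge-graph based drug repurposing with mechanistic explanations, in R.

Computational drug repurposing asks which existing drugs might treat which
diseases; the harder follow-up question is *why* — what chain of molecular
events connects the drug to the disease. `kgmoa` implements a two-module
framework over a directed biomedical knowledge graph (BKG) for researchers
who want both answers at once:

1. **Drug-repurposing prediction (DRP).** Every node gets an embedding that
   combines its text attributes with its graph neighborhood, trained with
   the random-walk skip-gram objective

   *L(z<sub>u</sub>) = −log σ(z<sub>u</sub>ᵀz<sub>v</sub>) −
   k·E<sub>v<sub>n</sub>∼P<sub>n</sub></sub> log σ(−z<sub>u</sub>ᵀz<sub>v<sub>n</sub></sub>)*

   where v co-occurs with u on fixed-length random walks and the k
   negatives are drawn from the degree-weighted unigram distribution. A
   random-forest classifier over concatenated pair embeddings
   [z<sub>drug</sub> ; z<sub>disease</sub>] assigns each drug–disease pair
   to one of three classes — *treat*, *not-treat*, or *unknown* (the last
   generated by negative sampling) — and its treat-class probability
   p<sub>treat</sub> ranks repurposing candidates.

2. **Mechanism-of-action (MOA) path prediction.** A reinforcement-learning
   agent walks the graph from a drug for exactly T = 3 steps (a self-loop
   action allows early stopping). Four three-layer subnetworks
   (linear → batch-norm → ELU, twice, then linear) implement an actor
   π(a|s) = softmax(**A**·MLP<sup>a</sup>(**s**)), a critic
   Q(s,a) = MLP<sup>c</sup>(**s**)·**a**, and two adversarial
   discriminators that compare the agent's path segments and meta-paths
   (category sequences) against *demonstration paths* extracted from known
   drug–target interactions and literature co-occurrence. The per-step
   reward mixes the discriminator log-odds with a decayed terminal reward
   from the DRP classifier:

   *R<sub>t</sub> = α<sub>p</sub>R<sub>p,t</sub> + α<sub>m</sub>R<sub>m,t</sub> +
   (1−α<sub>p</sub>−α<sub>m</sub>)·γ<sup>T−t</sup>·R<sub>e,T</sub>*

   Candidate 3-hop paths are then scored with
   Σ<sub>i</sub> δ<sup>i−1</sup> log(P<sub>i</sub>·N<sub>i</sub>) (δ = 0.9)
   and ranked; ranking quality is reported as MPR, MRR and Hit@K.

Supporting machinery includes knowledge-graph loading and customization
(category exclusion, low-quality-edge filters, predicate-hierarchy
deduplication, removal of all direct drug–disease edges), the
publication-based normalized Google distance (NGD) literature filter, the
per-drug 8/1/1 train/validation/test split, replacement-candidate ranking
protocols, and a fully seeded synthetic knowledge-graph generator with
planted treatments, gene modules, mechanism paths, hub genes and
publication co-occurrence — so the entire pipeline runs end-to-end with no
external data.

## Worked example

```r
library(kgmoa); library(data.table)

## a seeded synthetic knowledge graph with planted treatments and mechanisms
cfg <- synth_config(n_drugs = 40, n_diseases = 40, n_genes = 120,
                    n_pathways = 40, n_treat_pairs = 80,
                    n_not_treat_pairs = 50, n_active_drugs = 20,
                    n_active_diseases = 20, n_hub_genes = 8, seed = 1)
sim <- synth_generate(cfg)
sim$graph
#> <knowledge_graph> 240 nodes, 1181 edges, 4 categories, 7 predicates

## node embeddings: hashed attribute features + random-walk training
attr <- reduce_pca(attribute_embeddings(sim$graph, hash_encoder(64, seed = 1)), 48)
emb <- train_graph_embeddings(sim$graph, attr,
         graph_embed_config(hidden_dim = 24, epochs = 10,
                            num_negatives = 5, seed = 1))
#> embeddings: 240 nodes, 30064 corpus pairs, loss 4.170 -> 4.103

## three-class pair classifier on the training split
pairs <- split_by_drug(sim$pairs, seed = 1)
ns <- kg_node_sets(sim$graph)
train <- pairs[split == "train"]
unknown <- sample_unknown_pairs(train[label == "treat"], pairs,
                                ns$drugs, ns$diseases, seed = 1)
train_all <- rbind(train[, .(drug, disease, label)], unknown)
drp <- fit_drp(pair_features(emb, train_all), train_all$label,
               ntree = 200, seed = 1)
#> drp: 200 trees, training accuracy 1.000

## rank held-out positives among random replacement candidates
prot <- replacement_protocol("random_subset", subset_size = 60,
                             per_side = 30, repeats = 5, seed = 1)
rk <- rank_true_positives(drp, pairs[split == "test" & label == "treat"],
                          prot, emb, pairs[label == "treat"],
                          ns$drugs, ns$diseases)
per_rep <- rk[, .(mrr = mean(1 / rank)), by = rep]
sprintf("MRR %.3f +/- %.3f over %d candidate sets",
        mean(per_rep$mrr), sd(per_rep$mrr), nrow(per_rep))
#> [1] "MRR 0.274 +/- 0.005 over 5 candidate sets"
```

Each held-out treatment is ranked against 60 random drug/disease
replacements, so a chance-level MRR would be about 0.077; 0.274 means the
classifier places true treatments far up the candidate list.

```r
## mechanism-of-action agent: demonstrations + adversarial actor-critic
demo <- extract_demonstration_paths(sim$graph, train[label == "treat"],
                                    sim$drug_targets, sim$pub_map)
rl <- moa_config(hidden_dim = 16, action_emb_dim = 8, epochs = 6,
                 warmup = 2, bc_epochs = 10, seed = 1)
moa <- train_moa(moa_init(moa_env(sim$graph, attr, rl)), demo, drp, emb,
                 train[label == "treat"])

## best-ranked 3-hop mechanism paths for one held-out treatment
pair <- pairs[split == "test" & label == "treat"][1]
cand <- enumerate_paths(sim$graph, pair$drug, pair$disease, 3)
scored <- rank_paths(cand, vapply(cand, function(p) score_path(moa, p), 0))
top <- head(order(scored$rank), 3)
data.table(rank = scored$rank[top],
           score = round(scored$score[top], 2),
           path = vapply(cand[top], function(p)
             paste(p$nodes, collapse = " -> "), ""))
#>     rank score                                 path
#> 1:     1  1.17 DR0003 -> GN0076 -> PW0004 -> DI0020
#> 2:     2  1.09 DR0003 -> GN0059 -> PW0004 -> DI0020
#> 3:     3 -0.18 DR0003 -> GN0059 -> GN0117 -> DI0020
```

The two top-ranked paths are exactly the planted mechanisms for this pair:
the drug's target genes, their disease pathway, then the disease.

## Command line

A `kgx` front end for the pipeline stages ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kgx.R",package="kgmoa"))')" \
  build-kg --nodes nodes.tsv --edges edges.tsv --out kg_dir/
```

Subcommands: `simulate`, `build-kg`, `ngd-filter`, `make-pairs`,
`train-embeddings`, `extract-demo-paths`, `train-drp`, `rank`,
`train-moa`, `predict-paths`.

## Documentation

See the methods vignette (`vignettes/kgmoa-methods.Rmd`) for the model,
its assumptions, every tunable parameter, what the synthetic generator
does and does not emulate, and known limitations.
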