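# Shared fixtures.  The standard synthetic world and the models trained on
# it are expensive (minutes), so they are built lazily once per test run
# and cached in this environment; every test that uses them sees the exact
# same objects.
.fixtures <- new.env(parent = emptyenv())

# hand-made 6-node graph used by many unit tests
tiny_graph <- function() {
  nodes <- data.frame(
    id = c("d1", "d2", "z1", "g1", "g2", "p1"),
    name = c("aspirin", "ibuprofen", "headache", "ptgs2", "ptgs1", "prostaglandin"),
    category = c("Drug", "Drug", "Disease", "Gene", "Gene", "Pathway"))
  edges <- data.frame(
    subject   = c("d1", "d1", "g1", "p1", "d2", "g2", "g1"),
    predicate = c("targets", "targets", "participates_in",
                  "associated_with_condition", "targets",
                  "participates_in", "interacts_with"),
    object    = c("g1", "g2", "p1", "z1", "g2", "p1", "g2"),
    source    = c("a", "a", "b", "b", "a", "b", "c"))
  knowledge_graph(nodes, edges)
}

# small, fast synthetic world for unit-level pipeline tests
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synth_config(n_drugs = 40, n_diseases = 40, n_genes = 120,
                        n_pathways = 40, n_treat_pairs = 80,
                        n_not_treat_pairs = 50, n_active_drugs = 20,
                        n_active_diseases = 20, n_hub_genes = 8, seed = 5)
    .fixtures$small <- synth_generate(cfg)
  }
  .fixtures$small
}

# the standard world: defaults of synth_config(), used by the acceptance
# criteria on link-prediction recovery and the demonstration-path effect
std_fixture <- function() {
  if (!is.null(.fixtures$std)) return(.fixtures$std)
  sim <- synth_generate(synth_config())
  pairs <- split_by_drug(sim$pairs, seed = 3L)
  ns <- kg_node_sets(sim$graph)
  attr_full <- attribute_embeddings(sim$graph, hash_encoder(128L, seed = 2L))
  attr_red <- reduce_pca(attr_full, 100L)
  emb <- suppressMessages(train_graph_embeddings(
    sim$graph, attr_red,
    graph_embed_config(hidden_dim = 64L, epochs = 40L, num_negatives = 10L,
                       seed = 9L)))
  train <- pairs[pairs$split == "train", ]
  unknown <- sample_unknown_pairs(train[train$label == "treat", ], pairs,
                                  ns$drugs, ns$diseases, seed = 11L)
  train_all <- rbind(train[, c("drug", "disease", "label")], unknown)
  drp <- suppressMessages(fit_drp(pair_features(emb, train_all),
                                  train_all$label, ntree = 500L, seed = 4L))
  .fixtures$std <- list(sim = sim, pairs = pairs, ns = ns,
                        attr = attr_red, emb = emb,
                        train = train, train_all = train_all, drp = drp)
  .fixtures$std
}

# trained MOA models (full and no-demonstration ablation) on the standard
# world; both get the same seeded budget
moa_fixture <- function() {
  if (!is.null(.fixtures$moa)) return(.fixtures$moa)
  fx <- std_fixture()
  train_pos <- fx$train[fx$train$label == "treat", ]
  demo <- extract_demonstration_paths(fx$sim$graph, train_pos,
                                      fx$sim$drug_targets, fx$sim$pub_map)
  # deterministic subsample keeps the behavior-cloning stage CI-sized
  if (length(demo) > 1200L) demo <- demo[seq_len(1200L)]
  rl <- moa_config(max_hops = 3L, history = 2L, hidden_dim = 32L,
                   action_emb_dim = 8L, epochs = 12L, warmup = 4L,
                   bc_epochs = 10L, seed = 7L)
  env <- moa_env(fx$sim$graph, fx$attr, rl)
  full <- train_moa(moa_init(env), demo, fx$drp, fx$emb, train_pos)
  rl0 <- moa_config(alpha_p = 0, alpha_m = 0, max_hops = 3L, history = 2L,
                    hidden_dim = 32L, action_emb_dim = 8L, epochs = 12L,
                    warmup = 4L, seed = 7L)
  env0 <- moa_env(fx$sim$graph, fx$attr, rl0)
  ablation <- train_moa(moa_init(env0), list(), fx$drp, fx$emb, train_pos,
                        behavior_cloning = FALSE)
  .fixtures$moa <- list(demo = demo, full = full, ablation = ablation,
                        train_pos = train_pos)
  .fixtures$moa
}

# write a small node/edge table pair to tempfiles, return the paths
write_toy_tsvs <- function(nodes, edges) {
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  data.table::fwrite(nodes, nf, sep = "\t")
  data.table::fwrite(edges, ef, sep = "\t")
  list(nodes = nf, edges = ef)
}
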