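# brute-force path oracle: grow all edge sequences, keep simple paths
# from a to b with exactly k hops
dfs_oracle <- function(g, a, b, k) {
  e <- as.data.frame(g$edges)
  grow <- function(nodes) {
    if (length(nodes) == k + 1L)
      return(if (nodes[k + 1L] == b) list(nodes) else list())
    nxt <- e$object[e$subject == nodes[length(nodes)]]
    out <- list()
    for (v in unique(nxt)) if (!v %in% nodes)
      out <- c(out, grow(c(nodes, v)))
    out
  }
  grow(a)
}

test_that("enumerate_paths agrees with a brute-force oracle", {
  # two distinct 3-hop routes d1 -> g1 -> p1 -> z1 and d1 -> g2 -> p1 -> z1
  g <- tiny_graph()
  paths <- enumerate_paths(g, "d1", "z1", 3)
  keys <- unique(vapply(paths, function(p) paste(p$nodes, collapse = ">"), ""))
  oracle <- vapply(dfs_oracle(g, "d1", "z1", 3),
                   function(n) paste(n, collapse = ">"), "")
  expect_setequal(keys, oracle)
  expect_length(oracle, 2L)

  # disconnected pair, and exclusion of node-revisiting walks
  expect_length(enumerate_paths(g, "z1", "d1", 3), 0L)
  for (p in paths) expect_false(any(duplicated(p$nodes)))

  # parallel predicates yield distinct paths on the same node sequence
  g2 <- knowledge_graph(
    data.frame(id = c("a", "b", "c", "d"), name = "n", category = "Gene"),
    data.frame(subject = c("a", "a", "b", "c"),
               predicate = c("p", "q", "r", "r"),
               object = c("b", "b", "c", "d")))
  expect_length(enumerate_paths(g2, "a", "d", 3), 2L)
})

test_that("score_path evaluates the decayed log(P * N) sum", {
  # a chain where every state has exactly two actions (self-loop + edge);
  # with a uniform policy P_i = 1/2, N_i = 2, so every term is log(1) = 0
  g <- knowledge_graph(
    data.frame(id = c("a", "b", "c"), name = "n", category = "Gene"),
    data.frame(subject = c("a", "b"), predicate = "r", object = c("b", "c")))
  attr_tab <- attribute_embeddings(g, hash_encoder(8, seed = 1))
  cfg <- moa_config(hidden_dim = 8L, action_emb_dim = 4L, max_hops = 3L,
                    seed = 2L)
  env <- moa_env(g, attr_tab, cfg)
  model <- moa_init(env)
  model$embs$actor$node[] <- 0; model$embs$actor$pred[] <- 0  # uniform policy

  path2 <- list(nodes = c("a", "b", "c"), predicates = c("r", "r"))
  expect_equal(score_path(model, path2), 0, tolerance = 1e-12)
  path1 <- list(nodes = c("a", "b"), predicates = "r")
  expect_equal(score_path(model, path1), 0, tolerance = 1e-12)

  # raising the probability of the path's actions raises the score
  biased <- moa_init(env)
  expect_gt(max(score_path(biased, path2), -score_path(biased, path2)), 0)
  # monotonicity checked directly: nudge the actor toward the path
  bc <- behavior_clone(moa_init(env), list(path2), epochs = 60L, lr = 0.05)
  expect_gt(score_path(bc, path2), score_path(model, path2))

  # a pruned (unreachable) action gives -Inf
  gstar <- knowledge_graph(
    data.frame(id = c("s", "x", "y", "z", "sink"), name = "n",
               category = "Gene"),
    rbind(data.frame(subject = "s", predicate = "r",
                     object = c("x", "y", "z")),
          data.frame(subject = c("x", "x"), predicate = "r",
                     object = c("y", "sink"))))
  cfg1 <- moa_config(hidden_dim = 8L, action_emb_dim = 4L, neighbor_cap = 1L,
                     seed = 2L)
  env1 <- moa_env(gstar, attribute_embeddings(gstar, hash_encoder(8, 1)), cfg1)
  m1 <- moa_init(env1)
  pr <- kg_pagerank(gstar)
  kept <- names(sort(pr[c("x", "y", "z")], decreasing = TRUE))[1]
  dropped <- setdiff(c("x", "y", "z"), kept)[1]
  expect_equal(score_path(m1, list(nodes = c("s", dropped),
                                   predicates = "r")), -Inf)
})

test_that("rank_paths ranks by score with lexicographic tie-break", {
  paths <- list(list(nodes = c("a", "x", "q"), predicates = c("r", "r")),
                list(nodes = c("a", "y", "q"), predicates = c("r", "r")),
                list(nodes = c("a", "z", "q"), predicates = c("r", "r")))
  rk <- rank_paths(paths, c(3, 1, 2))
  expect_equal(rk$rank, c(1L, 3L, 2L))
  expect_equal(rk$n_candidates, rep(3L, 3))

  # ties resolved by node sequence
  rk2 <- rank_paths(paths, c(1, 1, 1))
  expect_equal(rk2$rank, c(1L, 2L, 3L))

  # ranks are a permutation of 1..n
  set.seed(1)
  rk3 <- rank_paths(paths[c(1, 2, 3)], rnorm(3))
  expect_setequal(rk3$rank, 1:3)
})

test_that("match_curated is order-insensitive node containment", {
  p <- list(nodes = c("d", "g", "p", "z"), predicates = c("a", "b", "c"))
  expect_true(match_curated(p, c("z", "other", "p", "g", "d", "more")))
  expect_false(match_curated(p, c("d", "g", "z")))
})

test_that("ranking_metrics match hand evaluation and brute force", {
  m <- ranking_metrics(c(1, 2, 4), c(10, 10, 10), K_list = c(1, 3, 5))
  expect_equal(m$mrr, (1 + 0.5 + 0.25) / 3, tolerance = 1e-12)
  expect_equal(unname(m$hit_at_k), c(1/3, 2/3, 1))

  m2 <- ranking_metrics(c(1, 5, 12), c(20, 20, 20), K_list = 10)
  expect_equal(unname(m2$hit_at_k), 2/3, tolerance = 1e-12)

  expect_equal(ranking_metrics(1, 100)$mpr, 100)     # best-rank percentile

  # brute-force recomputation on random small instances
  set.seed(2)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    r <- sample(seq_len(n), sample(1:5, 1), replace = TRUE)
    got <- ranking_metrics(r, rep(n, length(r)), K_list = c(1, 3, 10))
    expect_equal(got$mrr, sum(1 / r) / length(r))
    expect_equal(got$mpr, 100 * sum(n - r + 1) / (n * length(r)))
    expect_equal(unname(got$hit_at_k),
                 c(sum(r <= 1), sum(r <= 3), sum(r <= 10)) / length(r))
    expect_true(all(diff(got$hit_at_k) >= 0))    # non-decreasing in K
    expect_true(got$mrr > 0 && got$mrr <= 1)
    expect_true(got$mpr > 0 && got$mpr <= 100)
  }
  expect_error(ranking_metrics(integer(), integer()), "empty")
  expect_error(ranking_metrics(5, 4), "ranks")
})

test_that("classification metrics implement accuracy and macro F1", {
  truth <- c("treat", "treat", "not_treat", "unknown")
  expect_equal(classification_metrics(truth, truth),
               list(acc = 1, macro_f1 = 1))
  wrong <- c("not_treat", "unknown", "treat", "treat")
  expect_equal(classification_metrics(truth, wrong)$acc, 0)

  # TP = 8, FP = 2, FN = 2 for class treat -> F1_treat = 0.8
  tr <- c(rep("treat", 10), rep("not_treat", 10))
  pr <- c(rep("treat", 8), "not_treat", "not_treat",
          "treat", "treat", rep("not_treat", 8))
  got <- classification_metrics(tr, pr)
  f1_treat <- 2 * (8/10) * (8/10) / (8/10 + 8/10)
  expect_equal(f1_treat, 0.8)
  f1_nt <- 2 * (8/10) * (8/10) / (8/10 + 8/10)
  expect_equal(got$macro_f1, mean(c(f1_treat, f1_nt)))
  expect_equal(got$acc, 16 / 20)

  # excluding unknown recomputes over the remaining two classes
  tru <- c("treat", "not_treat", "unknown", "unknown")
  prd <- c("treat", "not_treat", "treat", "not_treat")
  ex <- classification_metrics(tru, prd, exclude_unknown = TRUE)
  expect_equal(ex$acc, 1)
  expect_equal(ex$macro_f1, 1)

  # a class with zero true and predicted members warns and scores 0
  expect_warning(
    z <- classification_metrics(c("a", "b"), c("a", "b"),
                                classes = c("a", "b", "c")),
    "no true or predicted")
  expect_equal(z$macro_f1, 2 / 3)
})

test_that("evaluate_moa_paths takes the best rank over matched paths", {
  g <- tiny_graph()
  attr_tab <- attribute_embeddings(g, hash_encoder(8, seed = 1))
  cfg <- moa_config(hidden_dim = 8L, action_emb_dim = 4L, seed = 2L)
  env <- moa_env(g, attr_tab, cfg)
  model <- moa_init(env)
  refs <- list(list(nodes = c("d1", "g1", "p1", "z1"),
                    predicates = c("targets", "participates_in",
                                   "associated_with_condition")),
               list(nodes = c("d1", "g2", "p1", "z1"),
                    predicates = c("targets", "participates_in",
                                   "associated_with_condition")))
  ev <- evaluate_moa_paths(model, g, data.frame(drug = "d1", disease = "z1"),
                           refs)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_candidates, 2L)
  expect_equal(ev$rank, 1L)   # both candidates matched: best rank is 1
})
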