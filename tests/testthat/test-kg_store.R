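test_that("kg_load reads node/edge TSVs and validates them", {
  nodes <- data.frame(id = c("a", "b", "c"), name = c("A", "B", "C"),
                      category = c("Drug", "Gene", "Disease"))
  edges <- data.frame(subject = c("a", "b"), predicate = c("targets", "rel"),
                      object = c("b", "c"), source = "s")
  f <- write_toy_tsvs(nodes, edges)
  g <- suppressMessages(kg_load(f$nodes, f$edges))
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)

  # dangling endpoint
  bad <- write_toy_tsvs(nodes, rbind(edges,
    data.frame(subject = "a", predicate = "rel", object = "zzz", source = "s")))
  expect_error(suppressMessages(kg_load(bad$nodes, bad$edges)), "zzz")

  # exact duplicate rows collapse to one edge, first source kept
  dup <- write_toy_tsvs(nodes, rbind(edges, edges[1, ]))
  g2 <- suppressMessages(kg_load(dup$nodes, dup$edges))
  expect_equal(nrow(g2$edges), 2L)

  # missing column is a format error
  expect_error(knowledge_graph(nodes[, c("id", "name")], edges), "category")
})

test_that("customize_graph applies all four filters", {
  nodes <- data.frame(
    id = c("d", "z", "g", "loc"),
    name = c("drug", "disease", "gene", "place"),
    category = c("Drug", "Disease", "Gene", "GeographicLocation"))
  edges <- data.frame(
    subject   = c("d", "d", "g", "d", "g", "g"),
    predicate = c("treats", "targets", "related_to", "interacts_with",
                  "interacts_with", "related_to"),
    object    = c("z", "g", "loc", "g", "z", "z"),
    source    = c("good", "good", "good", "lowq", "good", "good"))
  g <- knowledge_graph(nodes, edges)
  cfg <- kg_filter_config(
    excluded_categories = "GeographicLocation",
    low_quality_sources = "lowq",
    predicate_hierarchy = data.frame(child = "interacts_with",
                                     parent = "related_to"),
    drop_drug_disease_edges = TRUE)
  out <- suppressMessages(kg_customize(g, cfg))

  expect_false("loc" %in% out$nodes$id)           # excluded category gone
  expect_true(all(c("d", "z") %in% out$nodes$id)) # endpoints retained
  expect_false(any(out$edges$predicate == "treats"))   # drug-disease edge gone
  expect_false(any(out$edges$source == "lowq"))        # low-quality gone
  # g->z had both interacts_with and its parent related_to: parent removed
  gz <- out$edges[out$edges$subject == "g" & out$edges$object == "z", ]
  expect_equal(gz$predicate, "interacts_with")

  # idempotence and monotone counts
  out2 <- suppressMessages(kg_customize(out, cfg))
  expect_equal(out2$edges, out$edges)
  expect_equal(out2$nodes, out$nodes)
  expect_lte(nrow(out$edges), nrow(g$edges))

  # invariant: no remaining edge joins a drug and a disease
  ns <- kg_node_sets(out)
  e <- out$edges
  expect_false(any((e$subject %in% ns$drugs & e$object %in% ns$diseases) |
                   (e$subject %in% ns$diseases & e$object %in% ns$drugs)))
})

test_that("node_sets follows the category vocabulary", {
  nodes <- data.frame(
    id = c("a", "b", "c", "d"),
    name = "x",
    category = c("Drug", "Drug", "DiseaseOrPhenotypicFeature", "Gene"))
  g <- knowledge_graph(nodes,
                       data.frame(subject = "a", predicate = "targets",
                                  object = "d"))
  ns <- kg_node_sets(g)
  expect_setequal(ns$drugs, c("a", "b"))
  expect_equal(ns$diseases, "c")          # default disease category list

  g2 <- knowledge_graph(nodes,
                        data.frame(subject = "a", predicate = "t", object = "d"),
                        drug_categories = character(),
                        disease_categories = character())
  ns2 <- kg_node_sets(g2)
  expect_length(ns2$drugs, 0L)
  expect_length(ns2$diseases, 0L)

  # a node in both drug and disease vocabularies is a validation error
  expect_error(knowledge_graph(nodes,
                               data.frame(subject = "a", predicate = "t",
                                          object = "d"),
                               drug_categories = "Drug",
                               disease_categories = "Drug"),
               "both")
})

test_that("out_edges is deterministic and keeps parallel edges", {
  g <- tiny_graph()
  expect_equal(nrow(kg_out_edges(g, "z1")), 0L)
  # two predicates d1->g2? d1 targets g1 and g2: two rows, sorted
  oe <- kg_out_edges(g, "d1")
  expect_equal(oe$object, c("g1", "g2"))
  expect_identical(kg_out_edges(g, "g1"), kg_out_edges(g, "g1"))
  expect_error(kg_out_edges(g, "nope"), "unknown node")

  # parallel predicates to the same neighbor yield distinct rows
  g2 <- knowledge_graph(
    data.frame(id = c("a", "b"), name = "n", category = "Gene"),
    data.frame(subject = c("a", "a"), predicate = c("p", "q"),
               object = c("b", "b")))
  expect_equal(nrow(kg_out_edges(g2, "a")), 2L)
})

test_that("pagerank matches a power-iteration oracle", {
  # independent oracle: damped power iteration with uniform teleport and
  # dangling-node mass redistribution (igraph's convention)
  pr_oracle <- function(g, d = 0.85, iters = 2000) {
    ids <- g$nodes$id; n <- length(ids)
    M <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(nrow(g$edges)))
      M[g$edges$subject[i], g$edges$object[i]] <-
        M[g$edges$subject[i], g$edges$object[i]] + 1
    rs <- rowSums(M)
    x <- rep(1 / n, n)
    for (it in seq_len(iters)) {
      xn <- rep((1 - d) / n, n)
      for (i in seq_len(n)) {
        if (rs[i] > 0) xn <- xn + d * x[i] * M[i, ] / rs[i]
        else xn <- xn + d * x[i] / n
      }
      x <- xn
    }
    stats::setNames(as.numeric(x), ids)
  }

  # single isolated node
  g1 <- knowledge_graph(
    data.frame(id = "a", name = "a", category = "Gene"),
    data.frame(subject = character(), predicate = character(),
               object = character()))
  expect_equal(unname(kg_pagerank(g1)), 1)

  # symmetric 2-cycle
  g2 <- knowledge_graph(
    data.frame(id = c("a", "b"), name = "n", category = "Gene"),
    data.frame(subject = c("a", "b"), predicate = "r", object = c("b", "a")))
  expect_equal(unname(kg_pagerank(g2)), c(0.5, 0.5), tolerance = 1e-9)

  # 10-node star: leaves point at the hub
  ids <- c("hub", paste0("leaf", 1:9))
  g3 <- knowledge_graph(
    data.frame(id = ids, name = ids, category = "Gene"),
    data.frame(subject = ids[-1], predicate = "r", object = "hub"))
  pr <- kg_pagerank(g3)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(pr > 0))
  expect_equal(pr, pr_oracle(g3), tolerance = 1e-6)
})
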