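#' @useDynLib kgmoa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

.default_drug_categories    <- c("Drug", "Small Molecule", "SmallMolecule")
.default_disease_categories <- c("Disease", "PhenotypicFeature",
                                 "BehavioralFeature",
                                 "DiseaseOrPhenotypicFeature")

#' Construct a biomedical knowledge graph
#'
#' A knowledge graph is a directed multigraph of typed biomedical nodes
#' (drugs, diseases, genes, pathways, ...) connected by predicated edges.
#' Parallel edges with distinct predicates are allowed; exact duplicate
#' `(subject, predicate, object)` rows are collapsed, keeping the
#' first-seen source tag.
#'
#' @param nodes data.frame with columns `id`, `name`, `category`.
#' @param edges data.frame with columns `subject`, `predicate`, `object` and
#'   optionally `source` and `provenance_count` (defaults `"unknown"` / 1).
#' @param drug_categories,disease_categories character vectors of node
#'   categories treated as drugs / diseases.  The defaults follow the usual
#'   Biolink-style vocabulary ("Drug"/"Small Molecule" and the four
#'   disease-like categories).
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges,
                            drug_categories = .default_drug_categories,
                            disease_categories = .default_disease_categories) {
  nodes <- as.data.table(nodes)
  edges <- as.data.table(edges)
  req_n <- c("id", "name", "category")
  req_e <- c("subject", "predicate", "object")
  if (!all(req_n %in% names(nodes)))
    stop("node table must have columns: ", paste(req_n, collapse = ", "))
  if (!all(req_e %in% names(edges)))
    stop("edge table must have columns: ", paste(req_e, collapse = ", "))
  if (!"source" %in% names(edges)) edges[, source := "unknown"]
  if (!"provenance_count" %in% names(edges)) edges[, provenance_count := 1L]
  edges[, provenance_count := as.integer(provenance_count)]
  nodes <- nodes[, c("id", "name", "category"), with = FALSE]
  edges <- edges[, c("subject", "predicate", "object", "source",
                     "provenance_count"), with = FALSE]

  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(!nzchar(nodes$category)) || anyNA(nodes$category))
    stop("every node needs a non-empty category")
  # collapse exact duplicate (subject, predicate, object) rows, first wins
  edges <- unique(edges, by = c("subject", "predicate", "object"))
  bad <- setdiff(c(edges$subject, edges$object), nodes$id)
  if (length(bad))
    stop("edge endpoint(s) not present in node table: ",
         paste(utils::head(bad, 5), collapse = ", "))
  both <- intersect(drug_categories, disease_categories)
  if (length(both))
    stop("categories cannot be both drug and disease: ",
         paste(both, collapse = ", "))

  setkey(edges, subject)
  g <- list(nodes = nodes, edges = edges,
            drug_categories = drug_categories,
            disease_categories = disease_categories)
  class(g) <- "knowledge_graph"
  g
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d edges, %d categories, %d predicates\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$category)),
              length(unique(x$edges$predicate))))
  invisible(x)
}

#' Load a knowledge graph from node/edge TSV tables
#'
#' `nodes.tsv` must have a header with columns `id`, `name`, `category`;
#' `edges.tsv` must have `subject`, `predicate`, `object` and optionally
#' `source`, `provenance_count`.
#'
#' @param node_table,edge_table paths to TSV files.
#' @inheritParams knowledge_graph
#' @return A `knowledge_graph`.
#' @export
kg_load <- function(node_table, edge_table,
                    drug_categories = .default_drug_categories,
                    disease_categories = .default_disease_categories) {
  nodes <- fread(node_table, sep = "\t", colClasses = "character")
  edges <- fread(edge_table, sep = "\t")
  g <- knowledge_graph(nodes, edges, drug_categories, disease_categories)
  message(sprintf("loaded knowledge graph: %d nodes, %d edges",
                  nrow(g$nodes), nrow(g$edges)))
  g
}

#' Write a knowledge graph to a directory as TSV tables
#'
#' @param g a `knowledge_graph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
kg_write <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(g$nodes, file.path(dir, "nodes.tsv"), sep = "\t")
  fwrite(g$edges, file.path(dir, "edges.tsv"), sep = "\t")
  invisible(dir)
}

#' Filter configuration for knowledge-graph customization
#'
#' Encodes the pre-processing applied to a raw graph before model training:
#' dropping whole categories of nodes irrelevant to drug repurposing,
#' dropping low-quality edges (a provenance deny-list plus a minimum
#' supporting-publication count), collapsing hierarchically redundant
#' predicate pairs, and removing every direct drug--disease edge so that
#' labels cannot leak through one-hop shortcuts.
#'
#' @param excluded_categories node categories to drop entirely.
#' @param low_quality_sources edge `source` values to drop.
#' @param min_provenance_count drop edges whose `provenance_count` is below
#'   this (0 keeps everything).
#' @param predicate_hierarchy optional data.frame with columns
#'   `child`, `parent`; when a node pair carries both predicates the
#'   (redundant) parent edge is removed.
#' @param drop_drug_disease_edges drop every edge directly connecting a drug
#'   node and a disease node, in either direction.
#' @return An object of class `kg_filter_config`.
#' @export
kg_filter_config <- function(excluded_categories = character(),
                             low_quality_sources = character(),
                             min_provenance_count = 0L,
                             predicate_hierarchy = NULL,
                             drop_drug_disease_edges = TRUE) {
  stopifnot(min_provenance_count >= 0)
  if (!is.null(predicate_hierarchy)) {
    predicate_hierarchy <- as.data.table(predicate_hierarchy)
    stopifnot(all(c("child", "parent") %in% names(predicate_hierarchy)))
  }
  structure(list(excluded_categories = excluded_categories,
                 low_quality_sources = low_quality_sources,
                 min_provenance_count = as.integer(min_provenance_count),
                 predicate_hierarchy = predicate_hierarchy,
                 drop_drug_disease_edges = isTRUE(drop_drug_disease_edges)),
            class = "kg_filter_config")
}

#' Customize a knowledge graph for model training
#'
#' Applies, in order: (i) removal of nodes in excluded categories together
#' with their incident edges, (ii) the low-quality edge filter, (iii) removal
#' of hierarchically redundant parent-predicate edges, and (iv) removal of
#' all direct drug--disease edges.  The operation is idempotent and never
#' removes drug or disease nodes themselves.
#'
#' @param g a `knowledge_graph`.
#' @param cfg a [kg_filter_config()].
#' @return A new, filtered `knowledge_graph`.
#' @export
kg_customize <- function(g, cfg) {
  stopifnot(inherits(g, "knowledge_graph"), inherits(cfg, "kg_filter_config"))
  if (cfg$drop_drug_disease_edges &&
      length(intersect(cfg$excluded_categories,
                       c(g$drug_categories, g$disease_categories))))
    stop("excluded_categories would remove drug/disease nodes")
  nodes <- g$nodes[!category %in% cfg$excluded_categories]
  keep_ids <- nodes$id
  edges <- g$edges[subject %in% keep_ids & object %in% keep_ids]
  if (length(cfg$low_quality_sources))
    edges <- edges[!source %in% cfg$low_quality_sources]
  if (cfg$min_provenance_count > 0)
    edges <- edges[provenance_count >= cfg$min_provenance_count]
  if (!is.null(cfg$predicate_hierarchy) && nrow(edges)) {
    h <- cfg$predicate_hierarchy
    # a (subject, object) pair holding both a child predicate and its parent
    # keeps only the more specific child edge
    child_edges <- edges[predicate %in% h$child]
    if (nrow(child_edges)) {
      redundant <- merge(child_edges[, .(subject, object, child = predicate)],
                         h, by = "child", allow.cartesian = TRUE)
      drop_keys <- unique(redundant[, .(subject, object, predicate = parent)])
      edges <- edges[!drop_keys, on = c("subject", "object", "predicate")]
    }
  }
  if (cfg$drop_drug_disease_edges && nrow(edges)) {
    cat_of <- stats::setNames(nodes$category, nodes$id)
    s_drug <- cat_of[edges$subject] %in% g$drug_categories
    s_dis  <- cat_of[edges$subject] %in% g$disease_categories
    o_drug <- cat_of[edges$object]  %in% g$drug_categories
    o_dis  <- cat_of[edges$object]  %in% g$disease_categories
    edges <- edges[!((s_drug & o_dis) | (s_dis & o_drug))]
  }
  message(sprintf("customize: %d -> %d nodes, %d -> %d edges",
                  nrow(g$nodes), nrow(nodes), nrow(g$edges), nrow(edges)))
  knowledge_graph(nodes, edges, g$drug_categories, g$disease_categories)
}

#' Drug and disease node-id sets of a graph
#'
#' @param g a `knowledge_graph`.
#' @return list with character vectors `drugs` and `diseases`.
#' @export
kg_node_sets <- function(g) {
  list(drugs    = g$nodes[category %in% g$drug_categories, id],
       diseases = g$nodes[category %in% g$disease_categories, id])
}

#' Outgoing edges of a node
#'
#' Returned in deterministic order, sorted by `(predicate, object)`;
#' parallel edges yield distinct rows.
#'
#' @param g a `knowledge_graph`.
#' @param v node id.
#' @return data.table with columns `predicate`, `object`.
#' @export
kg_out_edges <- function(g, v) {
  if (!v %in% g$nodes$id) stop("unknown node: ", v)
  out <- g$edges[.(v), .(predicate, object), nomatch = NULL]
  setorder(out, predicate, object)
  out[]
}

#' PageRank scores of the directed graph
#'
#' Damping factor 0.85; parallel edges count with their multiplicity.
#' Scores are positive and sum to one.
#'
#' @param g a `knowledge_graph`.
#' @param damping damping factor.
#' @return named numeric vector over all node ids.
#' @export
kg_pagerank <- function(g, damping = 0.85) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, .(from = subject, to = object)],
    directed = TRUE, vertices = g$nodes[, .(name = id)])
  pr <- igraph::page_rank(ig, damping = damping)$vector
  pr[g$nodes$id]
}

#' Node category lookup
#' @param g a `knowledge_graph`.
#' @return named character vector id -> category.
#' @export
kg_categories <- function(g) stats::setNames(g$nodes$category, g$nodes$id)
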