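#' Configuration for the synthetic knowledge-graph generator
#'
#' The generator emulates a customized biomedical knowledge graph at desk
#' scale: four node categories (Drug, Gene, Pathway, Disease), planted
#' treat pairs each explained by a 2- or 3-hop mechanism path through a
#' known drug target, decoy edges, no direct drug--disease edges (matching
#' the customized-graph regime), and publication co-occurrence counts that
#' are Poisson with a higher mean along planted mechanism edges than
#' elsewhere.
#'
#' Defaults give roughly 2,000 nodes and 10,000 edges - large enough to
#' exercise every code path, small enough for single-CPU test runs.
#'
#' @param n_drugs,n_diseases,n_genes,n_pathways node counts per category.
#' @param n_treat_pairs,n_not_treat_pairs planted labeled pair counts.
#' @param n_active_drugs,n_active_diseases sizes of the drug and disease
#'   subsets labeled pairs are drawn from.  Real label sources concentrate
#'   on studied compounds and diseases, so drugs carry several indications
#'   and diseases several treatments - the collaborative structure both the
#'   per-drug split and link-prediction recovery rely on.
#' @param mechanism_hops 2 (drug-gene-disease) or 3
#'   (drug-gene-pathway-disease).
#' @param module_size number of genes in each disease's gene module.
#' @param targets_per_pair module genes targeted by a treating drug; each
#'   yields one planted mechanism path for the pair.
#' @param decoy_edge_rate mean number of decoy out-edges per node.
#' @param n_hub_genes number of promiscuous hub genes.  Hubs connect
#'   densely to drugs, diseases and each other, creating the many spurious
#'   multi-hop routes (and the pruning pressure) that characterize real
#'   biomedical graphs; mechanism-path retrieval must learn to avoid them.
#' @param hub_drug_p,hub_disease_p,hub_hub_p,gene_hub_p connection
#'   probabilities of hub genes to drugs, diseases, other hubs, and from
#'   ordinary genes.
#' @param pub_lambda_signal,pub_lambda_noise Poisson means for shared
#'   publication counts on planted-mechanism node pairs vs background pairs;
#'   signal must exceed noise.
#' @param seed integer RNG seed; the whole artifact is a deterministic
#'   function of the config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 520L, n_diseases = 520L, n_genes = 1560L,
                         n_pathways = 520L, n_treat_pairs = 700L,
                         n_not_treat_pairs = 400L, n_active_drugs = 100L,
                         n_active_diseases = 100L,
                         mechanism_hops = 3L,
                         module_size = 3L, targets_per_pair = 2L,
                         decoy_edge_rate = 1.5, n_hub_genes = 25L,
                         hub_drug_p = 0.2, hub_disease_p = 0.2,
                         hub_hub_p = 0.6, gene_hub_p = 0.05,
                         pub_lambda_signal = 25,
                         pub_lambda_noise = 2, seed = 42L) {
  stopifnot(n_drugs > 0, n_diseases > 0, n_genes > 0, n_pathways > 0,
            n_treat_pairs > 0, n_not_treat_pairs > 0,
            mechanism_hops %in% c(2L, 3L),
            module_size >= targets_per_pair, targets_per_pair >= 1L,
            n_genes >= module_size,
            pub_lambda_signal > pub_lambda_noise, pub_lambda_noise > 0)
  stopifnot(n_active_drugs <= n_drugs, n_active_diseases <= n_diseases)
  if (n_treat_pairs + n_not_treat_pairs > n_active_drugs * n_active_diseases)
    stop("more labeled pairs requested than active drug x disease combinations")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic knowledge graph with ground truth
#'
#' Emits a `knowledge_graph`, labeled pairs, a concept-publication map,
#' known drug-target interactions and a ground-truth manifest of planted
#' mechanism paths.  Every planted treat pair has at least one walkable
#' mechanism path whose second node is that drug's recorded target.
#'
#' @param cfg a [synth_config()].
#' @return list of class `kg_simulation`: `graph`, `pairs` (treat +
#'   not_treat, unsplit), `pub_map`, `drug_targets`, `truth` (list with
#'   `treat_pairs`, `not_treat_pairs`, `mechanism_paths`, `drug_targets`),
#'   and `config`.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  drugs    <- sprintf("DR%04d", seq_len(cfg$n_drugs))
  diseases <- sprintf("DI%04d", seq_len(cfg$n_diseases))
  genes    <- sprintf("GN%04d", seq_len(cfg$n_genes))
  pathways <- sprintf("PW%04d", seq_len(cfg$n_pathways))
  nodes <- data.table(
    id = c(drugs, diseases, genes, pathways),
    name = c(sprintf("drug %d", seq_along(drugs)),
             sprintf("disease %d", seq_along(diseases)),
             sprintf("gene %d", seq_along(genes)),
             sprintf("pathway %d", seq_along(pathways))),
    category = rep(c("Drug", "Disease", "Gene", "Pathway"),
                   c(length(drugs), length(diseases), length(genes),
                     length(pathways))))

  # labeled pairs: drawn without replacement from the grid of "active"
  # drugs (drugs with studied indications) x all diseases; most drugs in a
  # real graph carry no label at all
  n_lab <- cfg$n_treat_pairs + cfg$n_not_treat_pairs
  na_d <- cfg$n_active_drugs; na_z <- cfg$n_active_diseases
  cell <- sample.int(na_d * na_z, n_lab)
  pair_dt <- data.table(drug = drugs[(cell - 1L) %% na_d + 1L],
                        disease = diseases[(cell - 1L) %/% na_d + 1L])
  treat <- pair_dt[seq_len(cfg$n_treat_pairs)]
  not_treat <- pair_dt[(cfg$n_treat_pairs + 1L):n_lab]

  # every disease owns a gene module (and, in 3-hop mode, a pathway its
  # module genes participate in); a treating drug targets several module
  # genes, each giving one planted mechanism path - redundant mechanisms
  # are what make the treatment signal recoverable, as in real graphs
  # modules are dealt from a shuffled gene deck so overlap between two
  # diseases' modules is minimal at the configured gene pool size
  n_ord <- cfg$n_genes - min(cfg$n_hub_genes, cfg$n_genes)
  deck <- genes[sample.int(n_ord)]
  slot <- (seq_len(cfg$n_diseases * cfg$module_size) - 1L) %% n_ord + 1L
  module <- split(deck[slot], rep(seq_len(cfg$n_diseases),
                                  each = cfg$module_size))
  names(module) <- diseases
  dis_pathway <- pathways[sample.int(cfg$n_pathways, cfg$n_diseases,
                                     replace = TRUE)]
  names(dis_pathway) <- diseases
  module_edges <- rbindlist(lapply(diseases, function(z) {
    # association edges run in both directions, as in real curated graphs
    # (gene biomarker-for disease / disease has-basis-in gene)
    fwd <- if (cfg$mechanism_hops == 2L)
      data.table(subject = module[[z]],
                 predicate = "gene_associated_with_condition", object = z)
    else
      rbind(data.table(subject = module[[z]], predicate = "participates_in",
                       object = dis_pathway[[z]]),
            data.table(subject = dis_pathway[[z]],
                       predicate = "associated_with_condition", object = z))
    rbind(fwd, data.table(subject = z, predicate = "condition_has_basis_in",
                          object = module[[z]]))
  }))
  module_edges[, source := "disease_module"]

  mech <- list()
  target_rows <- vector("list", nrow(treat))
  target_edges <- vector("list", nrow(treat))
  for (i in seq_len(nrow(treat))) {
    d <- treat$drug[i]; z <- treat$disease[i]
    tg <- sample(module[[z]], cfg$targets_per_pair)
    target_rows[[i]] <- data.table(drug = d, target = tg)
    target_edges[[i]] <- rbind(
      data.table(subject = d, predicate = "targets", object = tg,
                 source = "drug_target"),
      data.table(subject = tg, predicate = "targeted_by", object = d,
                 source = "drug_target"))
    for (g in tg)
      mech[[length(mech) + 1L]] <-
        if (cfg$mechanism_hops == 2L)
          list(nodes = c(d, g, z),
               predicates = c("targets", "gene_associated_with_condition"))
        else
          list(nodes = c(d, g, dis_pathway[[z]], z),
               predicates = c("targets", "participates_in",
                              "associated_with_condition"))
  }
  mech_edges <- list(module_edges, rbindlist(target_edges))
  drug_targets <- unique(rbindlist(target_rows))

  # promiscuous hub genes: dense, unspecific connectivity
  nh <- min(cfg$n_hub_genes, cfg$n_genes)
  hubs <- genes[seq.int(cfg$n_genes - nh + 1L, cfg$n_genes)]
  bern_edges <- function(from, to, p, pred) {
    grid <- CJ(subject = from, object = to)[subject != object]
    grid <- grid[stats::runif(nrow(grid)) < p]
    if (nrow(grid)) grid[, predicate := pred] else NULL
  }
  hub_edges <- rbindlist(list(
    bern_edges(drugs, hubs, cfg$hub_drug_p, "interacts_with"),
    bern_edges(hubs, diseases, cfg$hub_disease_p, "related_to"),
    bern_edges(hubs, hubs, cfg$hub_hub_p, "interacts_with"),
    bern_edges(setdiff(genes, hubs), hubs, cfg$gene_hub_p, "interacts_with")),
    use.names = TRUE)
  if (!is.null(hub_edges) && nrow(hub_edges)) hub_edges[, source := "hub"]

  # decoy edges: random typed pairs, never directly drug--disease
  n_decoy <- round(cfg$decoy_edge_rate * nrow(nodes))
  cat_of <- stats::setNames(nodes$category, nodes$id)
  s <- sample(nodes$id, 2L * n_decoy, replace = TRUE)
  o <- sample(nodes$id, 2L * n_decoy, replace = TRUE)
  keep <- s != o &
    !((cat_of[s] == "Drug" & cat_of[o] == "Disease") |
      (cat_of[s] == "Disease" & cat_of[o] == "Drug")) &
    cat_of[o] != "Drug"              # nothing points back into drugs
  decoy <- data.table(subject = s[keep], object = o[keep])[seq_len(min(sum(keep), n_decoy))]
  decoy[, predicate := "related_to"]
  decoy[, source := "decoy"]

  edges <- rbindlist(c(mech_edges, list(hub_edges), list(decoy)),
                     use.names = TRUE)
  edges[, provenance_count := 1L]
  g <- knowledge_graph(nodes, edges)

  # publication map: per-concept solo publications plus shared blocks with
  # Poisson(signal) counts on mechanism-adjacent pairs (and treat endpoints)
  # and Poisson(noise) counts on random background pairs
  pub_counter <- new.env(parent = emptyenv()); pub_counter$n <- 0L
  new_pubs <- function(k) {
    if (k <= 0L) return(character())
    ids <- sprintf("PMID%07d", pub_counter$n + seq_len(k))
    pub_counter$n <- pub_counter$n + k
    ids
  }
  pubs <- stats::setNames(vector("list", nrow(nodes)), nodes$id)
  for (id in nodes$id) pubs[[id]] <- new_pubs(5L + stats::rpois(1L, 15))
  add_shared <- function(a, b, lambda) {
    k <- stats::rpois(1L, lambda)
    if (k > 0L) {
      shared <- new_pubs(k)
      pubs[[a]] <<- c(pubs[[a]], shared)
      pubs[[b]] <<- c(pubs[[b]], shared)
    }
  }
  signal_pairs <- unique(rbindlist(lapply(mech, function(m)
    data.table(a = m$nodes[-length(m$nodes)], b = m$nodes[-1L]))))
  for (i in seq_len(nrow(signal_pairs)))
    add_shared(signal_pairs$a[i], signal_pairs$b[i], cfg$pub_lambda_signal)
  for (i in seq_len(nrow(treat)))
    add_shared(treat$drug[i], treat$disease[i], cfg$pub_lambda_signal)
  n_noise <- 2L * nrow(nodes)
  na <- sample(nodes$id, n_noise, replace = TRUE)
  nb <- sample(nodes$id, n_noise, replace = TRUE)
  for (i in seq_len(n_noise))
    if (na[i] != nb[i]) add_shared(na[i], nb[i], cfg$pub_lambda_noise)
  pub_map <- concept_pub_map(pubs, total_pairs = max(1e6, 10 * pub_counter$n))

  pairs <- rbind(treat[, .(drug, disease, label = "treat")],
                 not_treat[, .(drug, disease, label = "not_treat")])
  pairs[, `:=`(sources = "synthetic", split = "unassigned")]

  structure(list(graph = g, pairs = pairs, pub_map = pub_map,
                 drug_targets = drug_targets,
                 truth = list(treat_pairs = treat, not_treat_pairs = not_treat,
                              mechanism_paths = mech,
                              drug_targets = drug_targets),
                 config = cfg),
            class = "kg_simulation")
}

#' Write a simulation to a directory in the package file formats
#'
#' Produces `nodes.tsv`, `edges.tsv`, `pairs.tsv`, `concept_pubs.tsv`,
#' `drug_targets.tsv`, `mechanism_paths.jsonl` and `manifest.json` - all
#' loadable with the package readers.
#'
#' @param sim a `kg_simulation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
synth_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kg_write(sim$graph, dir)
  write_pairs(sim$pairs, file.path(dir, "pairs.tsv"))
  write_concept_pubs(sim$pub_map, file.path(dir, "concept_pubs.tsv"))
  fwrite(sim$drug_targets, file.path(dir, "drug_targets.tsv"), sep = "\t")
  write_paths_jsonl(sim$truth$mechanism_paths,
                    file.path(dir, "mechanism_paths.jsonl"))
  manifest <- list(seed = sim$config$seed,
                   n_nodes = nrow(sim$graph$nodes),
                   n_edges = nrow(sim$graph$edges),
                   n_treat = nrow(sim$truth$treat_pairs),
                   n_not_treat = nrow(sim$truth$not_treat_pairs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Two-community fixture graph for embedding tests
#'
#' A stochastic-block-model style directed graph: two communities with dense
#' within-community and sparse between-community edges, all nodes category
#' `"Gene"`.  Used to check that the embedding objective separates
#' communities.
#'
#' @param n_per nodes per community.
#' @param p_in,p_out directed edge probabilities within / between
#'   communities.
#' @param seed integer RNG seed.
#' @return list with `graph` (a `knowledge_graph`) and `labels` (integer
#'   community id per node, named).
#' @export
two_community_graph <- function(n_per = 30L, p_in = 0.25, p_out = 0.02,
                                seed = 7L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(2L * n_per))
  labels <- stats::setNames(rep(1:2, each = n_per), ids)
  pairs <- CJ(subject = ids, object = ids)[subject != object]
  same <- labels[pairs$subject] == labels[pairs$object]
  p <- ifelse(same, p_in, p_out)
  pairs <- pairs[stats::runif(nrow(pairs)) < p]
  nodes <- data.table(id = ids, name = ids, category = "Gene")
  pairs[, `:=`(predicate = "related_to", source = "sbm")]
  g <- knowledge_graph(nodes, pairs)
  list(graph = g, labels = labels)
}
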