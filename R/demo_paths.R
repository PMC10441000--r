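# adjacency list of (predicate, object) rows keyed by subject
.kg_adj <- function(g) {
  e <- g$edges[, .(subject, predicate, object)]
  split(e[, .(predicate, object)], e$subject)
}

# depth-first enumeration of simple paths from `from` to `to` with at most
# (or exactly) `hops` edges
.dfs_paths <- function(adj, from, to, hops, exact = FALSE) {
  res <- list()
  walk <- function(nodes, preds) {
    cur <- nodes[length(nodes)]
    nh <- length(preds)
    if (cur == to && nh >= 1L && (!exact || nh == hops)) {
      res[[length(res) + 1L]] <<- list(nodes = nodes, predicates = preds)
      return(invisible())
    }
    if (nh >= hops) return(invisible())
    out <- adj[[cur]]
    if (is.null(out)) return(invisible())
    for (i in seq_len(nrow(out))) {
      nxt <- out$object[i]
      if (nxt %in% nodes) next            # simple paths only
      walk(c(nodes, nxt), c(preds, out$predicate[i]))
    }
  }
  walk(from, character())
  res
}

#' Extract demonstration paths from known drug-target interactions
#'
#' For each treat pair, enumerates knowledge-graph paths
#' drug -> target -> ... -> disease of at most `max_hops` edges whose second
#' node is a known target of that drug.  When a pair admits more than
#' `per_pair_cap` such paths, the cap best by mean literature closeness of
#' consecutive nodes are kept (lower mean NGD preferred; node pairs with no
#' co-occurrence score worst), with lexicographic node-sequence tie-break.
#' The result is deduplicated and deterministic.
#'
#' @param g a `knowledge_graph`.
#' @param treat_pairs data.frame of treat pairs (`drug`, `disease`).
#' @param drug_targets data.frame with `drug`, `target`.
#' @param pub_map a [concept_pub_map()] for NGD ranking.
#' @param max_hops maximum path length in edges (default 3).
#' @param per_pair_cap per-pair cap (default 50).
#' @return list of paths, each `list(nodes, predicates)`.
#' @export
extract_demonstration_paths <- function(g, treat_pairs, drug_targets, pub_map,
                                        max_hops = 3L, per_pair_cap = 50L) {
  treat_pairs <- as.data.table(treat_pairs)
  drug_targets <- as.data.table(drug_targets)
  adj <- .kg_adj(g)
  mean_ngd <- function(nodes) {
    v <- numeric(length(nodes) - 1L)
    for (i in seq_along(v)) {
      a <- nodes[i]; b <- nodes[i + 1L]
      v[i] <- if (is.null(pub_map$pubs[[a]]) || is.null(pub_map$pubs[[b]]) ||
                  length(pub_map$pubs[[a]]) == 0L ||
                  length(pub_map$pubs[[b]]) == 0L) Inf
              else if (cooccurrence(pub_map, a, b) == 0L) Inf
              else ngd(pub_map, a, b)
    }
    mean(v)
  }
  out <- list()
  for (i in seq_len(nrow(treat_pairs))) {
    d <- treat_pairs$drug[i]; z <- treat_pairs$disease[i]
    tgts <- sort(drug_targets[drug == d, target])
    cand <- list()
    for (t in tgts) {
      first <- adj[[d]]
      if (is.null(first)) next
      first <- first[object == t]
      if (!nrow(first)) next              # target not wired to this drug
      tails <- .dfs_paths(adj, t, z, max_hops - 1L)
      for (fp in seq_len(nrow(first)))
        for (tl in tails)
          cand[[length(cand) + 1L]] <- list(
            nodes = c(d, tl$nodes),
            predicates = c(first$predicate[fp], tl$predicates))
    }
    if (!length(cand)) next
    key <- vapply(cand, function(p)
      paste(c(p$nodes, p$predicates), collapse = "\r"), "")
    cand <- cand[!duplicated(key)]
    if (length(cand) > per_pair_cap) {
      sc <- vapply(cand, function(p) mean_ngd(p$nodes), 0)
      tie <- vapply(cand, function(p) paste(p$nodes, collapse = "\r"), "")
      cand <- cand[order(sc, tie)][seq_len(per_pair_cap)]
    }
    out <- c(out, cand)
  }
  key <- vapply(out, function(p)
    paste(c(p$nodes, p$predicates), collapse = "\r"), "")
  out[!duplicated(key)]
}

#' Meta-paths (category sequences) of a path set, with multiplicities
#'
#' @param paths list of paths (`list(nodes, predicates)`).
#' @param g a `knowledge_graph` providing node categories.
#' @return data.table with list column `categories`, string key `metapath`
#'   and `count`.
#' @export
demo_metapaths <- function(paths, g) {
  if (!length(paths))
    return(data.table(metapath = character(), categories = list(),
                      count = integer()))
  cat_of <- kg_categories(g)
  cats <- lapply(paths, function(p) unname(cat_of[p$nodes]))
  key <- vapply(cats, paste, "", collapse = "->")
  dt <- data.table(metapath = key)[, .(count = .N), by = metapath]
  dt[, categories := lapply(metapath, function(k) strsplit(k, "->", fixed = TRUE)[[1]])]
  setcolorder(dt, c("metapath", "categories", "count"))
  dt[]
}

#' Validate that every path is walkable edge-by-edge in a graph
#' @param paths list of paths.
#' @param g a `knowledge_graph`.
#' @return logical vector, one per path.
#' @export
paths_walkable <- function(paths, g) {
  ek <- paste(g$edges$subject, g$edges$predicate, g$edges$object, sep = "\r")
  vapply(paths, function(p) {
    k <- length(p$predicates)
    all(paste(p$nodes[seq_len(k)], p$predicates,
              p$nodes[seq_len(k) + 1L], sep = "\r") %in% ek)
  }, TRUE)
}

#' Read / write paths as JSON-lines
#'
#' One object per line: `{"nodes": [...], "predicates": [...]}`.
#' @param path file path.
#' @return list of paths.
#' @export
read_paths_jsonl <- function(path) {
  lapply(readLines(path), function(l) {
    o <- jsonlite::fromJSON(l)
    list(nodes = as.character(o$nodes),
         predicates = as.character(o$predicates))
  })
}

#' @rdname read_paths_jsonl
#' @param paths list of paths.
#' @export
write_paths_jsonl <- function(paths, path) {
  writeLines(vapply(paths, function(p)
    jsonlite::toJSON(list(nodes = p$nodes, predicates = p$predicates)), ""),
    path)
}
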