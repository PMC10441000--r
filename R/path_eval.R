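#' Enumerate candidate drug-to-disease paths
#'
#' All directed simple paths (no repeated nodes) from `drug` to `disease`
#' with exactly `max_hops` edges by default, in deterministic depth-first
#' order; parallel predicates yield distinct paths.
#'
#' @param g a `knowledge_graph`.
#' @param drug,disease node ids.
#' @param max_hops path length in edges (default 3).
#' @param exact require exactly `max_hops` edges (default TRUE; FALSE
#'   allows shorter paths too).
#' @return list of paths (`list(nodes, predicates)`); possibly empty.
#' @export
enumerate_paths <- function(g, drug, disease, max_hops = 3L, exact = TRUE) {
  stopifnot(drug %in% g$nodes$id, disease %in% g$nodes$id)
  .dfs_paths(.kg_adj(g), drug, disease, max_hops, exact = exact)
}

#' Score a path with the trained policy
#'
#' \deqn{\mathrm{score} = \sum_{i=1}^{k} \delta^{i-1}
#'   \log(P_i \times N_i)}
#' where \eqn{P_i} is the policy probability of the path's i-th action
#' given the reconstructed state and \eqn{N_i} the size of the (pruned)
#' action space at hop i, self-loop included.  An action unavailable to
#' the policy (pruned or absent) has \eqn{P_i = 0} and yields `-Inf`.
#'
#' @param model a `moa_model`.
#' @param path a path (`list(nodes, predicates)`).
#' @param delta decay coefficient (default 0.9).
#' @return numeric scalar, possibly `-Inf`.
#' @export
score_path <- function(model, path, delta = 0.9) {
  env <- model$env
  st <- env_initial_state(env, path$nodes[1L])
  score <- 0
  for (i in seq_along(path$predicates)) {
    A <- action_space(env, st)
    p <- actor_policy(model, st, A)
    pi_ <- env$pidx[[path$predicates[i]]]
    ni <- env$nidx[[path$nodes[i + 1L]]]
    ai <- if (is.null(pi_) || is.null(ni)) NA_integer_
          else which(A[, "pred"] == pi_ & A[, "nxt"] == ni)[1L]
    if (is.na(ai) || p[ai] == 0) return(-Inf)
    score <- score + delta^(i - 1) * log(p[ai] * nrow(A))
    st <- env_step(env, st, A[ai, ])
  }
  score
}

#' Rank scored paths of one drug-disease pair
#'
#' Descending score with deterministic tie-break by lexicographic node
#' sequence; ranks are the positions in that order.
#'
#' @param paths list of paths.
#' @param scores numeric vector of the same length.
#' @return data.table with `path_i`, `score`, `rank`, `n_candidates`.
#' @export
rank_paths <- function(paths, scores) {
  stopifnot(length(paths) >= 1L, length(paths) == length(scores))
  key <- vapply(paths, function(p) paste(p$nodes, collapse = "\r"), "")
  ord <- order(-scores, key)
  rank <- integer(length(scores)); rank[ord] <- seq_along(ord)
  data.table(path_i = seq_along(paths), score = scores, rank = rank,
             n_candidates = length(paths))
}

#' Match a predicted path against a curated mechanism path
#'
#' TRUE iff every node of the predicted path appears anywhere in the
#' curated node sequence (order-insensitive containment); this is the
#' matching rule used to call a 3-hop graph path "correct" against a
#' curated mechanism-of-action database entry.
#'
#' @param path a path (`list(nodes, predicates)`).
#' @param curated character vector of curated node ids.
#' @return logical scalar.
#' @export
match_curated <- function(path, curated) all(path$nodes %in% curated)

#' Ranking metrics: MPR, MRR and Hit@K
#'
#' MRR is the mean reciprocal rank; Hit@K the proportion of ranks at most
#' K; MPR the mean percentile rank with the convention
#' `PR = 100 (n - r + 1) / n` (best rank = 100).
#'
#' @param ranks integer vector of ranks (>= 1).
#' @param n_candidates integer vector (same length) of candidate-set
#'   sizes; each rank must not exceed it.
#' @param K_list integers for Hit@K.
#' @return list with `mpr`, `mrr`, `hit_at_k` (named numeric).
#' @export
ranking_metrics <- function(ranks, n_candidates, K_list = c(1, 3, 5, 10)) {
  if (!length(ranks)) stop("empty rank list")
  stopifnot(length(ranks) == length(n_candidates),
            all(ranks >= 1), all(ranks <= n_candidates))
  hits <- vapply(K_list, function(K) mean(ranks <= K), 0)
  names(hits) <- paste0("hit@", K_list)
  list(mpr = mean(100 * (n_candidates - ranks + 1) / n_candidates),
       mrr = mean(1 / ranks),
       hit_at_k = hits)
}

#' Classification metrics: accuracy and macro F1
#'
#' Macro F1 is the unweighted mean of per-class F1 scores.  With
#' `exclude_unknown`, pairs whose true label is `unknown` are dropped and
#' the mean runs over the remaining classes only.  A class with zero true
#' and zero predicted members contributes F1 = 0 with a warning.
#'
#' @param truth,pred character vectors of true / predicted labels.
#' @param exclude_unknown drop unknown-truth pairs (default FALSE).
#' @param classes class set to average over (default: classes present in
#'   `truth` or `pred`, after any exclusion).
#' @return list with `acc` and `macro_f1`.
#' @export
classification_metrics <- function(truth, pred, exclude_unknown = FALSE,
                                   classes = NULL) {
  stopifnot(length(truth) == length(pred))
  if (exclude_unknown) {
    keep <- truth != "unknown"
    truth <- truth[keep]; pred <- pred[keep]
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, pred)))
    if (exclude_unknown) classes <- setdiff(classes, "unknown")
  }
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0L) {
      warning("class '", cl, "' has no true or predicted members; F1 = 0")
      return(0)
    }
    if (tp == 0L) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  list(acc = mean(truth == pred), macro_f1 = mean(f1))
}

#' Evaluate mechanism-path retrieval for labeled pairs
#'
#' For each treat pair: enumerates all exact-`max_hops` candidate paths,
#' scores them with the policy, ranks them, and records the best (smallest)
#' rank over the pair's reference paths (matched with [match_curated()]
#' when `curated` gives node sets, or exact node-sequence matching when
#' `reference_paths` are supplied).  Pairs with no enumerable candidate or
#' no matched path are skipped.
#'
#' @param model a trained `moa_model`.
#' @param g the `knowledge_graph` used for enumeration.
#' @param pairs data.frame of treat pairs.
#' @param reference_paths list of reference paths (`list(nodes,
#'   predicates)`), matched by node sequence.
#' @param max_hops enumeration length (default `model$cfg$max_hops`).
#' @param delta path-score decay.
#' @return data.table with `drug`, `disease`, `rank`, `n_candidates`.
#' @export
evaluate_moa_paths <- function(model, g, pairs, reference_paths,
                               max_hops = model$cfg$max_hops, delta = 0.9) {
  pairs <- as.data.table(pairs)
  ref_by_pair <- split(reference_paths,
                       vapply(reference_paths, function(p)
                         paste(p$nodes[1L], p$nodes[length(p$nodes)],
                               sep = "\r"), ""))
  adj <- .kg_adj(g)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$drug[i]; z <- pairs$disease[i]
    refs <- ref_by_pair[[paste(d, z, sep = "\r")]]
    if (is.null(refs)) next
    cand <- .dfs_paths(adj, d, z, max_hops, exact = TRUE)
    if (!length(cand)) next
    ref_keys <- vapply(refs, function(p) paste(p$nodes, collapse = "\r"), "")
    cand_keys <- vapply(cand, function(p) paste(p$nodes, collapse = "\r"), "")
    matched <- which(cand_keys %in% ref_keys)
    if (!length(matched)) next
    sc <- vapply(cand, function(p) score_path(model, p, delta), 0)
    rk <- rank_paths(cand, sc)
    out[[i]] <- data.table(drug = d, disease = z,
                           rank = min(rk$rank[matched]),
                           n_candidates = length(cand))
  }
  rbindlist(out[!vapply(out, is.null, TRUE)])
}
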