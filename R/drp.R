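#' Pair features from node embeddings
#'
#' Concatenates the drug embedding followed by the disease embedding
#' (order fixed: drug first), giving a `2 * dim` feature vector per pair.
#'
#' @param emb embedding matrix with rownames = node ids.
#' @param pairs data.frame with `drug`, `disease`.
#' @return numeric matrix, one row per pair, `2 * ncol(emb)` columns.
#' @export
pair_features <- function(emb, pairs) {
  pairs <- as.data.table(pairs)
  miss <- setdiff(unique(c(pairs$drug, pairs$disease)), rownames(emb))
  if (length(miss))
    stop("missing embedding for node(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  cbind(emb[pairs$drug, , drop = FALSE], emb[pairs$disease, , drop = FALSE])
}

#' Fit the drug-repurposing pair classifier
#'
#' A random forest (bootstrap-bagged CART trees, Gini splits, per-node
#' feature subsampling) over pair features, classifying each drug-disease
#' pair as `not_treat`, `treat` or `unknown`.  A two-class ablation
#' (`classes = c("not_treat", "treat")`) is supported.
#'
#' @param features numeric matrix of pair features.
#' @param labels character vector of class labels, one per row.
#' @param classes class vocabulary in fixed order; every class must be
#'   present in `labels`.
#' @param ntree number of trees (default 1000).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param max_depth,min_node tree growth limits.
#' @param seed integer seed; fits are deterministic.
#' @return object of class `drp_model`.
#' @export
fit_drp <- function(features, labels,
                    classes = c("not_treat", "treat", "unknown"),
                    ntree = 1000L, mtry = NULL, max_depth = 25L,
                    min_node = 1L, seed = 1L) {
  stopifnot(nrow(features) == length(labels))
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls))
    stop("class(es) absent from training labels: ",
         paste(missing_cls, collapse = ", "))
  if (!all(labels %in% classes))
    stop("labels outside the class vocabulary")
  if (length(classes) < 2L) stop("need at least two classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  y <- match(labels, classes) - 1L
  forest <- cpp_grow_forest(features, y, length(classes), as.integer(ntree),
                            as.integer(mtry), as.integer(max_depth),
                            as.integer(min_node), as.integer(seed))
  m <- structure(list(forest = forest, classes = classes,
                      dim = ncol(features), seed = as.integer(seed)),
                 class = "drp_model")
  pr <- predict_drp(m, features)
  message(sprintf("drp: %d trees, training accuracy %.3f", ntree,
                  mean(pr$class == labels)))
  m
}

#' Predict class probabilities for drug-disease pairs
#'
#' @param m a `drp_model`.
#' @param features numeric matrix with `m$dim` columns.
#' @return list with `prob` (rows sum to 1, columns in `m$classes` order),
#'   `class` (argmax label) and `p_treat` (treat-class probability, 0 in
#'   a model fitted without a treat class).
#' @export
predict_drp <- function(m, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != m$dim)
    stop("feature dimension ", ncol(features), " != model dimension ", m$dim)
  prob <- cpp_predict_forest(m$forest, features, length(m$classes))
  colnames(prob) <- m$classes
  treat_p <- if ("treat" %in% m$classes) prob[, "treat"] else numeric(nrow(prob))
  list(prob = prob, class = m$classes[max.col(prob, ties.method = "first")],
       p_treat = treat_p)
}

#' Replacement protocol for ranking evaluation
#'
#' Controls how non-true-positive candidates are generated for each
#' true-positive pair: `drug` replaces the drug with every other drug id,
#' `disease` symmetric, `combined` is their union, and `random_subset`
#' draws `repeats` independent candidate sets of `subset_size` pairs
#' (`per_side` drug-replaced + `per_side` disease-replaced).
#'
#' @param mode one of `drug`, `disease`, `combined`, `random_subset`.
#' @param subset_size,per_side,repeats random-subset parameters; must
#'   satisfy `2 * per_side == subset_size`.
#' @param seed integer seed.
#' @return object of class `replacement_protocol`.
#' @export
replacement_protocol <- function(mode = c("random_subset", "drug", "disease",
                                          "combined"),
                                 subset_size = 1000L, per_side = 500L,
                                 repeats = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "random_subset" && 2L * per_side != subset_size)
    stop("random_subset requires 2 * per_side == subset_size")
  structure(list(mode = mode, subset_size = as.integer(subset_size),
                 per_side = as.integer(per_side),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "replacement_protocol")
}

#' Generate replacement candidates for one true-positive pair
#'
#' All modes exclude every known true-positive pair and the query pair
#' itself.
#'
#' @param pair list or one-row data.frame with `drug`, `disease`.
#' @param protocol a [replacement_protocol()].
#' @param known_positives data.frame of all known treat pairs.
#' @param drug_ids,disease_ids candidate pools.
#' @return list of data.tables (`drug`, `disease`), one per repeat (a
#'   single element for the deterministic modes).
#' @export
generate_replacement_candidates <- function(pair, protocol, known_positives,
                                            drug_ids, disease_ids) {
  d <- pair$drug[1]; z <- pair$disease[1]
  pos_keys <- paste(known_positives$drug, known_positives$disease, sep = "\r")
  drug_pool <- {
    cand <- data.table(drug = setdiff(drug_ids, d), disease = z)
    cand[!paste(drug, disease, sep = "\r") %in% pos_keys]
  }
  disease_pool <- {
    cand <- data.table(drug = d, disease = setdiff(disease_ids, z))
    cand[!paste(drug, disease, sep = "\r") %in% pos_keys]
  }
  switch(protocol$mode,
    drug = list(drug_pool),
    disease = list(disease_pool),
    combined = list(rbind(drug_pool, disease_pool)),
    random_subset = {
      if (nrow(drug_pool) < protocol$per_side ||
          nrow(disease_pool) < protocol$per_side)
        stop("candidate pools smaller than per_side = ", protocol$per_side)
      lapply(seq_len(protocol$repeats), function(r) {
        set.seed(protocol$seed + 7919L * r +
                 .fnv1a(paste(d, z), protocol$seed) %% 100000L)
        rbind(drug_pool[sample.int(nrow(drug_pool), protocol$per_side)],
              disease_pool[sample.int(nrow(disease_pool), protocol$per_side)])
      })
    })
}

#' Rank true positives among replacement candidates
#'
#' Each positive is ranked among itself plus its candidates by descending
#' treat probability, with competition ranking (rank = 1 + number of
#' candidates with strictly greater score, so score ties do not hurt the
#' positive's competition rank).
#'
#' @param m a fitted `drp_model`.
#' @param positives data.frame of true-positive pairs to rank.
#' @param protocol a [replacement_protocol()].
#' @param emb embedding matrix.
#' @param known_positives all known treat pairs (used for exclusion).
#' @param drug_ids,disease_ids candidate pools.
#' @return data.table with `drug`, `disease`, `rep`, `rank`,
#'   `n_candidates` (candidate-set size + 1 for the positive itself).
#' @export
rank_true_positives <- function(m, positives, protocol, emb, known_positives,
                                drug_ids, disease_ids) {
  positives <- as.data.table(positives)
  out <- vector("list", nrow(positives))
  for (i in seq_len(nrow(positives))) {
    pair <- positives[i]
    sets <- generate_replacement_candidates(pair, protocol, known_positives,
                                            drug_ids, disease_ids)
    rows <- lapply(seq_along(sets), function(r) {
      cand <- sets[[r]]
      p_query <- predict_drp(m, pair_features(emb, pair))$p_treat
      p_cand <- predict_drp(m, pair_features(emb, cand))$p_treat
      data.table(drug = pair$drug, disease = pair$disease, rep = r,
                 rank = 1L + sum(p_cand > p_query),
                 n_candidates = nrow(cand) + 1L)
    })
    out[[i]] <- rbindlist(rows)
  }
  rbindlist(out)
}

#' Save / load a fitted DRP model
#'
#' The model is written as an opaque binary blob plus a JSON metadata
#' sidecar (class order, feature dimension, seed).
#' @param m a `drp_model`.
#' @param dir output directory.
#' @export
save_drp <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(m, file.path(dir, "drp_model.rds"))
  writeLines(jsonlite::toJSON(list(classes = m$classes, dim = m$dim,
                                   seed = m$seed), auto_unbox = TRUE),
             file.path(dir, "drp_model.json"))
  invisible(dir)
}

#' @rdname save_drp
#' @export
load_drp <- function(dir) readRDS(file.path(dir, "drp_model.rds"))
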