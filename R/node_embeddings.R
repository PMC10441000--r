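# FNV-1a string hash, seed-mixed; returns non-negative double < 2^31
.fnv1a <- function(s, seed = 0L) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  bitwXor(as.integer(h), as.integer(seed %% 2^31)) %% 2^31
}

#' Seeded feature-hashing text encoder
#'
#' Deterministic drop-in stand-in for a biomedical language model: each
#' whitespace/punctuation token of the input string is hashed into one of
#' `dim` buckets with a hashed sign, and the resulting sparse counts are
#' L2-normalized.  Identical strings always map to identical vectors.
#'
#' @param dim output dimension.
#' @param seed hash seed.
#' @return function mapping a character vector to a
#'   `length(x)` x `dim` numeric matrix.
#' @export
hash_encoder <- function(dim = 256L, seed = 1L) {
  force(dim); force(seed)
  function(x) {
    out <- matrix(0, nrow = length(x), ncol = dim)
    for (i in seq_along(x)) {
      toks <- strsplit(tolower(x[i]), "[^a-z0-9]+")[[1]]
      toks <- toks[nzchar(toks)]
      for (tk in toks) {
        h <- .fnv1a(tk, seed)
        j <- h %% dim + 1L
        sgn <- if (.fnv1a(tk, seed + 1L) %% 2L == 0L) 1 else -1
        out[i, j] <- out[i, j] + sgn
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

#' Attribute embeddings for every node
#'
#' Encodes the string `"<name> <category>"` of each node with the supplied
#' text encoder (default: seeded hashing encoder; a transformer encoder can
#' be dropped in via the same contract).
#'
#' @param g a `knowledge_graph`.
#' @param encoder function: character vector -> numeric matrix with one row
#'   per input and a fixed number of columns.
#' @return numeric matrix, rownames = node ids.
#' @export
attribute_embeddings <- function(g, encoder = hash_encoder()) {
  txt <- paste(g$nodes$name, g$nodes$category)
  m <- encoder(txt)
  if (!is.matrix(m) || nrow(m) != nrow(g$nodes))
    stop("encoder must return one row per input string")
  if (any(!is.finite(m))) stop("encoder produced non-finite values")
  rownames(m) <- g$nodes$id
  m
}

#' PCA compression of an embedding table
#'
#' Projects onto the top `target_dim` principal components fitted on all
#' node vectors; tables already at or below `target_dim` pass through
#' unchanged.  The effective dimension is capped at `n - 1` components.
#'
#' @param tab numeric matrix with rownames.
#' @param target_dim target dimensionality (default 100).
#' @return numeric matrix with at most `target_dim` columns.
#' @export
reduce_pca <- function(tab, target_dim = 100L) {
  if (nrow(tab) < 2L) stop("need at least 2 rows for PCA")
  if (ncol(tab) <= target_dim) return(tab)
  k <- min(target_dim, nrow(tab) - 1L, ncol(tab))
  p <- stats::prcomp(tab, center = TRUE, scale. = FALSE, rank. = k)
  out <- p$x
  rownames(out) <- rownames(tab)
  out
}

#' Configuration for graph-embedding training
#'
#' @param walk_length steps per random walk.
#' @param walks_per_node walks started from every node.
#' @param window skip-gram co-occurrence window.
#' @param num_negatives negatives `k` per positive pair.
#' @param layers neighborhood mean-aggregation layers used to build the
#'   attribute-based initialization (1 or 2).
#' @param hidden_dim embedding dimension.
#' @param epochs passes of stochastic gradient descent over the corpus.
#' @param learning_rate initial SGD learning rate (decays linearly).
#' @param max_pairs_per_epoch cap on unique corpus pairs kept for training
#'   (very large corpora are subsampled in proportion to pair multiplicity).
#' @param subsample frequent-node subsampling threshold `t`: corpus
#'   occurrences of a node with corpus frequency `f` are kept with
#'   probability `sqrt(t / f)` (capped at 1), protecting specific
#'   neighborhood structure from promiscuous hub nodes.  The default
#'   (`NULL`) adapts to the graph as 5x the median node frequency, so only
#'   genuinely hub-like nodes are damped.
#' @param seed integer RNG seed.
#' @return object of class `graph_embed_config`.
#' @export
graph_embed_config <- function(walk_length = 8L, walks_per_node = 10L,
                               window = 5L, num_negatives = 20L, layers = 1L,
                               hidden_dim = 64L, epochs = 30L,
                               learning_rate = 0.05,
                               max_pairs_per_epoch = 500000L,
                               subsample = NULL, seed = 1L) {
  stopifnot(walk_length > 0, walks_per_node > 0, window > 0,
            num_negatives > 0, layers %in% 1:2, hidden_dim > 0, epochs > 0,
            is.null(subsample) || subsample > 0)
  structure(as.list(environment()), class = "graph_embed_config")
}

#' Random-walk co-occurrence corpus
#'
#' Uniform random walks over directed edges (parallel edges weight their
#' multiplicity), `walks_per_node` from every node, terminating early at
#' dead ends.  Emits all ordered (center, context) pairs within the window;
#' same-node pairs are discarded, so isolated nodes contribute nothing.
#'
#' @param g a `knowledge_graph`.
#' @param cfg a [graph_embed_config()].
#' @return data.table with character columns `center`, `context`.
#' @export
walk_corpus <- function(g, cfg) {
  set.seed(cfg$seed)
  ids <- g$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  adj <- split(idx[g$edges$object], g$edges$subject)
  nw <- length(ids) * cfg$walks_per_node
  walks <- matrix(NA_integer_, nrow = nw, ncol = cfg$walk_length + 1L)
  walks[, 1L] <- rep(seq_along(ids), each = cfg$walks_per_node)
  cur <- walks[, 1L]
  for (s in seq_len(cfg$walk_length)) {
    nxt <- rep(NA_integer_, nw)
    alive <- which(!is.na(cur))
    # vectorized step: sample neighbors for all walks at a node at once
    for (grp in split(alive, cur[alive])) {
      nb <- adj[[ids[cur[grp[1L]]]]]
      if (!is.null(nb) && length(nb))
        nxt[grp] <- nb[sample.int(length(nb), length(grp), replace = TRUE)]
    }
    walks[, s + 1L] <- nxt
    cur <- nxt
  }
  pairs <- vector("list", cfg$window * cfg$walk_length * 2L)
  k <- 0L
  for (d in seq_len(cfg$window)) {
    for (i in seq_len(cfg$walk_length + 1L - d)) {
      a <- walks[, i]; b <- walks[, i + d]
      ok <- !is.na(a) & !is.na(b) & a != b
      if (any(ok)) {
        k <- k + 1L; pairs[[k]] <- data.table(ci = a[ok], xi = b[ok])
        k <- k + 1L; pairs[[k]] <- data.table(ci = b[ok], xi = a[ok])
      }
    }
  }
  out <- rbindlist(pairs[seq_len(k)])
  data.table(center = ids[out$ci], context = ids[out$xi])
}

# forward pass of the linear mean-aggregation encoder
.embed_forward <- function(X, A, W) {
  H <- X
  caches <- vector("list", length(W))
  for (l in seq_along(W)) {
    C <- cbind(H, as.matrix(A %*% H))
    caches[[l]] <- C
    H <- C %*% W[[l]]
  }
  list(Z = H, caches = caches)
}

#' Train neighborhood-aware graph embeddings
#'
#' Minimizes the random-walk skip-gram objective with negative sampling:
#' for a corpus pair (u, v),
#' \deqn{L = -\log\sigma(z_u^\top z_v) - k\, E_{v_n \sim P_n}
#'   \log\sigma(-z_u^\top z_{v_n})}
#' with `k` negatives drawn from the degree^0.75 unigram distribution.
#' Embeddings are produced by a mean-aggregation encoder over the directed
#' neighborhood, initialized from the attribute features, so the final
#' vectors reflect both topology and attributes.
#'
#' @param g a `knowledge_graph`.
#' @param attr attribute-embedding matrix covering all nodes (rownames
#'   = node ids).
#' @param cfg a [graph_embed_config()].
#' @return embedding matrix (rownames = node ids, `cfg$hidden_dim` columns)
#'   with attributes `loss_history` (mean corpus loss per epoch, index 1 =
#'   before training) and `config`.
#' @export
train_graph_embeddings <- function(g, attr, cfg) {
  ids <- g$nodes$id
  if (!all(ids %in% rownames(attr)))
    stop("attribute embeddings must cover every node")
  X <- attr[ids, , drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- length(ids)
  corpus <- walk_corpus(g, cfg)   # seeds RNG with cfg$seed
  cc <- data.table(ci = match(corpus$center, ids),
                   xi = match(corpus$context, ids))
  # word2vec-style subsampling of occurrences involving frequent nodes
  nfreq <- tabulate(c(cc$ci, cc$xi), n) / (2 * nrow(cc))
  tsub <- if (is.null(cfg$subsample))
    5 * stats::median(nfreq[nfreq > 0]) else cfg$subsample
  keepp <- pmin(1, sqrt(tsub / pmax(nfreq, 1e-12)))
  cc <- cc[stats::runif(nrow(cc)) < keepp[ci] * keepp[xi]]
  agg <- cc[, .N, by = .(ci, xi)]
  if (nrow(agg) > cfg$max_pairs_per_epoch) {
    keep <- sample.int(nrow(agg), cfg$max_pairs_per_epoch, prob = agg$N)
    agg <- agg[sort(keep)]
  }

  # initialization: linear projection of the node's own attribute vector
  # concatenated with its out-neighborhood mean (one or two aggregation
  # rounds), rescaled to a small-entry start for the product-form gradient
  ei <- match(g$edges$subject, ids); ej <- match(g$edges$object, ids)
  A <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  A <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% A
  set.seed(cfg$seed + 1L)
  H <- X
  for (l in seq_len(cfg$layers)) {
    C <- cbind(H, as.matrix(A %*% H))
    W <- matrix(stats::rnorm(ncol(C) * cfg$hidden_dim,
                             sd = sqrt(1 / ncol(C))), ncol(C), cfg$hidden_dim)
    H <- C %*% W
  }
  Z <- H / max(stats::sd(H), 1e-12) * 0.1

  deg <- tabulate(ei, n) + tabulate(ej, n)
  pneg <- (deg + 1)^0.75; pneg <- pneg / sum(pneg)
  neg_table <- sample.int(n, 200000L, replace = TRUE, prob = pneg)

  k <- cfg$num_negatives
  init_loss <- local({  # comparable pre-training loss on the same corpus
    wv <- log1p(as.numeric(agg$N))
    tot <- 0
    for (chunk in split(seq_len(nrow(agg)),
                        ceiling(seq_len(nrow(agg)) / 50000))) {
      s <- rowSums(Z[agg$ci[chunk], , drop = FALSE] *
                   Z[agg$xi[chunk], , drop = FALSE])
      vn <- neg_table[sample.int(length(neg_table), length(chunk) * k,
                                 replace = TRUE)]
      sn <- rowSums(Z[rep(agg$ci[chunk], each = k), , drop = FALSE] *
                    Z[vn, , drop = FALSE])
      tot <- tot + sum(wv[chunk] * log1p(exp(-s))) +
        sum(rep(wv[chunk], each = k) * log1p(exp(sn)))
    }
    tot / sum(wv)
  })
  # multiplicity weights are damped (log-saturating) so very frequent
  # pairs cannot destabilize the sequential updates
  wts <- log1p(as.numeric(agg$N))
  Zt <- t(Z)
  ep_loss <- cpp_sgns(Zt, agg$ci, agg$xi, wts, neg_table,
                      as.integer(k), cfg$learning_rate,
                      as.integer(cfg$epochs), as.integer(cfg$seed + 2L))
  Z <- t(Zt)
  if (!all(is.finite(ep_loss)) || !all(is.finite(Z)))
    stop("embedding training diverged (non-finite values); lower the ",
         "learning rate")
  rownames(Z) <- ids
  attr(Z, "loss_history") <- c(init_loss, ep_loss)
  attr(Z, "config") <- cfg
  message(sprintf("embeddings: %d nodes, %d corpus pairs, loss %.3f -> %.3f",
                  n, nrow(agg), init_loss, ep_loss[length(ep_loss)]))
  Z
}

#' Read / write an embedding table as TSV
#'
#' Format: first column `id`, remaining columns `d1..dk`.
#' @param path TSV path.
#' @return numeric matrix with rownames.
#' @export
read_embeddings <- function(path) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname read_embeddings
#' @param emb numeric matrix with rownames.
#' @export
write_embeddings <- function(emb, path) {
  dt <- data.table(id = rownames(emb))
  cbind(dt, as.data.table(emb)) |>
    fwrite(path, sep = "\t")
  invisible(path)
}
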