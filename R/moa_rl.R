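#' Configuration for the mechanism-of-action RL module
#'
#' @param alpha_p,alpha_m mixing weights of the path- and meta-path
#'   discriminator rewards; `alpha_p + alpha_m <= 1`.  Setting both to 0
#'   reduces training to plain actor-critic with terminal-only shaping.
#' @param gamma decay coefficient of the terminal-reward term.
#' @param entropy_weight entropy-regularization weight of the actor loss.
#' @param max_hops episode length `T`; every episode runs exactly `T` steps,
#'   with the self-loop action providing effective early termination.
#' @param history number of past (node, predicate) tuples `K` kept in the
#'   state, padded with a reserved dummy node/predicate.
#' @param warmup epochs `z` during which only the discriminators train
#'   (actor and critic frozen).
#' @param neighbor_cap PageRank-pruned action-space cap: nodes with more
#'   out-neighbors keep only the highest-PageRank ones.
#' @param hidden_dim hidden width of all four subnetworks.
#' @param action_emb_dim node/predicate embedding dimension `d` (action
#'   embedding is `2 d`); also the category-embedding dimension of the
#'   meta-path discriminator.
#' @param epochs adversarial training epochs (after behavior cloning).
#' @param episodes_per_epoch rollouts per epoch (`NULL` = one per training
#'   drug).
#' @param learning_rate,disc_lr Adam learning rates for actor/critic and
#'   discriminators.
#' @param bc_epochs,bc_lr behavior-cloning epochs and learning rate.
#' @param seed integer seed; training is deterministic given it.
#' @return object of class `moa_config`.
#' @export
moa_config <- function(alpha_p = 0.1, alpha_m = 0.1, gamma = 0.99,
                       entropy_weight = 0.01, max_hops = 3L, history = 2L,
                       warmup = 5L, neighbor_cap = 3000L, hidden_dim = 64L,
                       action_emb_dim = 16L, epochs = 30L,
                       episodes_per_epoch = NULL, learning_rate = 1e-3,
                       disc_lr = 1e-3, bc_epochs = 100L, bc_lr = 5e-3,
                       seed = 1L) {
  stopifnot(alpha_p >= 0, alpha_m >= 0, alpha_p + alpha_m <= 1,
            gamma > 0, gamma <= 1, entropy_weight >= 0, max_hops >= 1,
            history >= 1, warmup >= 0, neighbor_cap >= 1)
  structure(as.list(environment()), class = "moa_config")
}

.DUMMY <- "__DUMMY__"
.SELF  <- "__SELF_LOOP__"
.BN_EPS <- 1e-5
.CLIP_EPS <- 1e-7

#' Build the knowledge-graph MDP environment
#'
#' Precomputes node/predicate indexing (index 1 reserved for the dummy
#' node/predicate), per-node PageRank-pruned action tables, node attribute
#' embeddings used for state encoding, and one-hot predicate encoding.
#'
#' @param g a `knowledge_graph`.
#' @param attr attribute-embedding matrix covering all nodes.
#' @param cfg a [moa_config()].
#' @return an environment object of class `moa_env`.
#' @export
moa_env <- function(g, attr, cfg) {
  ids <- g$nodes$id
  stopifnot(all(ids %in% rownames(attr)))
  node_ids <- c(.DUMMY, ids)
  preds <- c(.DUMMY, .SELF, sort(unique(g$edges$predicate)))
  nidx <- stats::setNames(seq_along(node_ids), node_ids)
  pidx <- stats::setNames(seq_along(preds), preds)
  X <- rbind(0, attr[ids, , drop = FALSE])   # dummy row = zeros
  rownames(X) <- node_ids

  pr <- kg_pagerank(g)
  e <- data.table(s = g$edges$subject, p = pidx[g$edges$predicate],
                  o = nidx[g$edges$object], opr = pr[g$edges$object],
                  oid = g$edges$object)
  setorder(e, s, p, oid)
  actions <- lapply(split(e, e$s), function(dt) {
    if (nrow(dt) > cfg$neighbor_cap) {
      # keep the neighbor_cap highest-PageRank neighbors, ties by node id
      keep_nodes <- unique(dt[order(-opr, oid), oid])
      keep_nodes <- keep_nodes[seq_len(min(length(keep_nodes), cfg$neighbor_cap))]
      dt <- dt[oid %in% keep_nodes]
    }
    cbind(pred = dt$p, nxt = dt$o)
  })
  cats <- c(.DUMMY, sort(unique(g$nodes$category)))
  cidx <- stats::setNames(seq_along(cats), cats)
  node_cat <- c(1L, unname(cidx[g$nodes$category]))
  ns <- kg_node_sets(g)
  structure(list(node_ids = node_ids, nidx = nidx, preds = preds,
                 pidx = pidx, X = X, actions = actions, pagerank = pr,
                 cats = cats, node_cat = node_cat,
                 disease_idx = unname(nidx[ns$diseases]),
                 drug_idx = unname(nidx[ns$drugs]),
                 cfg = cfg,
                 state_dim = (2L + cfg$history) * ncol(X) +
                   cfg$history * length(preds)),
            class = "moa_env")
}

#' Initial state for a starting drug
#' @param env a `moa_env`.
#' @param drug drug node id.
#' @return state object (list with `drug`, `current`, `hist_nodes`,
#'   `hist_preds`, `t`).
#' @export
env_initial_state <- function(env, drug) {
  di <- env$nidx[[drug]]
  if (is.null(di)) stop("unknown node: ", drug)
  list(drug = di, current = di,
       hist_nodes = rep(1L, env$cfg$history),
       hist_preds = rep(1L, env$cfg$history), t = 0L)
}

#' Action space at a state
#'
#' The self-loop action always comes first; out-neighbor actions follow in
#' deterministic (predicate, node-id) order, PageRank-pruned to the
#' configured cap.
#'
#' @param env a `moa_env`.
#' @param state a state.
#' @return integer matrix with columns `pred`, `nxt` (predicate and node
#'   indices), self-loop in row 1.
#' @export
action_space <- function(env, state) {
  out <- env$actions[[env$node_ids[state$current]]]
  selfrow <- cbind(pred = env$pidx[[.SELF]], nxt = state$current)
  if (is.null(out)) selfrow else rbind(selfrow, out)
}

#' Take an action in the environment
#'
#' @param env a `moa_env`.
#' @param state current state with `state$t < max_hops`.
#' @param action integer vector/1-row matrix with `pred`, `nxt`, which must
#'   be a row of [action_space()].
#' @return the next state: `current` moved, history shifted by one tuple,
#'   `t` incremented.
#' @export
env_step <- function(env, state, action) {
  if (state$t >= env$cfg$max_hops) stop("episode is over (t = ", state$t, ")")
  action <- as.integer(action)
  A <- action_space(env, state)
  if (!any(A[, "pred"] == action[1] & A[, "nxt"] == action[2]))
    stop("illegal action")
  K <- env$cfg$history
  list(drug = state$drug, current = action[2],
       hist_nodes = c(state$current, state$hist_nodes)[seq_len(K)],
       hist_preds = c(action[1], state$hist_preds)[seq_len(K)],
       t = state$t + 1L)
}

#' State embedding
#'
#' Concatenation of the attribute embeddings of the start drug, the current
#' node and the `K` history nodes, plus one-hot encodings of the `K`
#' history predicates.
#'
#' @param env a `moa_env`.
#' @param state a state.
#' @return numeric vector of length `env$state_dim`.
#' @export
state_embedding <- function(env, state) {
  np <- length(env$preds)
  oh <- matrix(0, length(state$hist_preds), np)
  oh[cbind(seq_along(state$hist_preds), state$hist_preds)] <- 1
  c(env$X[state$drug, ], env$X[state$current, ],
    t(env$X[state$hist_nodes, , drop = FALSE]), t(oh))
}

# ---- MLP with batch-norm (EMA statistics) + ELU, manual backprop --------

.make_mlp <- function(din, dh, dout) {
  gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  list(W1 = gl(din, dh), b1 = numeric(dh),
       g1 = rep(1, dh), be1 = numeric(dh),
       rm1 = numeric(dh), rv1 = rep(1, dh),
       W2 = gl(dh, dh), b2 = numeric(dh),
       g2 = rep(1, dh), be2 = numeric(dh),
       rm2 = numeric(dh), rv2 = rep(1, dh),
       W3 = gl(dh, dout), b3 = numeric(dout))
}

.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
.elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# forward; batch statistics update the EMA (momentum 0.1) when train = TRUE
# and the batch has >= 2 rows; normalization always uses the EMA statistics,
# which are treated as constants during backprop
.mlp_forward <- function(net, X, train = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  upd <- train && nrow(X) >= 2L
  Z1 <- sweep(X %*% net$W1, 2, net$b1, "+")
  if (upd) {
    net$rm1 <- 0.9 * net$rm1 + 0.1 * colMeans(Z1)
    net$rv1 <- 0.9 * net$rv1 + 0.1 * apply(Z1, 2, stats::var)
  }
  nh1 <- sweep(sweep(Z1, 2, net$rm1, "-"), 2, sqrt(net$rv1 + .BN_EPS), "/")
  y1 <- sweep(sweep(nh1, 2, net$g1, "*"), 2, net$be1, "+")
  a1 <- .elu(y1)
  Z2 <- sweep(a1 %*% net$W2, 2, net$b2, "+")
  if (upd) {
    net$rm2 <- 0.9 * net$rm2 + 0.1 * colMeans(Z2)
    net$rv2 <- 0.9 * net$rv2 + 0.1 * apply(Z2, 2, stats::var)
  }
  nh2 <- sweep(sweep(Z2, 2, net$rm2, "-"), 2, sqrt(net$rv2 + .BN_EPS), "/")
  y2 <- sweep(sweep(nh2, 2, net$g2, "*"), 2, net$be2, "+")
  a2 <- .elu(y2)
  out <- sweep(a2 %*% net$W3, 2, net$b3, "+")
  list(out = out, net = net,
       cache = list(X = X, nh1 = nh1, y1 = y1, a1 = a1,
                    nh2 = nh2, y2 = y2, a2 = a2))
}

.mlp_backward <- function(net, cache, dOut) {
  if (is.null(dim(dOut))) dOut <- matrix(dOut, nrow = 1L)
  dW3 <- crossprod(cache$a2, dOut); db3 <- colSums(dOut)
  da2 <- dOut %*% t(net$W3)
  dy2 <- da2 * .elu_grad(cache$y2)
  dg2 <- colSums(dy2 * cache$nh2); dbe2 <- colSums(dy2)
  dZ2 <- sweep(sweep(dy2, 2, net$g2, "*"), 2, sqrt(net$rv2 + .BN_EPS), "/")
  dW2 <- crossprod(cache$a1, dZ2); db2 <- colSums(dZ2)
  da1 <- dZ2 %*% t(net$W2)
  dy1 <- da1 * .elu_grad(cache$y1)
  dg1 <- colSums(dy1 * cache$nh1); dbe1 <- colSums(dy1)
  dZ1 <- sweep(sweep(dy1, 2, net$g1, "*"), 2, sqrt(net$rv1 + .BN_EPS), "/")
  dW1 <- crossprod(cache$X, dZ1); db1 <- colSums(dZ1)
  list(grads = list(W1 = dW1, b1 = db1, g1 = dg1, be1 = dbe1,
                    W2 = dW2, b2 = db2, g2 = dg2, be2 = dbe2,
                    W3 = dW3, b3 = db3),
       dX = dZ1 %*% t(net$W1))
}

.PARAM_NAMES <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2", "W3", "b3")

.adam_new <- function(net)
  list(m = lapply(net[.PARAM_NAMES], function(p) p * 0),
       v = lapply(net[.PARAM_NAMES], function(p) p * 0), t = 0)

.adam_step <- function(net, grads, st, lr) {
  st$t <- st$t + 1
  for (nm in .PARAM_NAMES) {
    st$m[[nm]] <- 0.9 * st$m[[nm]] + 0.1 * grads[[nm]]
    st$v[[nm]] <- 0.999 * st$v[[nm]] + 0.001 * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - 0.9^st$t)
    vh <- st$v[[nm]] / (1 - 0.999^st$t)
    net[[nm]] <- net[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
  }
  list(net = net, st = st)
}

#' Initialize an untrained mechanism-of-action model
#'
#' Four subnetworks share the same three-layer architecture (linear,
#' batch-norm, ELU twice, then linear) but own separate parameters; the
#' actor, critic and path discriminator each own node and predicate
#' embedding matrices for action encoding, and the meta-path discriminator
#' owns a category embedding matrix.  Index 1 of every embedding matrix is
#' the reserved dummy.
#'
#' @param env a `moa_env`.
#' @return object of class `moa_model`.
#' @export
moa_init <- function(env) {
  cfg <- env$cfg
  set.seed(cfg$seed)
  d <- cfg$action_emb_dim
  nn <- length(env$node_ids); np <- length(env$preds)
  emb <- function(n) matrix(stats::rnorm(n * d, sd = 0.1), n, d)
  nets <- list(
    actor  = .make_mlp(env$state_dim, cfg$hidden_dim, 2L * d),
    critic = .make_mlp(env$state_dim, cfg$hidden_dim, 2L * d),
    disc_p = .make_mlp(env$state_dim + 2L * d, cfg$hidden_dim, 1L),
    disc_m = .make_mlp((cfg$max_hops + 1L) * d, cfg$hidden_dim, 1L))
  embs <- list(
    actor  = list(node = emb(nn), pred = emb(np)),
    critic = list(node = emb(nn), pred = emb(np)),
    disc_p = list(node = emb(nn), pred = emb(np)),
    disc_m = list(cat = emb(length(env$cats))))
  structure(list(env = env, cfg = cfg, nets = nets, embs = embs,
                 log = NULL), class = "moa_model")
}

.as_action_row <- function(action) {
  if (is.matrix(action)) action <- action[1L, ]
  matrix(as.integer(action), 1L, 2L, dimnames = list(NULL, c("pred", "nxt")))
}

# action embedding rows [pred_emb ; node_emb] for a subnetwork
.action_embed <- function(model, subnet, A) {
  e <- model$embs[[subnet]]
  cbind(e$pred[A[, "pred"], , drop = FALSE],
        e$node[A[, "nxt"], , drop = FALSE])
}

#' Actor policy: action probabilities at a state
#'
#' Softmax over the dot products of each action embedding with the actor
#' MLP output for the state; probabilities are positive and sum to one
#' over exactly the action space.
#'
#' @param model a `moa_model`.
#' @param state a state.
#' @param A optional precomputed [action_space()] matrix.
#' @return numeric probability vector, one entry per action row.
#' @export
actor_policy <- function(model, state, A = NULL) {
  if (is.null(A)) A <- action_space(model$env, state)
  s <- state_embedding(model$env, state)
  m <- .mlp_forward(model$nets$actor, s)$out[1L, ]
  logits <- .action_embed(model, "actor", A) %*% m
  z <- exp(logits - max(logits))
  as.numeric(z / sum(z))
}

#' Critic value of a state-action pair
#'
#' Dot product of the critic MLP output for the state with the critic's
#' embedding of the action.
#'
#' @param model a `moa_model`.
#' @param state a state.
#' @param action integer `c(pred, nxt)` action.
#' @return numeric scalar.
#' @export
critic_value <- function(model, state, action) {
  s <- state_embedding(model$env, state)
  q <- .mlp_forward(model$nets$critic, s)$out[1L, ]
  a <- .action_embed(model, "critic", .as_action_row(action))
  sum(q * a[1L, ])
}

.disc_p_prob <- function(model, s_emb, A_rows) {
  x <- cbind(matrix(s_emb, nrow = nrow(A_rows), ncol = length(s_emb),
                    byrow = TRUE)[, , drop = FALSE],
             A_rows)
  p <- 1 / (1 + exp(-.mlp_forward(model$nets$disc_p, x)$out[, 1L]))
  pmin(pmax(p, .CLIP_EPS), 1 - .CLIP_EPS)
}

# meta-path embedding: concatenated category embeddings over max_hops + 1
# positions, shorter paths padded by repeating the final category
.metapath_input <- function(model, cats_idx) {
  L <- model$cfg$max_hops + 1L
  if (length(cats_idx) < L)
    cats_idx <- c(cats_idx, rep(cats_idx[length(cats_idx)],
                                L - length(cats_idx)))
  as.numeric(t(model$embs$disc_m$cat[cats_idx[seq_len(L)], , drop = FALSE]))
}

.disc_m_prob <- function(model, cats_idx) {
  x <- .metapath_input(model, cats_idx)
  p <- 1 / (1 + exp(-.mlp_forward(model$nets$disc_m, x)$out[1L, 1L]))
  min(max(p, .CLIP_EPS), 1 - .CLIP_EPS)
}

#' Discriminator-based intermediate rewards
#'
#' Log-odds of the path discriminator on the (state, action) segment and of
#' the meta-path discriminator on the path's category sequence; outputs are
#' clipped away from 0/1 before the log-odds.
#'
#' @param model a `moa_model`.
#' @param state a state.
#' @param action integer `c(pred, nxt)`.
#' @param metapath integer vector of category indices of the path.
#' @return list with `R_p` and `R_m`.
#' @export
discriminator_rewards <- function(model, state, action, metapath) {
  s <- state_embedding(model$env, state)
  a <- .action_embed(model, "disc_p", .as_action_row(action))
  dp <- .disc_p_prob(model, s, a)
  dm <- .disc_m_prob(model, metapath)
  list(R_p = log(dp) - log(1 - dp), R_m = log(dm) - log(1 - dm))
}

#' Combined per-step reward
#'
#' \deqn{R_t = \alpha_p R_{p,t} + \alpha_m R_{m,t} +
#'   (1 - \alpha_p - \alpha_m)\, \gamma^{T - t} R_{e,T}}
#'
#' @param cfg a [moa_config()].
#' @param R_p,R_m discriminator rewards at step `t`.
#' @param R_eT terminal environment reward.
#' @param t step index (1-based; `t = T` is the final step).
#' @return numeric scalar.
#' @export
combined_reward <- function(cfg, R_p, R_m, R_eT, t) {
  cfg$alpha_p * R_p + cfg$alpha_m * R_m +
    (1 - cfg$alpha_p - cfg$alpha_m) * cfg$gamma^(cfg$max_hops - t) * R_eT
}

#' Terminal reward from the drug-repurposing classifier
#'
#' 1 if the final node is a known treated disease of the drug; the treat
#' probability if it is a disease predicted as treat; 0 if a disease
#' predicted otherwise; -1 if not a disease node at all.
#'
#' @param drp_model fitted [fit_drp()] model.
#' @param emb embedding matrix used by the classifier.
#' @param drug,v_T node ids of the start drug and final node.
#' @param known_diseases disease ids known to be treated by `drug`.
#' @param disease_ids all disease node ids.
#' @return numeric scalar in `[-1, 1]`.
#' @export
terminal_reward <- function(drp_model, emb, drug, v_T, known_diseases,
                            disease_ids) {
  if (v_T %in% known_diseases) return(1)
  if (!v_T %in% disease_ids) return(-1)
  pr <- predict_drp(drp_model, pair_features(emb, data.table(drug = drug,
                                                             disease = v_T)))
  if (pr$class[1L] == "treat") pr$p_treat[1L] else 0
}

#' Binary cross-entropy losses of the two discriminators
#'
#' @param model a `moa_model`.
#' @param pos_sa,neg_sa lists of `list(state, action)` segments
#'   (demonstration / actor-generated).
#' @param pos_mp,neg_mp lists of category-index metapaths.
#' @return list with `L_p` and `L_m` (mean BCE over positives plus mean
#'   over negatives, per discriminator).
#' @export
discriminator_losses <- function(model, pos_sa, neg_sa, pos_mp, neg_mp) {
  if (!length(pos_sa) || !length(neg_sa) || !length(pos_mp) || !length(neg_mp))
    stop("both positive and negative samples are required")
  dprob <- function(seg) {
    s <- state_embedding(model$env, seg$state)
    a <- .action_embed(model, "disc_p", .as_action_row(seg$action))
    .disc_p_prob(model, s, a)
  }
  dp_pos <- vapply(pos_sa, dprob, 0); dp_neg <- vapply(neg_sa, dprob, 0)
  dm_pos <- vapply(pos_mp, function(m) .disc_m_prob(model, m), 0)
  dm_neg <- vapply(neg_mp, function(m) .disc_m_prob(model, m), 0)
  list(L_p = -mean(log(dp_pos)) - mean(log(1 - dp_neg)),
       L_m = -mean(log(dm_pos)) - mean(log(1 - dm_neg)))
}

# reconstruct the (state, action-index) sequence of a node/predicate path,
# padding to T steps with self-loop actions; returns NULL if some action is
# not available (e.g. pruned)
.path_segments <- function(model, path) {
  env <- model$env
  cfg <- model$cfg
  st <- env_initial_state(env, path$nodes[1L])
  segs <- vector("list", cfg$max_hops)
  nsteps <- length(path$predicates)
  for (t in seq_len(cfg$max_hops)) {
    A <- action_space(env, st)
    if (t <= nsteps) {
      pi_ <- env$pidx[[path$predicates[t]]]
      ni <- env$nidx[[path$nodes[t + 1L]]]
      if (is.null(pi_) || is.null(ni)) return(NULL)
      ai <- which(A[, "pred"] == pi_ & A[, "nxt"] == ni)[1L]
    } else ai <- 1L                      # self-loop padding
    if (is.na(ai)) return(NULL)
    segs[[t]] <- list(state = st, A = A, action_i = ai)
    st <- env_step(env, st, A[ai, ])
  }
  segs
}

#' Behavior-cloning warm start of the actor
#'
#' Minimizes the mean squared error between the actor's action-probability
#' vector and the one-hot demonstration action at every demonstration
#' state (demonstration paths shorter than `T` are padded with self-loop
#' actions, teaching the agent to stop).
#'
#' @param model a `moa_model`.
#' @param demo_paths list of paths (`list(nodes, predicates)`).
#' @param epochs passes over the demonstration set (default
#'   `cfg$bc_epochs`).
#' @param lr learning rate (default `cfg$bc_lr`).
#' @return the model with an updated actor; attribute `bc_loss` holds the
#'   per-epoch mean loss.
#' @export
behavior_clone <- function(model, demo_paths, epochs = model$cfg$bc_epochs,
                           lr = model$cfg$bc_lr) {
  if (epochs == 0L || !length(demo_paths)) return(model)
  segs <- unlist(lapply(demo_paths, function(p) .path_segments(model, p)),
                 recursive = FALSE)
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (!length(segs)) stop("no demonstration path is walkable")
  ad <- .adam_new(model$nets$actor)
  losses <- numeric(epochs)
  d <- model$cfg$action_emb_dim
  for (ep in seq_len(epochs)) {
    gacc <- NULL; loss <- 0
    demb <- model$embs$actor
    dnode <- demb$node * 0; dpred <- demb$pred * 0
    for (seg in segs) {
      s <- state_embedding(model$env, seg$state)
      fw <- .mlp_forward(model$nets$actor, s, train = TRUE)
      model$nets$actor <- fw$net
      m <- fw$out[1L, ]
      AE <- .action_embed(model, "actor", seg$A)
      logits <- as.numeric(AE %*% m)
      z <- exp(logits - max(logits)); p <- z / sum(z)
      y <- numeric(length(p)); y[seg$action_i] <- 1
      loss <- loss + mean((p - y)^2)
      dp <- 2 * (p - y) / length(p)
      dlogits <- p * (dp - sum(dp * p))
      dm <- as.numeric(crossprod(AE, dlogits))
      dAE <- outer(dlogits, m)
      bw <- .mlp_backward(model$nets$actor, fw$cache, dm)
      if (is.null(gacc)) gacc <- bw$grads
      else for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] + bw$grads[[nm]]
      dpred <- dpred + rowsum_into(dpred * 0, seg$A[, "pred"],
                                   dAE[, seq_len(d), drop = FALSE])
      dnode <- dnode + rowsum_into(dnode * 0, seg$A[, "nxt"],
                                   dAE[, d + seq_len(d), drop = FALSE])
    }
    n <- length(segs)
    for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / n
    up <- .adam_step(model$nets$actor, gacc, ad, lr)
    model$nets$actor <- up$net; ad <- up$st
    model$embs$actor$pred <- model$embs$actor$pred - lr * dpred / n
    model$embs$actor$node <- model$embs$actor$node - lr * dnode / n
    losses[ep] <- loss / n
  }
  attr(model, "bc_loss") <- losses
  model
}

# roll out one episode following the current policy; returns list of
# per-step records plus the visited node sequence
.rollout <- function(model, drug) {
  env <- model$env
  st <- env_initial_state(env, drug)
  steps <- vector("list", model$cfg$max_hops)
  nodes <- env$node_ids[st$current]
  for (t in seq_len(model$cfg$max_hops)) {
    A <- action_space(env, st)
    p <- actor_policy(model, st, A)
    ai <- sample.int(nrow(A), 1L, prob = p)
    steps[[t]] <- list(state = st, A = A, action_i = ai, prob = p)
    st <- env_step(env, st, A[ai, ])
    nodes <- c(nodes, env$node_ids[st$current])
  }
  list(steps = steps, final = st, nodes = nodes)
}

# one full-batch Adam update of a discriminator from embedded inputs
.disc_update <- function(net, adam_st, X, y, lr) {
  fw <- .mlp_forward(net, X, train = TRUE)
  net <- fw$net
  p <- 1 / (1 + exp(-fw$out[, 1L]))
  p <- pmin(pmax(p, .CLIP_EPS), 1 - .CLIP_EPS)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- matrix((p - y) / length(y), ncol = 1L)
  bw <- .mlp_backward(net, fw$cache, dlogit)
  up <- .adam_step(net, bw$grads, adam_st, lr)
  list(net = up$net, st = up$st, loss = loss, dX = bw$dX)
}

#' Train the mechanism-of-action RL agent
#'
#' Multistage training: (1) behavior cloning of the actor on demonstration
#' paths; (2) `warmup` epochs in which only the two discriminators train
#' while actor and critic stay frozen; (3) joint optimization - the critic
#' minimizes the squared temporal-difference error and the actor follows
#' the TD-weighted log-policy gradient with entropy regularization, while
#' the discriminators keep adversarially updating on fresh rollouts.
#' Rollouts start from the drugs of the training treat pairs and run
#' exactly `T` steps.  With `alpha_p = alpha_m = 0` (or no demonstration
#' paths) the discriminators are skipped and training reduces to plain
#' actor-critic with terminal-only shaping.
#'
#' @param model a `moa_model` from [moa_init()].
#' @param demo_paths list of demonstration paths (may be empty).
#' @param drp_model fitted [fit_drp()] model supplying terminal rewards.
#' @param drp_emb embedding matrix the classifier was trained on.
#' @param treat_pairs training-split treat pairs (`drug`, `disease`);
#'   defines rollout start drugs and each drug's known diseases.
#' @param behavior_cloning run the behavior-cloning stage (default TRUE
#'   when demonstrations are available).
#' @return the trained model; `model$log` holds per-epoch `L_a`, `L_c`,
#'   `L_p`, `L_m` and `mean_reward`.
#' @export
train_moa <- function(model, demo_paths, drp_model, drp_emb, treat_pairs,
                      behavior_cloning = length(demo_paths) > 0L) {
  cfg <- model$cfg
  env <- model$env
  use_disc <- (cfg$alpha_p > 0 || cfg$alpha_m > 0) && length(demo_paths) > 0L
  set.seed(cfg$seed + 1L)
  if (behavior_cloning && length(demo_paths))
    model <- behavior_clone(model, demo_paths)

  treat_pairs <- as.data.table(treat_pairs)
  known_by_drug <- split(treat_pairs$disease, treat_pairs$drug)
  start_drugs <- sort(unique(treat_pairs$drug))
  disease_ids <- env$node_ids[env$disease_idx]
  d <- cfg$action_emb_dim

  # demonstration segments / metapaths as discriminator positives
  demo_pos <- list(); demo_mp <- list(); demo_keys <- character()
  if (use_disc) {
    for (p in demo_paths) {
      segs <- .path_segments(model, p)
      if (is.null(segs)) next
      for (seg in segs) {
        demo_pos[[length(demo_pos) + 1L]] <- seg
        demo_keys <- c(demo_keys,
                       paste(seg$state$current, seg$A[seg$action_i, "pred"],
                             seg$A[seg$action_i, "nxt"], sep = "_"))
      }
      ni <- env$nidx[p$nodes]
      demo_mp[[length(demo_mp) + 1L]] <- env$node_cat[ni]
    }
    if (!length(demo_pos)) use_disc <- FALSE
  }
  demo_keys <- unique(demo_keys)

  ad_a <- .adam_new(model$nets$actor)
  ad_c <- .adam_new(model$nets$critic)
  ad_p <- .adam_new(model$nets$disc_p)
  ad_m <- .adam_new(model$nets$disc_m)
  log <- vector("list", cfg$epochs)

  seg_input <- function(subnet, seg) {
    a <- .action_embed(model, subnet,
                       seg$A[seg$action_i, , drop = FALSE])
    c(state_embedding(env, seg$state), a[1L, ])
  }

  for (epoch in seq_len(cfg$epochs)) {
    set.seed(cfg$seed + 1000L + epoch)
    drugs <- if (is.null(cfg$episodes_per_epoch)) start_drugs
             else sample(start_drugs, min(cfg$episodes_per_epoch,
                                          length(start_drugs)))
    rollouts <- lapply(drugs, function(dg) .rollout(model, dg))
    L_p <- NA_real_; L_m <- NA_real_

    if (use_disc) {
      # negatives: rollout segments not exactly matching a demonstration one
      neg <- list(); neg_mp <- list()
      for (ro in rollouts) {
        ni <- vapply(ro$nodes, function(x) env$nidx[[x]], 1L)
        mp <- env$node_cat[ni]
        if (!any(vapply(demo_mp, identical, TRUE, y = mp)))
          neg_mp[[length(neg_mp) + 1L]] <- mp
        for (seg in ro$steps) {
          key <- paste(seg$state$current, seg$A[seg$action_i, "pred"],
                       seg$A[seg$action_i, "nxt"], sep = "_")
          if (!key %in% demo_keys) neg[[length(neg) + 1L]] <- seg
        }
      }
      if (length(neg)) {
        Xp <- t(vapply(c(demo_pos, neg), function(s) seg_input("disc_p", s),
                       numeric(env$state_dim + 2L * d)))
        yp <- rep(1:0, c(length(demo_pos), length(neg)))
        up <- .disc_update(model$nets$disc_p, ad_p, Xp, yp, cfg$disc_lr)
        model$nets$disc_p <- up$net; ad_p <- up$st; L_p <- up$loss
        # embedding-row updates for the action part of the input
        allseg <- c(demo_pos, neg)
        dA <- up$dX[, env$state_dim + seq_len(2L * d), drop = FALSE]
        for (i in seq_along(allseg)) {
          arow <- allseg[[i]]$A[allseg[[i]]$action_i, ]
          model$embs$disc_p$pred[arow["pred"], ] <-
            model$embs$disc_p$pred[arow["pred"], ] -
            cfg$disc_lr * dA[i, seq_len(d)]
          model$embs$disc_p$node[arow["nxt"], ] <-
            model$embs$disc_p$node[arow["nxt"], ] -
            cfg$disc_lr * dA[i, d + seq_len(d)]
        }
      }
      if (length(neg_mp)) {
        Xm <- t(vapply(c(demo_mp, neg_mp),
                       function(mm) .metapath_input(model, mm),
                       numeric((cfg$max_hops + 1L) * d)))
        ym <- rep(1:0, c(length(demo_mp), length(neg_mp)))
        up <- .disc_update(model$nets$disc_m, ad_m, Xm, ym, cfg$disc_lr)
        model$nets$disc_m <- up$net; ad_m <- up$st; L_m <- up$loss
        allmp <- c(demo_mp, neg_mp)
        L1 <- cfg$max_hops + 1L
        for (i in seq_along(allmp)) {
          mm <- allmp[[i]]
          if (length(mm) < L1) mm <- c(mm, rep(mm[length(mm)], L1 - length(mm)))
          dcat <- matrix(up$dX[i, ], nrow = L1, byrow = TRUE)
          for (j in seq_len(L1))
            model$embs$disc_m$cat[mm[j], ] <-
              model$embs$disc_m$cat[mm[j], ] - cfg$disc_lr * dcat[j, ]
        }
      }
    }

    L_a <- NA_real_; L_c <- NA_real_; mean_rew <- NA_real_
    if (epoch > cfg$warmup) {
      ga <- NULL; gc <- NULL
      demb_a <- list(node = model$embs$actor$node * 0,
                     pred = model$embs$actor$pred * 0)
      demb_c <- list(node = model$embs$critic$node * 0,
                     pred = model$embs$critic$pred * 0)
      L_a <- 0; L_c <- 0; rew_sum <- 0; ntr <- 0
      for (ro in rollouts) {
        dg <- env$node_ids[ro$steps[[1L]]$state$drug]
        vT <- env$node_ids[ro$final$current]
        R_eT <- terminal_reward(drp_model, drp_emb, dg, vT,
                                known_by_drug[[dg]] %||% character(),
                                disease_ids)
        ni <- vapply(ro$nodes, function(x) env$nidx[[x]], 1L)
        mp <- env$node_cat[ni]
        Tn <- cfg$max_hops
        R <- numeric(Tn); Q <- numeric(Tn)
        for (t in seq_len(Tn)) {
          seg <- ro$steps[[t]]
          if (use_disc) {
            dr <- discriminator_rewards(model, seg$state,
                                        seg$A[seg$action_i, ], mp)
          } else dr <- list(R_p = 0, R_m = 0)
          R[t] <- combined_reward(cfg, dr$R_p, dr$R_m, R_eT, t)
          Q[t] <- critic_value(model, seg$state, seg$A[seg$action_i, ])
        }
        TD <- R + c(Q[-1L], 0) - Q
        rew_sum <- rew_sum + sum(R)
        for (t in seq_len(Tn)) {
          seg <- ro$steps[[t]]
          s <- state_embedding(env, seg$state)
          # ---- critic (semi-gradient of squared TD error) ----
          fwc <- .mlp_forward(model$nets$critic, s, train = TRUE)
          model$nets$critic <- fwc$net
          qvec <- fwc$out[1L, ]
          AEc <- .action_embed(model, "critic",
                               seg$A[seg$action_i, , drop = FALSE])[1L, ]
          dq <- -2 * TD[t]
          bwc <- .mlp_backward(model$nets$critic, fwc$cache, dq * AEc)
          if (is.null(gc)) gc <- bwc$grads
          else for (nm in names(gc)) gc[[nm]] <- gc[[nm]] + bwc$grads[[nm]]
          arow <- seg$A[seg$action_i, ]
          demb_c$pred[arow["pred"], ] <- demb_c$pred[arow["pred"], ] +
            dq * qvec[seq_len(d)]
          demb_c$node[arow["nxt"], ] <- demb_c$node[arow["nxt"], ] +
            dq * qvec[d + seq_len(d)]
          L_c <- L_c + TD[t]^2
          # ---- actor: -TD * grad log pi - entropy regularization ----
          fwa <- .mlp_forward(model$nets$actor, s, train = TRUE)
          model$nets$actor <- fwa$net
          m <- fwa$out[1L, ]
          AE <- .action_embed(model, "actor", seg$A)
          logits <- as.numeric(AE %*% m)
          z <- exp(logits - max(logits)); p <- z / sum(z)
          onehot <- numeric(length(p)); onehot[seg$action_i] <- 1
          lp <- log(pmax(p, .CLIP_EPS))
          ent_grad <- p * (lp - sum(p * lp))        # dH/dlogits = -this
          dlogits <- -TD[t] * (onehot - p) + cfg$entropy_weight * ent_grad
          dm <- as.numeric(crossprod(AE, dlogits))
          dAE <- outer(dlogits, m)
          bwa <- .mlp_backward(model$nets$actor, fwa$cache, dm)
          if (is.null(ga)) ga <- bwa$grads
          else for (nm in names(ga)) ga[[nm]] <- ga[[nm]] + bwa$grads[[nm]]
          idx <- seq_len(d)
          demb_a$pred <- demb_a$pred +
            rowsum_into(demb_a$pred * 0, seg$A[, "pred"], dAE[, idx, drop = FALSE])
          demb_a$node <- demb_a$node +
            rowsum_into(demb_a$node * 0, seg$A[, "nxt"], dAE[, d + idx, drop = FALSE])
          L_a <- L_a - TD[t] * lp[seg$action_i] -
            cfg$entropy_weight * (-sum(p * lp))
          ntr <- ntr + 1L
        }
      }
      if (ntr > 0L) {
        for (nm in names(ga)) ga[[nm]] <- ga[[nm]] / ntr
        for (nm in names(gc)) gc[[nm]] <- gc[[nm]] / ntr
        upa <- .adam_step(model$nets$actor, ga, ad_a, cfg$learning_rate)
        model$nets$actor <- upa$net; ad_a <- upa$st
        upc <- .adam_step(model$nets$critic, gc, ad_c, cfg$learning_rate)
        model$nets$critic <- upc$net; ad_c <- upc$st
        model$embs$actor$pred <- model$embs$actor$pred -
          cfg$learning_rate * demb_a$pred / ntr
        model$embs$actor$node <- model$embs$actor$node -
          cfg$learning_rate * demb_a$node / ntr
        model$embs$critic$pred <- model$embs$critic$pred -
          cfg$learning_rate * demb_c$pred / ntr
        model$embs$critic$node <- model$embs$critic$node -
          cfg$learning_rate * demb_c$node / ntr
        L_a <- L_a / ntr; L_c <- L_c / ntr
        mean_rew <- rew_sum / ntr
        if (!is.finite(L_a) || !is.finite(L_c))
          stop("training diverged (non-finite loss) at epoch ", epoch)
      }
    }
    log[[epoch]] <- data.table(epoch = epoch, L_a = L_a, L_c = L_c,
                               L_p = L_p, L_m = L_m, mean_reward = mean_rew)
  }
  model$log <- rbindlist(log)
  model
}

# scatter-add rows of `add` into a zero matrix at (possibly repeated) idx
rowsum_into <- function(zero, idx, add) {
  rs <- rowsum(add, idx, reorder = FALSE)
  zero[as.integer(rownames(rs)), ] <- rs
  zero
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a trained MOA model
#' @param model a `moa_model`.
#' @param dir output directory.
#' @export
save_moa <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "moa_model.rds"))
  writeLines(jsonlite::toJSON(model$cfg[c("alpha_p", "alpha_m", "gamma",
                                          "max_hops", "history", "warmup",
                                          "seed")], auto_unbox = TRUE),
             file.path(dir, "moa_model.json"))
  if (!is.null(model$log))
    fwrite(model$log, file.path(dir, "training_log.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname save_moa
#' @export
load_moa <- function(dir) readRDS(file.path(dir, "moa_model.rds"))
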