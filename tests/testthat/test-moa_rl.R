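# force an MLP to compute the constant function x -> b3
zero_net <- function(net, b3 = 0) {
  for (nm in c("W1", "W2", "W3")) net[[nm]][] <- 0
  net$b1[] <- 0; net$b2[] <- 0
  net$g1[] <- 1; net$g2[] <- 1; net$be1[] <- 0; net$be2[] <- 0
  net$rm1[] <- 0; net$rm2[] <- 0; net$rv1[] <- 1; net$rv2[] <- 1
  net$b3[] <- b3
  net
}

tiny_env <- function(alpha_p = 0.1, alpha_m = 0.1, ...) {
  g <- tiny_graph()
  attr_tab <- attribute_embeddings(g, hash_encoder(16, seed = 1))
  cfg <- moa_config(alpha_p = alpha_p, alpha_m = alpha_m, max_hops = 3L,
                    history = 2L, hidden_dim = 8L, action_emb_dim = 4L,
                    seed = 3L, ...)
  moa_env(g, attr_tab, cfg)
}

test_that("environment steps maintain the history-K state", {
  env <- tiny_env()
  st <- env_initial_state(env, "d1")
  expect_equal(st$t, 0L)
  expect_equal(st$hist_nodes, c(1L, 1L))      # dummy padding

  A <- action_space(env, st)
  expect_equal(unname(A[1, "nxt"]), st$current)   # self-loop first
  expect_equal(nrow(A), 1L + 2L)                  # d1 has 2 out-edges

  # self-loop keeps the node, increments t
  st1 <- env_step(env, st, A[1, ])
  expect_equal(st1$current, st$current)
  expect_equal(st1$t, 1L)

  # two real steps fill the history with both (node, predicate) tuples
  st2 <- env_step(env, st, A[2, ])
  A2 <- action_space(env, st2)
  st3 <- env_step(env, st2, A2[2, ])
  expect_equal(st3$hist_nodes, c(st2$current, st$current))
  expect_equal(st3$hist_preds[2], unname(A[2, "pred"]))

  # episode over at t = T; illegal actions rejected
  stT <- st; stT$t <- env$cfg$max_hops
  expect_error(env_step(env, stT, A[1, ]), "over")
  expect_error(env_step(env, st, c(999L, 999L)), "illegal")

  s_emb <- state_embedding(env, st)
  expect_length(s_emb, env$state_dim)
})

test_that("action spaces are PageRank-pruned to the cap", {
  ids <- c("hub", paste0("n", 1:50))
  g <- knowledge_graph(
    data.frame(id = ids, name = ids, category = "Gene"),
    rbind(data.frame(subject = "hub", predicate = "r", object = ids[-1]),
          # n1..n5 get extra in-links, raising their PageRank
          data.frame(subject = paste0("n", 6:10), predicate = "r",
                     object = paste0("n", 1:5))))
  attr_tab <- attribute_embeddings(g, hash_encoder(8, seed = 1))
  cfg <- moa_config(neighbor_cap = 10L, hidden_dim = 8L, action_emb_dim = 4L,
                    seed = 1L)
  env <- moa_env(g, attr_tab, cfg)
  A <- action_space(env, env_initial_state(env, "hub"))
  expect_equal(nrow(A), 11L)              # self-loop + capped 10

  # oracle: the kept neighbors are the top-cap by independent PageRank sort
  pr <- kg_pagerank(g)
  nb <- ids[-1]
  top <- nb[order(-pr[nb], nb)][1:10]
  kept <- env$node_ids[A[-1, "nxt"]]
  expect_setequal(kept, top)
})

test_that("actor policy is a masked softmax over the action space", {
  env <- tiny_env()
  model <- moa_init(env)
  st <- env_initial_state(env, "d1")
  A <- action_space(env, st)
  p <- actor_policy(model, st, A)
  expect_length(p, nrow(A))               # zero mass outside by construction
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-7)

  # all-equal logits give the uniform distribution
  mu <- model
  mu$embs$actor$node[] <- 0; mu$embs$actor$pred[] <- 0
  expect_equal(actor_policy(mu, st, A), rep(1 / nrow(A), nrow(A)),
               tolerance = 1e-12)

  # a single available action gets probability 1
  stz <- env_initial_state(env, "z1")     # z1 has no out-edges
  expect_equal(actor_policy(model, stz), 1)
})

test_that("critic value is the dot product of MLP output and action embedding", {
  env <- tiny_env()
  model <- moa_init(env)
  st <- env_initial_state(env, "d1")
  A <- action_space(env, st)

  # zero action embeddings give value 0
  m0 <- model
  m0$embs$critic$node[] <- 0; m0$embs$critic$pred[] <- 0
  expect_equal(critic_value(m0, st, A[2, ]), 0)

  # linearity: doubling the action embedding doubles the value
  m2 <- model
  q1 <- critic_value(m2, st, A[2, ])
  m2$embs$critic$node <- 2 * m2$embs$critic$node
  m2$embs$critic$pred <- 2 * m2$embs$critic$pred
  expect_equal(critic_value(m2, st, A[2, ]), 2 * q1, tolerance = 1e-12)

  # exact hand computation with a constant-output MLP
  mc <- model
  mc$nets$critic <- zero_net(mc$nets$critic, b3 = c(1, 2, 3, 4, 5, 6, 7, 8))
  a_emb <- c(mc$embs$critic$pred[A[2, "pred"], ],
             mc$embs$critic$node[A[2, "nxt"], ])
  expect_equal(critic_value(mc, st, A[2, ]), sum((1:8) * a_emb),
               tolerance = 1e-12)
})

test_that("discriminator rewards are clipped log-odds", {
  env <- tiny_env()
  model <- moa_init(env)
  st <- env_initial_state(env, "d1")
  A <- action_space(env, st)
  mp <- env$node_cat[c(st$drug, st$drug, st$drug, st$drug)]

  # D = 0.5 gives zero reward
  m5 <- model
  m5$nets$disc_p <- zero_net(m5$nets$disc_p, b3 = 0)
  m5$nets$disc_m <- zero_net(m5$nets$disc_m, b3 = 0)
  r <- discriminator_rewards(m5, st, A[2, ], mp)
  expect_equal(r$R_p, 0, tolerance = 1e-12)
  expect_equal(r$R_m, 0, tolerance = 1e-12)

  # D_m = 0.9 gives ln 9
  m9 <- m5
  m9$nets$disc_m <- zero_net(m9$nets$disc_m, b3 = log(9))
  expect_equal(discriminator_rewards(m9, st, A[2, ], mp)$R_m, log(9),
               tolerance = 1e-9)
  expect_equal(log(9), 2.1972246, tolerance = 1e-7)

  # monotone in D over a grid; saturated D is clipped, stays finite
  vals <- vapply(c(-30, -2, 0, 2, 30), function(b) {
    mm <- m5; mm$nets$disc_p <- zero_net(mm$nets$disc_p, b3 = b)
    discriminator_rewards(mm, st, A[2, ], mp)$R_p
  }, 0)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(is.finite(vals)))
})

test_that("combined_reward implements the decayed mixture", {
  cfg <- moa_config(alpha_p = 0.1, alpha_m = 0.1, gamma = 0.9, max_hops = 3L)
  # hand-evaluated: 0.1*1 + 0.1*(-1) + 0.8 * 0.9^2 * 1 = 0.648
  expect_equal(combined_reward(cfg, R_p = 1, R_m = -1, R_eT = 1, t = 1),
               0.648, tolerance = 1e-12)
  # terminal-only degenerate case
  cfg0 <- moa_config(alpha_p = 0, alpha_m = 0, gamma = 0.7, max_hops = 3L)
  expect_equal(combined_reward(cfg0, 5, -5, R_eT = 2, t = 1), 0.7^2 * 2)
  # at t = T the decay is gamma^0 = 1
  expect_equal(combined_reward(cfg, 0, 0, R_eT = 1, t = 3), 0.8)
  # gamma in (0, 1] bounds the environment term by |R_eT|
  for (gm in c(0.2, 0.6, 1)) {
    cfgg <- moa_config(alpha_p = 0, alpha_m = 0, gamma = gm, max_hops = 3L)
    expect_lte(abs(combined_reward(cfgg, 0, 0, R_eT = -1, t = 2)), 1)
  }
})

test_that("terminal_reward follows its four branches exactly", {
  # training features mimic [drug ; disease] pair structure so that the
  # crafted pairs below land squarely in one class each
  b <- list(X = rbind(matrix(rep(c(4, 4, 0, 0), each = 20), 20, 4),
                      matrix(4, 20, 4), matrix(-4, 20, 4)),
            y = rep(c("not_treat", "treat", "unknown"), each = 20))
  drp <- suppressMessages(fit_drp(b$X, b$y, ntree = 30, seed = 1))
  emb <- rbind(D = c(4, 4), Zt = c(4, 4), Zn = c(0, 0), G = c(9, 9))
  diseases <- c("Zt", "Zn")

  expect_equal(terminal_reward(drp, emb, "D", "Zt", "Zt", diseases), 1)
  expect_equal(terminal_reward(drp, emb, "D", "G", character(), diseases), -1)
  pr_t <- predict_drp(drp, pair_features(emb, data.frame(drug = "D",
                                                         disease = "Zt")))
  expect_equal(pr_t$class, "treat")
  expect_equal(terminal_reward(drp, emb, "D", "Zt", character(), diseases),
               pr_t$p_treat)
  pr_n <- predict_drp(drp, pair_features(emb, data.frame(drug = "D",
                                                         disease = "Zn")))
  expect_false(pr_n$class == "treat")
  expect_equal(terminal_reward(drp, emb, "D", "Zn", character(), diseases), 0)
})

test_that("discriminator losses are the two-term binary cross-entropy", {
  env <- tiny_env()
  model <- moa_init(env)
  st <- env_initial_state(env, "d1")
  A <- action_space(env, st)
  seg <- list(state = st, action = A[2, ])
  mp <- env$node_cat[rep(st$drug, 4)]

  # D identically 0.5 on both discriminators: L = 2 log 2 each
  m5 <- model
  m5$nets$disc_p <- zero_net(m5$nets$disc_p, 0)
  m5$nets$disc_m <- zero_net(m5$nets$disc_m, 0)
  L <- discriminator_losses(m5, list(seg), list(seg), list(mp), list(mp))
  expect_equal(L$L_p, 2 * log(2), tolerance = 1e-9)
  expect_equal(L$L_m, 2 * log(2), tolerance = 1e-9)

  # near-perfect discriminator: loss collapses toward the clipping floor
  mperf <- model
  mperf$nets$disc_p <- zero_net(mperf$nets$disc_p, 40)   # D ~ 1
  Lp <- discriminator_losses(mperf, list(seg), list(seg), list(mp), list(mp))
  # positives perfectly classified; negatives maximally wrong
  expect_lt(-log(1 - 1e-7) * 2, 1e-5)

  # hand-computed BCE on two samples with known D values
  mh <- model
  mh$nets$disc_m <- zero_net(mh$nets$disc_m, log(3))   # D_m = 0.75
  Lh <- discriminator_losses(mh, list(seg), list(seg), list(mp), list(mp))
  expect_equal(Lh$L_m, -log(0.75) - log(0.25), tolerance = 1e-9)

  expect_error(discriminator_losses(model, list(), list(seg), list(mp),
                                    list(mp)), "required")
})

test_that("behavior cloning converges to the demonstrated actions", {
  env <- tiny_env()
  model <- moa_init(env)
  demo <- list(list(nodes = c("d1", "g1", "p1", "z1"),
                    predicates = c("targets", "participates_in",
                                   "associated_with_condition")))
  # zero epochs change nothing
  m0 <- behavior_clone(model, demo, epochs = 0L)
  expect_identical(m0$nets$actor, model$nets$actor)

  m <- behavior_clone(model, demo, epochs = 150L, lr = 0.05)
  bc <- attr(m, "bc_loss")
  expect_lt(bc[length(bc)], bc[1])
  # the argmax action at each demonstration state equals the demo action
  st <- env_initial_state(env, "d1")
  for (i in 1:3) {
    A <- action_space(env, st)
    p <- actor_policy(m, st, A)
    want <- which(env$node_ids[A[, "nxt"]] == demo[[1]]$nodes[i + 1] &
                  env$preds[A[, "pred"]] == demo[[1]]$predicates[i])
    expect_equal(which.max(p), want)
    st <- env_step(env, st, A[want, ])
  }
  # seeded: rerun is identical
  m2 <- behavior_clone(model, demo, epochs = 150L, lr = 0.05)
  expect_identical(m$nets$actor, m2$nets$actor)
})

test_that("zero TD error yields zero critic loss", {
  # alpha_p + alpha_m = 1 removes the environment term; with no
  # demonstrations the discriminator rewards are fixed at zero, and a
  # zeroed critic gives Q = 0 everywhere, so every TD error is 0
  env <- tiny_env(alpha_p = 0.5, alpha_m = 0.5, epochs = 1L, warmup = 0L)
  model <- moa_init(env)
  model$nets$critic <- zero_net(model$nets$critic, rep(0, 8))
  model$embs$critic$node[] <- 0; model$embs$critic$pred[] <- 0
  b <- list(X = rbind(matrix(0, 10, 4), matrix(4, 10, 4), matrix(-4, 10, 4)),
            y = rep(c("not_treat", "treat", "unknown"), each = 10))
  drp <- suppressMessages(fit_drp(b$X, b$y, ntree = 10, seed = 1))
  emb <- rbind(d1 = c(1, 1), d2 = c(1, 1), z1 = c(4, 4))
  out <- train_moa(model, list(), drp, emb,
                   data.frame(drug = "d1", disease = "z1"),
                   behavior_cloning = FALSE)
  expect_equal(out$log$L_c, 0, tolerance = 1e-12)
})

test_that("training is deterministic and freezes actor/critic in warmup", {
  env <- tiny_env(epochs = 5L, warmup = 2L, bc_epochs = 5L)
  b <- list(X = rbind(matrix(0, 10, 4), matrix(4, 10, 4), matrix(-4, 10, 4)),
            y = rep(c("not_treat", "treat", "unknown"), each = 10))
  drp <- suppressMessages(fit_drp(b$X, b$y, ntree = 10, seed = 1))
  emb <- rbind(d1 = c(4, 4), d2 = c(4, 4), z1 = c(4, 4))
  demo <- list(list(nodes = c("d1", "g1", "p1", "z1"),
                    predicates = c("targets", "participates_in",
                                   "associated_with_condition")))
  pairs <- data.frame(drug = "d1", disease = "z1")

  m1 <- train_moa(moa_init(env), demo, drp, emb, pairs)
  m2 <- train_moa(moa_init(env), demo, drp, emb, pairs)
  expect_identical(m1$nets, m2$nets)
  expect_identical(m1$embs, m2$embs)
  expect_equal(m1$log, m2$log)

  # during the warmup epochs only the discriminators move
  expect_true(all(is.na(m1$log$L_a[1:2])))
  expect_false(any(is.na(m1$log$L_p)))
  # with alpha_p = alpha_m = 0 the discriminators are skipped entirely
  env0 <- tiny_env(alpha_p = 0, alpha_m = 0, epochs = 3L, warmup = 1L)
  m0 <- train_moa(moa_init(env0), list(), drp, emb, pairs,
                  behavior_cloning = FALSE)
  expect_true(all(is.na(m0$log$L_p)))
  expect_false(any(is.na(m0$log$L_a[-1])))
})
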