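test_that("the policy space matches brute-force trajectory enumeration", {
  hm <- tmaze_model()
  pol <- hm$level1$policies[, 1:2, 1]
  # oracle: simulate every two-move action pair from the centre under the
  # absorbing-arm rule and count the distinct trajectories
  traj <- unique(t(apply(expand.grid(a1 = 1:4, a2 = 1:4), 1, function(a) {
    l2 <- a[1]
    l3 <- if (l2 %in% c(2, 3)) l2 else a[2]
    c(l2, l3)
  })))
  expect_equal(nrow(pol), 10L)
  expect_equal(nrow(traj), 10L)
  # each policy realises one distinct trajectory
  realized <- t(apply(pol, 1, function(a) {
    l2 <- a[1]
    l3 <- if (l2 %in% c(2, 3)) l2 else a[2]
    c(l2, l3)
  }))
  expect_equal(nrow(unique(realized)), 10L)
})

test_that("all built tables satisfy the conditional-table invariants", {
  hm <- tmaze_model()
  m1 <- hm$level1
  expect_silent(validate_mdp_model(m1))
  for (mod in names(m1$A)) expect_silent(validate_cond_table(m1$A[[mod]]))
  for (f in names(hm$link$states)) {
    expect_silent(validate_cond_table(cond_table(hm$link$states[[f]])))
  }
  nP <- dim(hm$link$policy_bias)[1]
  expect_true(all(abs(colSums(matrix(hm$link$policy_bias, nP)) - 1) < 1e-10))
})

test_that("arms absorb and the context never moves", {
  hm <- tmaze_model()
  B <- hm$level1$B$location
  for (arm in 2:3) for (a in 1:4) {
    expect_identical(B[, arm, a], as.numeric(seq_len(4) == arm))
  }
  expect_identical(hm$level1$B$context[, , 1], diag(2))
})

test_that("the context factor doubles as the third semantic slot", {
  hm <- tmaze_model()
  m1 <- hm$level1
  # one shared factor, not a duplicate
  expect_true("context" %in% names(m1$factors))
  expect_false(any(c("side", "context2") %in% names(m1$factors)))
  # the maze cue reveals it ...
  d <- dim(m1$A$extero)
  ctx_dim <- 1L + match("context", names(m1$factors))
  cue_idx <- match("cue", m1$factors$location)
  for (ctx in 1:2) {
    states <- c(cue_idx, ctx, 1, 1, 1, 1, 1)
    col <- matrix(m1$A$extero, d[1])[, deepexplain:::flat_index(states, d[-1])]
    expect_equal(which.max(col), 3L + ctx)  # cue-left / cue-right
  }
  # ... and the answer frame speaks it at the side position
  a4 <- match("a4", m1$factors$syntax)
  vocab <- m1$outcomes$heard
  dh <- dim(m1$A$heard)
  for (ctx in 1:2) {
    states <- c(1, ctx, 1, 1, 1, 1, a4)
    col <- matrix(m1$A$heard, dh[1])[, deepexplain:::flat_index(states, dh[-1])]
    expect_equal(vocab[which.max(col)], c("left", "right")[ctx])
  }
})

test_that("syntax chains are deterministic and silent syntax absorbs", {
  hm <- tmaze_model()
  Bs <- hm$level1$B$syntax[, , 1]
  expect_true(all(colSums(Bs == 1) == 1))   # deterministic chain
  expect_equal(Bs[1, 1], 1)                 # silent -> silent
  syn <- hm$level1$factors$syntax
  # query frame q1 -> q2 -> q3 -> q4 -> q4
  q <- match(paste0("q", 1:4), syn)
  expect_equal(Bs[q[2], q[1]], 1)
  expect_equal(Bs[q[4], q[4]], 1)
  # answer frame a1 ... a7 -> a7
  a <- match(paste0("a", 1:7), syn)
  for (i in 1:6) expect_equal(Bs[a[i + 1], a[i]], 1)
  expect_equal(Bs[a[7], a[7]], 1)
})

test_that("linguistic syntax attenuates the maze outcomes", {
  hm <- tmaze_model()
  m1 <- hm$level1
  d <- dim(m1$A$extero)
  # at any non-silent syntax state, every location/context maps to
  # centre + neutral
  for (syn in 2:12) for (loc in 1:4) for (ctx in 1:2) {
    states <- c(loc, ctx, 1, 1, 1, 1, syn)
    ext <- matrix(m1$A$extero, d[1])[, deepexplain:::flat_index(states, d[-1])]
    rew <- matrix(m1$A$reward, 3)[, deepexplain:::flat_index(states, d[-1])]
    expect_equal(ext, c(1, 0, 0, 0, 0))
    expect_equal(rew, c(1, 0, 0))
  }
})

test_that("semantic link rules cover every move/reward combination", {
  expect_equal(unname(semantic_link_table("cue", "right")),
               c("did-not-know", "explored", "cue"))
  expect_equal(unname(semantic_link_table("right", "right")),
               c("knew", "exploited", "right-arm"))
  expect_equal(unname(semantic_link_table("left", "right")),
               c("did-not-know", "guessed", "left-arm"))
  expect_equal(unname(semantic_link_table("centre", "left")),
               c("did-not-know", "waited", "centre"))
  expect_equal(unname(semantic_link_table("left-arm", "left")),
               c("knew", "exploited", "left-arm"))
  expect_error(semantic_link_table("corner", "left"))
})

test_that("task configuration rejects invalid values", {
  expect_error(task_config(pref_attractive = -1), "attractive")
  expect_error(task_config(link_smoothing = 0.7), "smoothing")
  expect_error(task_config(epochs = c("solve", "nap")), "epoch")
  expect_error(task_config(true_context = "up"))
})

test_that("slot tokens are disjoint from frame tokens", {
  v <- task_vocabulary()
  frames <- setdiff(c(v$frame_query, v$frame_answer),
                    grep("^<", c(v$frame_query, v$frame_answer), value = TRUE))
  slots <- unlist(v$slots)
  expect_length(intersect(frames, slots), 0L)
  expect_false(v$silence %in% c(frames, slots))
  expect_equal(anyDuplicated(v$tokens), 0L)
})

test_that("the maze environment follows the true physics", {
  hm <- tmaze_model()
  m1 <- hm$level1
  # true states: centre, context right, silent syntax
  s0 <- c(location = 1L, context = 2L, query = 1L, knowledge = 1L,
          verb = 1L, destination = 1L, syntax = 1L)
  # centre, action go-cue: cue location, neutral reward
  step <- environment_step(m1, s0, c(location = 4L))
  expect_equal(step$states[["location"]], 4L)
  expect_equal(step$observations[["reward"]], 1L)
  # at the cue in the reward-right context: cue observation indicates right
  expect_equal(m1$outcomes$extero[step$observations[["extero"]]], "cue-right")
  # arms absorb under every action
  at_left <- s0; at_left[["location"]] <- 2L
  for (a in 1:4) {
    expect_equal(environment_step(m1, at_left,
                                  c(location = a))$states[["location"]], 2L)
  }
})

test_that("the scripted task environment presents the query and echoes answers", {
  cfg <- task_config(query_type = "second")
  env <- build_environment(cfg)
  v <- task_vocabulary()$tokens
  # solve epoch: silence, no words heard
  env <- deepexplain:::begin_epoch(env, "solve")
  expect_equal(v[env_emit(env, 1)[["heard"]]], "silence")
  # query epoch: the four query-frame words in order
  env <- deepexplain:::begin_epoch(env, "query")
  heard <- vapply(1:4, function(t) v[env_emit(env, t)[["heard"]]], "")
  expect_equal(heard, c("please", "explain", "second", "move"))
  # answer epoch: the spoken token at t is observed at t
  env <- deepexplain:::begin_epoch(env, "answer")
  o <- env_emit(env, 1, spoken = match("knew", v))
  expect_equal(v[o[["heard"]]], "knew")
  expect_equal(v[o[["spoken"]]], "knew")
  # moves are not enacted outside the solve epoch
  env2 <- env_advance(env, c(location = 2L))
  expect_equal(env2$true_loc, 1L)
})

test_that("model tables round-trip bit-exactly through JSON", {
  hm <- tmaze_model()
  path <- tempfile(fileext = ".json")
  model_to_json(hm$level1, path)
  m2 <- model_from_json(path)
  for (mod in names(hm$level1$A)) {
    expect_identical(as.numeric(hm$level1$A[[mod]]), as.numeric(m2$A[[mod]]))
  }
  for (f in names(hm$level1$B)) {
    expect_identical(as.numeric(hm$level1$B[[f]]), as.numeric(m2$B[[f]]))
  }
  expect_identical(hm$level1$C, m2$C)
  expect_identical(lapply(hm$level1$D, as.numeric), m2$D)
  expect_identical(hm$level1$policies, m2$policies)
  expect_identical(hm$level1$factors, m2$factors)
  unlink(path)
})

test_that("expected free energy of the cue-first policy matches hand arithmetic", {
  hm <- tmaze_model()
  m1 <- hm$level1
  obs1 <- list(c(extero = 1L, reward = 1L, heard = 1L, spoken = 1L))
  # policy 9 is (go-cue, go-right)
  expect_equal(m1$policies[9, 1:2, 1], c(4L, 3L))
  res <- infer_states(m1, obs1, 9L)
  G <- expected_free_energy(m1, res$marginals, t_now = 1L)
  # independent arithmetic: softmax preferences, predicted outcomes from the
  # known deterministic structure, KL by direct summation (ambiguity is zero)
  kl <- function(p, q) sum(p[p > 0] * log(p[p > 0] / q[p > 0]))
  c_ext <- exp(c(-1, 0, 0, 0, 0)); c_ext <- c_ext / sum(c_ext)
  c_rew <- exp(c(0, 3, -6)); c_rew <- c_rew / sum(c_rew)
  c_word <- rep(1 / 21, 21)
  silence <- c(1, rep(0, 20))
  # step 2: at the cue, context still 50/50
  g2 <- kl(c(0, 0, 0, 0.5, 0.5), c_ext) + kl(c(1, 0, 0), c_rew) +
    2 * kl(silence, c_word)
  # step 3: in the right arm under a 50/50 context belief the reward is
  # attractive or aversive with equal probability
  g3 <- kl(c(0, 0, 1, 0, 0), c_ext) + kl(c(0, 0.5, 0.5), c_rew) +
    2 * kl(silence, c_word)
  expect_equal(G, g2 + g3, tolerance = 1e-6)
})

test_that("the first move under uncertainty is epistemic: go to the cue", {
  hm <- tmaze_model()
  m1 <- hm$level1
  obs1 <- list(c(extero = 1L, reward = 1L, heard = 1L, spoken = 1L))
  nP <- dim(m1$policies)[1]
  res <- lapply(seq_len(nP), function(p) infer_states(m1, obs1, p))
  Fv <- vapply(res, `[[`, 0, "F")
  Gv <- vapply(res, function(r) expected_free_energy(m1, r$marginals, 1L), 0)
  q_pi <- policy_posterior(rep(1, nP), Gv, Fv)
  a <- select_action(m1, q_pi, 1L)
  expect_equal(m1$actions$location[a[["location"]]], "go-cue")
})
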