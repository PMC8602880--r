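# Single-factor helper model with explicit tables.
chain_model <- function(A, B, D, horizon, n_a = dim(B)[3]) {
  n_s <- length(D)
  n_o <- nrow(A)
  steps <- horizon - 1L
  mdp_model(factors = list(x = paste0("s", seq_len(n_s))),
            controllable = TRUE,
            actions = list(x = paste0("a", seq_len(n_a))),
            A = list(o = array(A, dim = c(n_o, n_s))),
            B = list(x = B), C = list(o = rep(0, n_o)),
            D = list(x = D),
            policies = array(rep(1L, steps), dim = c(1L, steps, 1L)),
            E = 1, horizon = horizon, generated = character())
}

test_that("a single observation with a flat prior is plain Bayes", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), nrow = 2)   # obs x state
  B <- array(diag(2), dim = c(2, 2, 1))
  m <- chain_model(A, B, c(0.5, 0.5), horizon = 1L)
  res <- infer_states(m, list(c(o = 1L)), 1L)
  expect_equal(unname(res$marginals$x[, 1]), normalize(A[1, ]),
               tolerance = 1e-10)
})

test_that("uninformative likelihoods leave the prior rollout untouched", {
  set.seed(5)
  n_s <- 3; n_o <- 2; H <- 3
  A <- matrix(1 / n_o, n_o, n_s)   # every state predicts outcomes uniformly
  B <- array(0, dim = c(n_s, n_s, 1))
  for (s in seq_len(n_s)) B[, s, 1] <- normalize(stats::runif(n_s))
  D <- normalize(stats::runif(n_s))
  m <- chain_model(A, B, D, horizon = H)
  obs <- list(c(o = 1L), c(o = 2L), c(o = 1L))
  res <- infer_states(m, obs, 1L)
  expected <- cbind(D, B[, , 1] %*% D, B[, , 1] %*% B[, , 1] %*% D)
  expect_equal(unname(res$marginals$x), unname(expected), tolerance = 1e-10)
})

test_that("a hand-set two-state chain matches exact enumeration", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), nrow = 2)
  B <- array(c(0.9, 0.1, 0.2, 0.8), dim = c(2, 2, 1))
  D <- c(0.6, 0.4)
  m <- chain_model(A, B, D, horizon = 2L)
  obs <- c(1L, 2L)
  res <- infer_states(m, list(c(o = 1L), c(o = 2L)), 1L)
  oracle <- enum_posteriors(A, list(B[, , 1]), D, obs, 2L)
  expect_equal(unname(res$marginals$x), oracle, tolerance = 1e-6)
})

test_that("posteriors match brute-force enumeration on 100 random models", {
  for (seed in 1:100) {
    rm <- random_small_model(seed)
    m <- rm$model
    obs_list <- lapply(rm$obs, function(o) c(o = o))
    res <- infer_states(m, obs_list, 1L)
    B_seq <- if (rm$T_len > 1) {
      lapply(seq_len(rm$T_len - 1L), function(s) {
        matrix(m$B$x[, , m$policies[1, s, 1]], nrow = dim(m$B$x)[1])
      })
    } else list()
    A <- matrix(m$A$o, nrow = dim(m$A$o)[1])
    oracle <- enum_posteriors(A, B_seq, m$D$x, rm$obs, rm$T_len)
    expect_equal(unname(res$marginals$x), oracle, tolerance = 1e-6)
    # at the exact posterior, F is the negative log marginal likelihood
    paths <- as.matrix(expand.grid(rep(list(seq_along(m$D$x)), rm$T_len)))
    evid <- sum(apply(paths, 1, function(s) {
      p <- m$D$x[s[1]]
      if (rm$T_len > 1) for (tau in 2:rm$T_len) {
        p <- p * B_seq[[tau - 1]][s[tau], s[tau - 1]]
      }
      for (tau in seq_along(rm$obs)) p <- p * A[rm$obs[tau], s[tau]]
      p
    }))
    expect_equal(res$F, -log(evid), tolerance = 1e-5)
    expect_true(all(diff(res$F_trace) <= 1e-8))
  }
})

test_that("free energy is non-increasing across sweeps in coupled models", {
  set.seed(42)
  for (rep in 1:30) {
    sizes <- sample(2:3, 2, replace = TRUE)
    n_o <- sample(2:3, 1)
    H <- sample(2:3, 1)
    rcol <- function(n) normalize(stats::runif(n) + 0.05)
    A <- array(0, dim = c(n_o, sizes))
    for (j in seq_len(prod(sizes))) {
      idx <- arrayInd(j, sizes)
      A[, idx[1], idx[2]] <- rcol(n_o)
    }
    B <- lapply(sizes, function(n) {
      b <- array(0, dim = c(n, n, 1))
      for (s in seq_len(n)) b[, s, 1] <- rcol(n)
      b
    })
    m <- mdp_model(factors = list(x = paste0("x", seq_len(sizes[1])),
                                  y = paste0("y", seq_len(sizes[2]))),
                   controllable = c(FALSE, FALSE),
                   actions = list(),
                   A = list(o = A), B = list(x = B[[1]], y = B[[2]]),
                   C = list(o = rep(0, n_o)),
                   D = list(x = rcol(sizes[1]), y = rcol(sizes[2])),
                   policies = array(integer(0), dim = c(1L, H - 1L, 0L)),
                   E = 1, horizon = H, generated = character())
    obs <- lapply(seq_len(H), function(t) c(o = sample(seq_len(n_o), 1)))
    res <- suppressWarnings(infer_states(m, obs, 1L, tol = 0))
    expect_true(all(diff(res$F_trace) <= 1e-8))
  }
})

test_that("inference warns when stopped before convergence", {
  set.seed(9)
  A <- array(0, dim = c(2, 2, 2))
  for (j in 1:2) for (k in 1:2) A[, j, k] <- normalize(stats::runif(2) + 0.1)
  b <- array(c(0.7, 0.3, 0.4, 0.6), dim = c(2, 2, 1))
  m <- mdp_model(factors = list(x = c("x1", "x2"), y = c("y1", "y2")),
                 controllable = c(FALSE, FALSE), actions = list(),
                 A = list(o = A), B = list(x = b, y = b),
                 C = list(o = c(0, 0)),
                 D = list(x = c(0.5, 0.5), y = c(0.3, 0.7)),
                 policies = array(integer(0), dim = c(1L, 1L, 0L)),
                 E = 1, horizon = 2L, generated = character())
  expect_warning(infer_states(m, list(c(o = 1L)), 1L, max_iter = 1L),
                 "not converged")
})

test_that("ambiguity vanishes for deterministic likelihoods; G closed forms", {
  # deterministic likelihood: outcome entropy is zero in every state
  A <- array(0, dim = c(2, 2)); A[1, 1] <- 1; A[2, 2] <- 1
  B <- array(diag(2), dim = c(2, 2, 1))
  m <- chain_model(A, B, c(0.5, 0.5), horizon = 2L)
  expect_equal(max(abs(m$H_A$o)), 0)
  # uniform beliefs + identity likelihood predict uniform outcomes; flat
  # preferences make risk zero, so G = 0 exactly
  res <- infer_states(m, list(), 1L)
  expect_equal(expected_free_energy(m, res$marginals, t_now = 1L), 0,
               tolerance = 1e-9)
  # a stochastic likelihood contributes its expected entropy as ambiguity
  A2 <- matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2)
  m2 <- chain_model(A2, B, c(0.5, 0.5), horizon = 2L)
  res2 <- infer_states(m2, list(), 1L)
  h <- -(0.8 * log(0.8) + 0.2 * log(0.2))
  expect_equal(expected_free_energy(m2, res2$marginals, t_now = 1L), h,
               tolerance = 1e-6)
})

test_that("policy posterior combines bias, risk and evidence correctly", {
  G <- c(1, 2, 3)
  expect_equal(policy_posterior(rep(1, 3), G, rep(4, 3)), softmax(-G))
  # delta bias wins regardless of G and F
  expect_equal(policy_posterior(c(0, 1, 0), c(100, 0, -100), c(5, 5, 5)),
               c(0, 1, 0))
  # hand-set arithmetic
  E <- c(2, 1, 1); Gv <- c(0.5, 1, 0); Fv <- c(1, 0, 2)
  expect_equal(policy_posterior(E, Gv, Fv),
               softmax(log(E / 4) - Gv - Fv), tolerance = 1e-12)
  # invariance to constants added to G or F
  expect_equal(policy_posterior(E, Gv + 7, Fv), policy_posterior(E, Gv, Fv))
  expect_equal(policy_posterior(E, Gv, Fv - 3), policy_posterior(E, Gv, Fv))
  expect_error(policy_posterior(c(0, 0), c(1, 1)), "zero")
  expect_error(policy_posterior(c(1, 1), c(1, 1, 1)), "mismatch")
})

test_that("select_action marginalises the policy posterior", {
  m <- chain_model(matrix(c(1, 0, 0, 1), 2), array(diag(2), c(2, 2, 1)),
                   c(0.5, 0.5), horizon = 3L, n_a = 2)
  m$policies <- array(c(1L, 2L, 2L, 1L, 1L, 2L), dim = c(3, 2, 1))
  m$E <- rep(1, 3)
  # delta posterior: that policy's action
  expect_equal(unname(select_action(m, c(0, 1, 0), 1L)), 2L)
  expect_equal(unname(select_action(m, c(0, 1, 0), 2L)), 1L)
  # split posterior over two policies sharing the step-2 action
  expect_equal(unname(select_action(m, c(0.5, 0, 0.5), 2L)), 1L)
  # exact ties break to the lowest action index
  expect_equal(unname(select_action(m, c(0.5, 0.5, 0), 1L)), 1L)
})

test_that("reflexive outcomes maximise expected log-likelihood", {
  # delta beliefs, deterministic likelihood: the mapped word
  A <- array(0, dim = c(2, 2)); A[1, 1] <- 1; A[2, 2] <- 1
  m <- chain_model(A, array(diag(2), c(2, 2, 1)), c(0.5, 0.5), 2L)
  m$generated <- "o"
  expect_equal(unname(reflexive_outcome(list(x = c(0, 1)), m, "o")), 2L)
  # uniform beliefs, asymmetric likelihood: expected-log comparison by hand
  A2 <- matrix(c(0.9, 0.1, 0.6, 0.4), nrow = 2)  # w1 likelier in both states
  m2 <- chain_model(A2, array(diag(2), c(2, 2, 1)), c(0.5, 0.5), 2L)
  e1 <- 0.5 * log(0.9) + 0.5 * log(0.6)
  e2 <- 0.5 * log(0.1) + 0.5 * log(0.4)
  expect_true(e1 > e2)
  expect_equal(unname(reflexive_outcome(list(x = c(0.5, 0.5)), m2, "o")), 1L)
})
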