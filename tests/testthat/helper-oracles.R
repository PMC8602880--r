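# Independent oracles used to pin expected values.

# Exact smoothed posterior marginals of a single-factor POMDP chain by
# enumeration of every state path. A: n_obs x n_states likelihood matrix;
# B_seq: list of (T - 1) transition matrices (next x prev); D: prior;
# obs: integer outcome indices for steps 1..t (t <= T).
enum_posteriors <- function(A, B_seq, D, obs, T_len) {
  n <- length(D)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_len)))
  w <- apply(paths, 1, function(s) {
    p <- D[s[1]]
    if (T_len > 1) for (tau in 2:T_len) p <- p * B_seq[[tau - 1]][s[tau], s[tau - 1]]
    for (tau in seq_along(obs)) p <- p * A[obs[tau], s[tau]]
    p
  })
  w <- w / sum(w)
  q <- matrix(0, n, T_len)
  for (tau in seq_len(T_len)) {
    for (s in seq_len(n)) q[s, tau] <- sum(w[paths[, tau] == s])
  }
  q
}

# Brute-force expectation of a conditional table under factor marginals by
# summing over every parent tuple.
enum_expectation <- function(table, marginals) {
  d <- dim(table)
  grid <- as.matrix(expand.grid(lapply(d[-1], seq_len)))
  out <- rep(0, d[1])
  tm <- matrix(table, nrow = d[1])
  for (i in seq_len(nrow(grid))) {
    w <- prod(vapply(seq_along(marginals),
                     function(f) marginals[[f]][grid[i, f]], 0))
    col <- 1L
    mult <- 1L
    for (f in seq_along(marginals)) {
      col <- col + (grid[i, f] - 1L) * mult
      mult <- mult * d[f + 1L]
    }
    out <- out + w * tm[, col]
  }
  out
}

# Random single-factor model for oracle-equivalence checks.
random_small_model <- function(seed) {
  set.seed(seed)
  n_s <- sample(1:3, 1)
  n_o <- sample(1:3, 1)
  T_len <- sample(1:3, 1)
  n_a <- sample(1:2, 1)
  rcol <- function(n) normalize(stats::runif(n) + 0.05)
  A <- array(0, dim = c(n_o, n_s))
  for (s in seq_len(n_s)) A[, s] <- rcol(n_o)
  B <- array(0, dim = c(n_s, n_s, n_a))
  for (s in seq_len(n_s)) for (a in seq_len(n_a)) B[, s, a] <- rcol(n_s)
  D <- rcol(n_s)
  steps <- T_len - 1L
  pol <- array(sample(seq_len(n_a), steps, replace = TRUE),
               dim = c(1L, steps, 1L))
  m <- mdp_model(factors = list(x = paste0("s", seq_len(n_s))),
                 controllable = TRUE,
                 actions = list(x = paste0("a", seq_len(n_a))),
                 A = list(o = A), B = list(x = B),
                 C = list(o = rep(0, n_o)),
                 D = list(x = D),
                 policies = pol, E = 1, horizon = T_len,
                 generated = character())
  obs <- sample(seq_len(n_o), T_len, replace = TRUE)
  list(model = m, obs = obs, T_len = T_len)
}

# Cache for the expensive full simulations so several test files can share
# one run per configuration.
run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = run_cache)) {
    assign(key, force(expr), envir = run_cache)
  }
  get(key, envir = run_cache)
}

standard_run <- function(query = "second", context = "right") {
  cached(paste0("std_", query, "_", context),
         run_standard(query, context, seed = 1L))
}

confab_run <- function() cached("confab", run_confabulation(seed = 1L))

severed_run <- function() {
  cached("severed", run_standard("second", "right", seed = 1L,
                                 sever_bias = TRUE))
}

tmaze_model <- function() cached("hm", build_model(task_config()))
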