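# The T-maze-with-language task: level-1 maze + linguistic factors, outcome
# modalities with sensory attenuation, the 10-policy space, and the level-2
# narrative model with its semantic-prediction link.

LOCATIONS <- c("centre", "left", "right", "cue")
ARM_IDX <- c(2L, 3L)
CONTEXTS <- c("left", "right")
QUERIES <- c("first", "second")
KNOWLEDGE <- c("knew", "did-not-know")
# Ordered by increasing epistemic commitment: verbs compatible with not
# knowing the reward location come first, so data-unconstrained ties resolve
# to the explanation presuming least knowledge.
VERBS <- c("explored", "guessed", "exploited", "waited")
DESTINATIONS <- c("cue", "left-arm", "right-arm", "centre")
SYNTAX <- c("silent", paste0("q", 1:4), paste0("a", 1:7))
NARRATIVES <- c("solve", "query", "answer")

#' Task vocabulary
#'
#' Token lists for the query frame ("please explain <first|second> move"),
#' the answer frame ("I <knowledge> reward-was <side> so-I <verb>
#' <destination>") and the silence token. Slot tokens are disjoint from
#' frame tokens.
#'
#' @return List with `tokens` (all 21 tokens in outcome order), `frame_query`,
#'   `frame_answer`, `slots` (tokens per semantic slot) and `silence`.
#' @export
task_vocabulary <- function() {
  tokens <- c("silence",
              "please", "explain", "first", "second", "move",
              "I", "knew", "did-not-know", "reward-was", "left", "right",
              "so-I", VERBS,
              paste0("the-", DESTINATIONS))
  list(tokens = tokens,
       silence = "silence",
       frame_query = c("please", "explain", "<query>", "move"),
       frame_answer = c("I", "<knowledge>", "reward-was", "<side>",
                        "so-I", "<verb>", "<destination>"),
       slots = list(query = c("first", "second"),
                    knowledge = c("knew", "did-not-know"),
                    side = c("left", "right"),
                    verb = VERBS,
                    destination = paste0("the-", DESTINATIONS)))
}

#' Configuration of the T-maze explanation task
#'
#' @param true_context Arm holding the reward: `"left"` or `"right"`.
#' @param query_type Which move is queried: `"first"` or `"second"`.
#' @param epochs Narrative epochs to simulate; `c("solve", "query",
#'   "answer")` is the standard task, `c("query", "answer", "answer")` the
#'   confabulation variant (the maze-solving epoch never happens).
#' @param pref_attractive,pref_neutral,pref_aversive Log prior preferences
#'   for the three reward outcomes (must be ordered attractive > neutral >
#'   aversive).
#' @param pref_centre Log preference for the exteroceptive "centre" outcome
#'   (mildly aversive by default).
#' @param kappa Concentration of the context-sensitive policy bias: the
#'   prior weight of a policy is proportional to `exp(kappa * matches)`
#'   where `matches` counts agreement between the policy's two moves and the
#'   narrative-level move states.
#' @param link_smoothing Probability mass spread uniformly over non-predicted
#'   levels in each deterministic between-level link column. Keeps ascending
#'   evidence finite and grades a link violation by the cardinality of the
#'   violated slot.
#' @param horizons Named integer vector of level-1 steps per epoch type.
#' @param seed Integer seed for any stochastic tables (the shipped tables
#'   are deterministic).
#' @return List of class `"task_config"`.
#' @export
task_config <- function(true_context = "right", query_type = "second",
                        epochs = c("solve", "query", "answer"),
                        pref_attractive = 3, pref_neutral = 0,
                        pref_aversive = -6, pref_centre = -1,
                        kappa = 2, link_smoothing = 0.01,
                        horizons = c(solve = 3L, query = 4L, answer = 7L),
                        seed = 1L) {
  true_context <- match.arg(true_context, CONTEXTS)
  query_type <- match.arg(query_type, QUERIES)
  if (!all(epochs %in% NARRATIVES)) {
    stop("task_config: unknown epoch type", call. = FALSE)
  }
  if (!(pref_attractive > pref_neutral && pref_neutral > pref_aversive)) {
    stop("task_config: need attractive > neutral > aversive preference",
         call. = FALSE)
  }
  if (link_smoothing < 0 || link_smoothing >= 0.5) {
    stop("task_config: link_smoothing must be in [0, 0.5)", call. = FALSE)
  }
  if (any(horizons[unique(epochs)] < 3L)) {
    stop("task_config: every epoch needs >= 3 steps", call. = FALSE)
  }
  structure(list(true_context = true_context, query_type = query_type,
                 epochs = epochs, pref_attractive = pref_attractive,
                 pref_neutral = pref_neutral, pref_aversive = pref_aversive,
                 pref_centre = pref_centre, kappa = kappa,
                 link_smoothing = link_smoothing, horizons = horizons,
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Semantic explanation implied by a move and a reward location
#'
#' The narrative level treats the destination of the queried move, together
#' with the true reward arm, as determining the explanation: visiting the
#' cue means the agent explored because it did not know the reward location;
#' reaching the rewarded arm is taken as evidence the location was known
#' (exploited); reaching the unrewarded arm means an incorrect guess; and
#' staying in the centre means waiting.
#'
#' @param destination Move destination: `"centre"`, `"left"`, `"right"` or
#'   `"cue"` (the arm names `"left-arm"`/`"right-arm"` are also accepted).
#' @param reward Reward arm: `"left"` or `"right"`.
#' @return Named character vector with elements `knowledge`, `verb` and
#'   `destination` (the destination expressed as a semantic level).
#' @export
semantic_link_table <- function(destination, reward) {
  dest <- sub("-arm$", "", destination)
  dest <- match.arg(dest, LOCATIONS)
  reward <- match.arg(reward, CONTEXTS)
  if (dest == "cue") {
    out <- c(knowledge = "did-not-know", verb = "explored",
             destination = "cue")
  } else if (dest == "centre") {
    out <- c(knowledge = "did-not-know", verb = "waited",
             destination = "centre")
  } else if (dest == reward) {
    out <- c(knowledge = "knew", verb = "exploited",
             destination = paste0(dest, "-arm"))
  } else {
    out <- c(knowledge = "did-not-know", verb = "guessed",
             destination = paste0(dest, "-arm"))
  }
  out
}

# Word token index emitted for a syntax position and semantic levels.
# syn/qry/knw/ctx/vrb/dst are integer level indices.
word_index <- function(syn, qry, knw, ctx, vrb, dst) {
  # token offsets in task_vocabulary()$tokens
  ifelse(syn == 1L, 1L,                       # silence
  ifelse(syn == 2L, 2L,                       # please
  ifelse(syn == 3L, 3L,                       # explain
  ifelse(syn == 4L, 3L + qry,                 # first / second
  ifelse(syn == 5L, 6L,                       # move
  ifelse(syn == 6L, 7L,                       # I
  ifelse(syn == 7L, 7L + knw,                 # knew / did-not-know
  ifelse(syn == 8L, 10L,                      # reward-was
  ifelse(syn == 9L, 10L + ctx,                # left / right
  ifelse(syn == 10L, 13L,                     # so-I
  ifelse(syn == 11L, 13L + vrb,               # verb slot
         17L + dst)))))))))))                 # destination slot
}

# Delta column smoothed by alpha: 1 - alpha on idx, alpha/(n-1) elsewhere.
smooth_delta <- function(n, idx, alpha) {
  if (n == 1L) return(1)
  col <- rep(alpha / (n - 1L), n)
  col[idx] <- 1 - alpha
  col
}

build_level1 <- function(config) {
  factors <- list(location = LOCATIONS, context = CONTEXTS,
                  query = QUERIES, knowledge = KNOWLEDGE,
                  verb = VERBS, destination = DESTINATIONS,
                  syntax = SYNTAX)
  sizes <- vapply(factors, length, 1L)
  controllable <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  actions <- list(location = paste0("go-", LOCATIONS))
  vocab <- task_vocabulary()
  nw <- length(vocab$tokens)

  g <- expand.grid(loc = seq_len(4), ctx = seq_len(2), qry = seq_len(2),
                   knw = seq_len(2), vrb = seq_len(4), dst = seq_len(4),
                   syn = seq_len(12))
  N <- nrow(g)
  delta_A <- function(n_out, o_idx) {
    m <- matrix(0, n_out, N)
    m[cbind(o_idx, seq_len(N))] <- 1
    array(m, dim = c(n_out, sizes))
  }
  # exteroceptive: location identity while the maze is "live" (silent
  # syntax); the cue location reveals the context; any linguistic syntax
  # attenuates the mapping to a constant "centre" outcome.
  extero_o <- ifelse(g$syn != 1L, 1L,
              ifelse(g$loc == 1L, 1L,
              ifelse(g$loc == 2L, 2L,
              ifelse(g$loc == 3L, 3L,
              ifelse(g$ctx == 1L, 4L, 5L)))))
  # reward: attractive in the context arm, aversive in the other, neutral
  # elsewhere and whenever attenuated.
  reward_o <- ifelse(g$syn != 1L, 1L,
              ifelse(g$loc == 2L, ifelse(g$ctx == 1L, 2L, 3L),
              ifelse(g$loc == 3L, ifelse(g$ctx == 2L, 2L, 3L), 1L)))
  heard_o <- word_index(g$syn, g$qry, g$knw, g$ctx, g$vrb, g$dst)
  spoken_o <- ifelse(g$syn <= 5L, 1L, heard_o)

  A <- list(extero = delta_A(5L, extero_o),
            reward = delta_A(3L, reward_o),
            heard = delta_A(nw, heard_o),
            spoken = delta_A(nw, spoken_o))

  identity_B <- function(n) array(diag(n), dim = c(n, n, 1))
  B_loc <- array(0, dim = c(4, 4, 4))
  for (s in 1:4) for (a in 1:4) {
    B_loc[if (s %in% ARM_IDX) s else a, s, a] <- 1  # arms absorb
  }
  B_syn <- matrix(0, 12, 12)
  nxt <- c(1, 3, 4, 5, 5, 7, 8, 9, 10, 11, 12, 12)  # silent stays; frames
  B_syn[cbind(nxt, 1:12)] <- 1                      # chain then hold
  B <- list(location = B_loc, context = identity_B(2),
            query = identity_B(2), knowledge = identity_B(2),
            verb = identity_B(4), destination = identity_B(4),
            syntax = array(B_syn, dim = c(12, 12, 1)))

  C <- list(extero = c(config$pref_centre, 0, 0, 0, 0),
            reward = c(config$pref_neutral, config$pref_attractive,
                       config$pref_aversive),
            heard = rep(0, nw), spoken = rep(0, nw))

  D <- list(location = c(1, 0, 0, 0), context = c(0.5, 0.5),
            query = c(0.5, 0.5), knowledge = c(0.5, 0.5),
            verb = rep(0.25, 4), destination = rep(0.25, 4),
            syntax = c(1, rep(0, 11)))

  pol <- enumerate_policies()
  outcomes <- list(extero = c("centre", "left", "right", "cue-left",
                              "cue-right"),
                   reward = c("neutral", "attractive", "aversive"),
                   heard = vocab$tokens, spoken = vocab$tokens)
  mdp_model(factors, controllable, actions, A, B, C, D,
            policies = array(pol, dim = c(nrow(pol), 2, 1)),
            E = rep(1, nrow(pol)), horizon = 3L, outcomes = outcomes,
            generated = "spoken")
}

# All two-move location sequences from the centre that honour the absorbing
# arms: a first move into an arm forces the second move to stay there.
enumerate_policies <- function() {
  pol <- NULL
  for (a1 in 1:4) {
    seconds <- if (a1 %in% ARM_IDX) a1 else 1:4
    for (a2 in seconds) pol <- rbind(pol, c(a1, a2))
  }
  storage.mode(pol) <- "integer"
  pol
}

build_level2 <- function(config) {
  factors <- list(narrative = NARRATIVES, move1 = LOCATIONS,
                  move2 = LOCATIONS, reward_loc = CONTEXTS,
                  query_type = QUERIES)
  ident <- function(n) diag(n)
  B_narr <- matrix(0, 3, 3)
  B_narr[cbind(c(2, 3, 3), 1:3)] <- 1   # solve -> query -> answer (absorbs)
  B <- list(narrative = B_narr, move1 = ident(4), move2 = ident(4),
            reward_loc = ident(2), query_type = ident(2))
  start <- config$epochs[1]
  D <- list(narrative = as.numeric(NARRATIVES == start),
            move1 = rep(0.25, 4), move2 = rep(0.25, 4),
            reward_loc = c(0.5, 0.5), query_type = c(0.5, 0.5))
  list(factors = factors, B = B, D = D)
}

build_link <- function(config, level1) {
  alpha <- config$link_smoothing
  sizes2 <- c(3L, 4L, 4L, 2L, 2L)   # narrative, move1, move2, reward, query
  tuples <- expand.grid(narr = 1:3, m1 = 1:4, m2 = 1:4, rew = 1:2, qry = 1:2)
  n_tup <- nrow(tuples)
  link_for <- function(n1, col_fun) {
    m <- matrix(0, n1, n_tup)
    for (i in seq_len(n_tup)) m[, i] <- col_fun(tuples[i, ])
    array(m, dim = c(n1, sizes2))
  }
  sem <- function(tp) {
    move <- if (QUERIES[tp$qry] == "first") tp$m1 else tp$m2
    semantic_link_table(LOCATIONS[move], CONTEXTS[tp$rew])
  }
  states <- list(
    location = link_for(4L, function(tp) smooth_delta(4L, 1L, alpha)),
    context = link_for(2L, function(tp) smooth_delta(2L, tp$rew, alpha)),
    query = link_for(2L, function(tp) smooth_delta(2L, tp$qry, alpha)),
    knowledge = link_for(2L, function(tp) {
      if (NARRATIVES[tp$narr] != "answer") return(rep(0.5, 2))
      smooth_delta(2L, match(sem(tp)[["knowledge"]], KNOWLEDGE), alpha)
    }),
    verb = link_for(4L, function(tp) {
      if (NARRATIVES[tp$narr] != "answer") return(rep(0.25, 4))
      smooth_delta(4L, match(sem(tp)[["verb"]], VERBS), alpha)
    }),
    destination = link_for(4L, function(tp) {
      if (NARRATIVES[tp$narr] != "answer") return(rep(0.25, 4))
      smooth_delta(4L, match(sem(tp)[["destination"]], DESTINATIONS), alpha)
    }),
    syntax = link_for(12L, function(tp) {
      first <- c(solve = 1L, query = 2L, answer = 6L)[[NARRATIVES[tp$narr]]]
      smooth_delta(12L, first, alpha)
    })
  )
  # Context-sensitive policy bias: weight of policy pi given narrative move
  # states (g2, g3) is exp(kappa * [move1(pi) == g2] + kappa *
  # [move2(pi) == g3]), normalised over policies per (g2, g3).
  pol <- level1$policies[, 1:2, 1]
  nP <- nrow(pol)
  bias <- array(0, dim = c(nP, 4, 4))
  for (g2 in 1:4) for (g3 in 1:4) {
    w <- exp(config$kappa * ((pol[, 1] == g2) + (pol[, 2] == g3)))
    bias[, g2, g3] <- w / sum(w)
  }
  list(states = states, policy_bias = bias,
       bias_parents = c("move1", "move2"),
       factor_names = c("narrative", "move1", "move2", "reward_loc",
                        "query_type"))
}

#' Build the hierarchical T-maze-with-language model
#'
#' Constructs the full two-level generative model: a level-1 factorised
#' POMDP over maze states (location, context) and linguistic states
#' (query, knowledge, verb, destination, syntax) with four outcome
#' modalities (exteroceptive, reward, heard word, spoken word) and ten
#' two-move policies; a level-2 narrative model over epochs (solve the
#' maze, hear the query, answer) plus the two moves, the reward location
#' and the query type; and the between-level link that turns level-2
#' beliefs into level-1 empirical priors and a policy bias.
#'
#' @param config A [task_config()].
#' @return A list of class `"hier_model"` with elements `level1`
#'   ([mdp_model()] template), `level2`, `link`, `horizons`, `epochs` and
#'   `config`.
#' @export
build_model <- function(config = task_config()) {
  level1 <- build_level1(config)
  structure(list(level1 = level1, level2 = build_level2(config),
                 link = build_link(config, level1),
                 horizons = config$horizons, epochs = config$epochs,
                 config = config),
            class = "hier_model")
}

#' @export
print.hier_model <- function(x, ...) {
  cat("<hier_model: T-maze with language>\n")
  cat("  epochs:", paste(x$epochs, collapse = " -> "), "\n")
  cat("  level-2 factors:",
      paste(names(x$level2$factors), collapse = ", "), "\n")
  print(x$level1)
  invisible(x)
}

#' Build the T-maze task environment
#'
#' The generative process behind the simulations: it fixes the true reward
#' context, moves the agent through the maze only during maze-solving
#' epochs, presents the query sentence word by word during the query epoch,
#' and echoes the agent's own spoken words back as heard words during
#' answer epochs.
#'
#' @param config A [task_config()].
#' @return An environment of class `"tmaze_env"` for use with [run_trial()]
#'   and [run_hierarchy()].
#' @export
build_environment <- function(config = task_config()) {
  vocab <- task_vocabulary()
  tok <- function(x) match(x, vocab$tokens)
  query_words <- tok(c("please", "explain", QUERIES[match(config$query_type,
                                                          QUERIES)], "move"))
  structure(list(context = match(config$true_context, CONTEXTS),
                 query_words = query_words,
                 true_loc = 1L, epoch_type = config$epochs[1],
                 silence = 1L, vocab = vocab),
            class = "tmaze_env")
}

# Reset an environment at an epoch boundary: the agent is (back) at the
# centre and the epoch script changes.
begin_epoch <- function(env, type) {
  env$epoch_type <- type
  env$true_loc <- 1L
  env
}

#' @export
env_emit.tmaze_env <- function(env, t, spoken = NA_integer_) {
  solve <- env$epoch_type == "solve"
  loc <- env$true_loc
  extero <- if (!solve) 1L else
    if (loc == 1L) 1L else if (loc == 2L) 2L else if (loc == 3L) 3L else
      if (env$context == 1L) 4L else 5L
  reward <- if (!solve) 1L else
    if (loc == 2L) (if (env$context == 1L) 2L else 3L) else
    if (loc == 3L) (if (env$context == 2L) 2L else 3L) else 1L
  sp <- if (is.na(spoken)) env$silence else spoken
  heard <- switch(env$epoch_type,
                  solve = env$silence,
                  query = if (t <= length(env$query_words))
                    env$query_words[t] else env$silence,
                  answer = sp)
  c(extero = extero, reward = reward, heard = heard, spoken = sp)
}

#' @export
env_advance.tmaze_env <- function(env, action) {
  if (env$epoch_type == "solve") {
    a <- action[["location"]]
    env$true_loc <- if (env$true_loc %in% ARM_IDX) env$true_loc else a
  }
  env
}
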