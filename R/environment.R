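# Generative process: the environment side of a simulation. It mirrors the
# structure of a generative model (transition and likelihood tables) with the
# true hidden states fixed or propagated deterministically.

#' Advance the true states of a generative process and emit observations
#'
#' Propagates each hidden-state factor through its transition table under the
#' given action (deterministically: the most probable successor, which is the
#' unique successor for the delta tables used in the shipped task), then
#' draws one outcome per modality from the likelihood tables (again exact for
#' delta tables; sampled under the session RNG otherwise).
#'
#' @param process An [mdp_model()] (or structurally compatible list) whose
#'   `B` and `A` tables define the true dynamics and emissions.
#' @param true_states Named integer vector of current true levels per factor.
#' @param action Named integer vector of control levels per controllable
#'   factor (as returned by [select_action()]), or `NULL` for no action
#'   (all factors use control level 1).
#' @return List with `states` (next true states) and `observations` (named
#'   integer vector per modality).
#' @export
environment_step <- function(process, true_states, action = NULL) {
  nxt <- true_states
  for (f in names(process$factors)) {
    a <- 1L
    if (!is.null(action) && f %in% names(action)) a <- action[[f]]
    col <- process$B[[f]][, true_states[[f]], a]
    nxt[[f]] <- draw_level(col)
  }
  list(states = nxt, observations = emit_observations(process, nxt))
}

emit_observations <- function(process, true_states) {
  obs <- integer(length(process$A))
  names(obs) <- names(process$A)
  for (mod in names(process$A)) {
    d <- dim(process$A[[mod]])
    idx <- matrix(process$A[[mod]], nrow = d[1])[
      , flat_index(true_states, d[-1])]
    obs[[mod]] <- draw_level(idx)
  }
  obs
}

# Column index into a flattened (outcomes x prod(sizes)) table for a tuple
# of factor levels.
flat_index <- function(levels, sizes) {
  idx <- 1L
  mult <- 1L
  for (i in seq_along(sizes)) {
    idx <- idx + (levels[[i]] - 1L) * mult
    mult <- mult * sizes[[i]]
  }
  idx
}

# Deterministic for delta columns, sampled otherwise.
draw_level <- function(p) {
  if (max(p) >= 1 - PROB_TOL) which.max(p) else
    sample.int(length(p), 1L, prob = p)
}

# --- generic simulation-environment interface used by run_trial ------------

#' Observations emitted by an environment at a time step
#'
#' S3 generic; methods exist for plain generative-process environments
#' ([process_env()]) and the scripted T-maze task environment
#' ([build_environment()]).
#'
#' @param env Environment object.
#' @param t Time step within the current epoch.
#' @param spoken Outcome index the agent reflexively generates for its
#'   spoken modality at this step (or `NA`).
#' @return Named integer vector of outcome indices per modality.
#' @export
env_emit <- function(env, t, spoken = NA_integer_) UseMethod("env_emit")

#' Advance an environment by one action
#'
#' S3 generic companion to [env_emit()].
#'
#' @param env Environment object.
#' @param action Named integer vector per controllable factor.
#' @return The updated environment.
#' @export
env_advance <- function(env, action) UseMethod("env_advance")

#' Wrap a generative process as a simulation environment
#'
#' @param process An [mdp_model()] acting as the true generative process.
#' @param true_states Named integer vector of initial true levels.
#' @return An environment of class `"process_env"` for use with
#'   [run_trial()].
#' @export
process_env <- function(process, true_states) {
  structure(list(process = process, true = true_states),
            class = "process_env")
}

#' @export
env_emit.process_env <- function(env, t, spoken = NA_integer_) {
  obs <- emit_observations(env$process, env$true)
  for (g in env$process$generated) if (!is.na(spoken)) obs[[g]] <- spoken
  obs
}

#' @export
env_advance.process_env <- function(env, action) {
  env$true <- environment_step(env$process, env$true, action)$states
  env
}
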