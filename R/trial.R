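# One level-1 trial: the perception-action loop over a single epoch.

# Policy-averaged predictive marginals about time t: from the previous
# step's per-policy posteriors weighted by the previous policy posterior,
# or the initial priors at t = 1.
predictive_marginals <- function(model, prev, q_pi, t) {
  if (is.null(prev)) return(model$D)
  out <- lapply(names(model$factors), function(f) {
    acc <- 0
    for (p in seq_along(prev)) acc <- acc + q_pi[p] * prev[[p]]$marginals[[f]][, t]
    acc
  })
  names(out) <- names(model$factors)
  out
}

#' Run a single-level trial
#'
#' Executes the full perception-action loop of a flat (single-level) agent
#' over one epoch: at each time step the agent reflexively generates any
#' self-produced outcome from its predictive beliefs, receives observations
#' from the environment, infers per-policy state posteriors and free
#' energies, scores policies by expected free energy, forms the policy
#' posterior, and (except at the final step) selects and enacts an action.
#'
#' @param model An [mdp_model()] (its `D` and `E` act as the empirical
#'   priors for this trial).
#' @param env Environment implementing [env_emit()] and [env_advance()].
#' @param max_iter,tol Passed to [infer_states()].
#' @return A `"trial_record"`: list with `observations` (modality x time
#'   matrix of outcome indices), `actions` (control indices per step),
#'   `beliefs` (per step, policy-averaged marginals about that step),
#'   `q_pi` (policy posterior per step, policies x time), `F`, `G`
#'   (per-policy traces, policies x time), `final` (per-policy full
#'   posteriors from the last step), `q_pi_final`, `F_trace` (per-iteration
#'   free energy of the final inference per policy), and `env` (final
#'   environment state).
#' @export
run_trial <- function(model, env, max_iter = 16L, tol = 1e-4) {
  H <- model$horizon
  nP <- dim(model$policies)[1]
  obs <- vector("list", H)
  actions <- matrix(NA_integer_, nrow = max(H - 1L, 0L),
                    ncol = sum(model$controllable))
  colnames(actions) <- names(model$factors)[model$controllable]
  q_pi <- normalize(model$E)
  q_pi_mat <- matrix(0, nP, H)
  F_mat <- matrix(0, nP, H)
  G_mat <- matrix(0, nP, H)
  beliefs <- vector("list", H)
  prev <- NULL
  res <- NULL
  for (t in seq_len(H)) {
    sp <- NA_integer_
    if (length(model$generated)) {
      pred <- predictive_marginals(model, prev, q_pi, t)
      sp <- unname(reflexive_outcome(pred, model, model$generated[1]))
    }
    obs[[t]] <- env_emit(env, t, sp)
    res <- lapply(seq_len(nP), function(p) {
      infer_states(model, obs[seq_len(t)], p, priors = model$D,
                   max_iter = max_iter, tol = tol)
    })
    F_mat[, t] <- vapply(res, `[[`, 0, "F")
    G_mat[, t] <- vapply(res, function(r) {
      expected_free_energy(model, r$marginals, t)
    }, 0)
    q_pi <- policy_posterior(model$E, G_mat[, t], F_mat[, t])
    q_pi_mat[, t] <- q_pi
    beliefs[[t]] <- lapply(names(model$factors), function(f) {
      acc <- 0
      for (p in seq_len(nP)) acc <- acc + q_pi[p] * res[[p]]$marginals[[f]][, t]
      acc
    })
    names(beliefs[[t]]) <- names(model$factors)
    if (t < H) {
      a <- select_action(model, q_pi, t)
      actions[t, ] <- a
      env <- env_advance(env, a)
    }
    prev <- res
  }
  obs_mat <- do.call(cbind, obs)
  structure(
    list(observations = obs_mat, actions = actions, beliefs = beliefs,
         q_pi = q_pi_mat, F = F_mat, G = G_mat,
         final = res, q_pi_final = q_pi,
         F_trace = lapply(res, `[[`, "F_trace"),
         env = env),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  H <- ncol(x$observations)
  cat("<trial_record: ", H, " steps, ", nrow(x$q_pi), " policies>\n", sep = "")
  invisible(x)
}

#' Extend a model's planning horizon
#'
#' Returns a copy of the model with the given horizon; policies shorter than
#' `horizon - 1` steps are padded by repeating their final control level
#' (for the shipped T-maze this is a self-transition at the location
#' reached, so two-move policies remain well defined over longer epochs).
#'
#' @param model An [mdp_model()].
#' @param horizon New horizon (must be >= the model's policy length + 1).
#' @return An `"mdp_model"` with adjusted horizon and padded policies.
#' @export
extend_horizon <- function(model, horizon) {
  horizon <- as.integer(horizon)
  steps <- dim(model$policies)[2]
  if (horizon - 1L < steps) {
    stop("extend_horizon: horizon shorter than policy length", call. = FALSE)
  }
  pol <- model$policies
  if (horizon - 1L > steps) {
    pad <- pol[, rep(steps, horizon - 1L - steps), , drop = FALSE]
    newpol <- array(0L, dim = c(dim(pol)[1], horizon - 1L, dim(pol)[3]))
    newpol[, seq_len(steps), ] <- pol
    newpol[, (steps + 1L):(horizon - 1L), ] <- pad
    pol <- newpol
  }
  mdp_model(model$factors, model$controllable, model$actions, model$A,
            model$B, model$C, model$D, pol, model$E, horizon,
            outcomes = model$outcomes, generated = model$generated)
}
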