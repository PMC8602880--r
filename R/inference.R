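# Structured variational inference for a single-level factorised POMDP.
#
# Per policy, the approximate posterior factorises across hidden-state
# factors but keeps each factor's full temporal chain. Each factor update is
# an exact forward-backward pass given mean-field expectations of the other
# factors in the likelihood, so the scheme is exact for single-factor models
# and block-coordinate monotone in the variational free energy in general.

# Transition matrix applied to factor f entering time tau (tau >= 2) under
# policy matrix `pol` (steps x controllable factors).
step_B <- function(m, pol, f, tau) {
  ctrl <- names(m$factors)[m$controllable]
  i <- match(f, ctrl)
  a <- if (is.na(i)) 1L else pol[tau - 1L, i]
  m$B[[f]][, , a]
}

# Resolve a policy argument (index or matrix) to a steps x n_ctrl matrix.
resolve_policy <- function(m, policy) {
  if (length(policy) == 1L && is.numeric(policy)) {
    np <- dim(m$policies)[3]
    matrix(m$policies[policy, , ], ncol = np)
  } else {
    pol <- as.matrix(policy)
    storage.mode(pol) <- "integer"
    pol
  }
}

# Prior rollout of every factor chain under a policy (no evidence).
prior_rollout <- function(m, pol, priors) {
  H <- m$horizon
  lapply(names(m$factors), function(f) {
    q <- matrix(0, nrow = length(m$factors[[f]]), ncol = H)
    q[, 1] <- priors[[f]]
    if (H > 1) for (tau in 2:H) q[, tau] <- step_B(m, pol, f, tau) %*% q[, tau - 1]
    rownames(q) <- m$factors[[f]]
    q
  }) |> stats::setNames(names(m$factors))
}

# Log-likelihood message for factor f at time tau: the mean-field
# expectation over the other factors of ln P(o_tau | s), summed over
# observed modalities.
lik_message <- function(m, obs_tau, marg_tau, f_idx) {
  nf <- length(m$factors)
  msg <- rep(0, length(m$factors[[f_idx]]))
  for (mod in names(obs_tau)) {
    lnA <- m$lnA[[mod]]
    d <- dim(lnA)
    sl <- array(matrix(lnA, nrow = d[1])[obs_tau[[mod]], ], dim = d[-1])
    msg <- msg + if (nf == 1L) as.vector(sl) else
      contract_except(sl, marg_tau, f_idx)
  }
  msg
}

#' Infer hidden-state posteriors under a policy
#'
#' Runs structured variational inference for one policy: each hidden-state
#' factor's temporal chain is updated by an exact forward-backward pass given
#' the mean-field expectations of the other factors in the likelihood, and
#' factors are swept until the variational free energy converges. The
#' returned free energy is the divergence of the posterior from the
#' policy-conditioned prior minus the expected log-likelihood of the
#' observations (accumulated over all observed time steps).
#'
#' @param model An [mdp_model()].
#' @param observations List, one element per observed time step (from step 1
#'   up to the current step); each element is a named integer vector of
#'   outcome indices per modality. Modalities may be omitted (unobserved).
#' @param policy Policy index into `model$policies`, or an integer matrix
#'   `(horizon - 1) x n_controllable` of control-level indices.
#' @param priors Named list of initial-state priors per factor (defaults to
#'   `model$D`).
#' @param max_iter Maximum factor sweeps (default 16).
#' @param tol Convergence tolerance on the free-energy change per sweep.
#' @return List with elements `marginals` (per factor, a levels x horizon
#'   matrix of posterior marginals), `F` (the variational free energy),
#'   `F_trace` (free energy after each sweep; non-increasing),
#'   `converged`, and `pairwise` (per factor, consecutive-time joint
#'   distributions used in the free-energy computation).
#' @export
infer_states <- function(model, observations, policy, priors = model$D,
                         max_iter = 16L, tol = 1e-4) {
  m <- model
  pol <- resolve_policy(m, policy)
  H <- m$horizon
  t_obs <- length(observations)
  if (t_obs > H) stop("infer_states: more observations than horizon",
                      call. = FALSE)
  fac <- names(m$factors)
  nf <- length(fac)
  q <- prior_rollout(m, pol, priors)
  xi <- vector("list", nf); names(xi) <- fac

  fb_update <- function(f_i) {
    f <- fac[f_i]
    n <- length(m$factors[[f]])
    # likelihood messages (probability scale, per-column rescaled)
    L <- matrix(1, n, H)
    for (tau in seq_len(t_obs)) {
      marg_tau <- lapply(q, function(qq) qq[, tau])
      msg <- lik_message(m, observations[[tau]], marg_tau, f_i)
      L[, tau] <- exp(msg - max(msg))
    }
    alpha <- matrix(0, n, H); beta <- matrix(0, n, H)
    alpha[, 1] <- normalize(priors[[f]] * L[, 1])
    if (H > 1) for (tau in 2:H) {
      alpha[, tau] <- normalize(L[, tau] * (step_B(m, pol, f, tau) %*% alpha[, tau - 1]))
    }
    beta[, H] <- 1
    if (H > 1) for (tau in (H - 1):1) {
      beta[, tau] <- normalize(t(step_B(m, pol, f, tau + 1)) %*%
                                 (L[, tau + 1] * beta[, tau + 1]))
    }
    qf <- matrix(0, n, H)
    for (tau in 1:H) qf[, tau] <- normalize(alpha[, tau] * beta[, tau])
    rownames(qf) <- m$factors[[f]]
    xf <- vector("list", H)
    if (H > 1) for (tau in 2:H) {
      Bt <- step_B(m, pol, f, tau)
      # j[s_prev, s_next] = alpha[s_prev, tau-1] * B[s_next, s_prev] *
      #                     L[s_next, tau] * beta[s_next, tau]
      j <- t(Bt * (L[, tau] * beta[, tau])) * alpha[, tau - 1]
      xf[[tau]] <- j / sum(j)
    }
    list(q = qf, xi = xf)
  }

  free_energy <- function() {
    Fv <- 0
    for (f_i in seq_len(nf)) {
      f <- fac[f_i]
      q1 <- q[[f]][, 1]
      Fv <- Fv + sum(q1 * (log_guard(q1) - log_guard(priors[[f]])))
      if (H > 1) for (tau in 2:H) {
        j <- xi[[f]][[tau]]           # prev x next
        qprev <- q[[f]][, tau - 1]
        Bt <- step_B(m, pol, f, tau)  # next x prev
        Fv <- Fv + sum(j * (log_guard(j) - log_guard(qprev) - t(log_guard(Bt))))
      }
    }
    for (tau in seq_len(t_obs)) {
      marg_tau <- lapply(q, function(qq) qq[, tau])
      for (mod in names(observations[[tau]])) {
        lnA <- m$lnA[[mod]]
        d <- dim(lnA)
        sl <- array(matrix(lnA, nrow = d[1])[observations[[tau]][[mod]], ],
                    dim = d[-1])
        Fv <- Fv - if (nf == 1L) sum(sl * marg_tau[[1]]) else
          contract_all(sl, marg_tau)
      }
    }
    Fv
  }

  F_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (f_i in seq_len(nf)) {
      upd <- fb_update(f_i)
      q[[fac[f_i]]] <- upd$q
      xi[[fac[f_i]]] <- upd$xi
    }
    F_trace <- c(F_trace, free_energy())
    if (it > 1 && abs(F_trace[it] - F_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    if (nf == 1L && it == 1L) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("infer_states: free energy not converged after ", max_iter,
            " sweeps", call. = FALSE)
  }
  list(marginals = q, pairwise = xi, F = F_trace[length(F_trace)],
       F_trace = F_trace, converged = converged)
}

#' Expected free energy of a policy
#'
#' Scores a policy over its remaining (unobserved) time steps as risk plus
#' ambiguity: the divergence of the predicted outcome distribution from the
#' softmax-normalised prior preferences, plus the expected entropy of the
#' likelihood mapping, summed over future steps and modalities.
#'
#' @param model An [mdp_model()].
#' @param marginals Per-factor posterior marginals under the policy, as
#'   returned by [infer_states()] (`$marginals`).
#' @param t_now Current time step; steps `t_now + 1, ..., horizon` count as
#'   future.
#' @param preferences Named list of log-preference vectors per modality
#'   (defaults to `model$C`). Modalities without preferences are treated as
#'   flat.
#' @return Scalar expected free energy `G` (risk + ambiguity); the ambiguity
#'   component is always non-negative, and `G >= 0` whenever preferences are
#'   compared against predicted support.
#' @export
expected_free_energy <- function(model, marginals, t_now,
                                 preferences = model$C) {
  m <- model
  H <- m$horizon
  if (t_now >= H) return(0)
  G <- 0
  for (tau in (t_now + 1):H) {
    marg_tau <- lapply(marginals, function(qq) qq[, tau])
    for (mod in names(m$A)) {
      d <- dim(m$A[[mod]])
      qo <- as.vector(matrix(m$A[[mod]], nrow = d[1]) %*%
                        outer_product(marg_tau))
      Cm <- preferences[[mod]]
      if (is.null(Cm)) Cm <- rep(0, d[1])
      risk <- kl_divergence(qo, softmax(Cm))
      nf <- length(marg_tau)
      ambiguity <- if (nf == 1L) sum(m$H_A[[mod]] * marg_tau[[1]]) else
        contract_all(m$H_A[[mod]], marg_tau)
      G <- G + risk + ambiguity
    }
  }
  G
}

#' Posterior over policies
#'
#' Combines the prior policy bias `E`, the expected free energy `G` and the
#' accumulated variational free energy `F` of each policy into the policy
#' posterior `softmax(log E - G - F)`. Invariant to adding a constant to all
#' `G` (or all `F`) values; a zero bias weight excludes a policy exactly.
#'
#' @param bias Non-negative prior weight per policy (at least one positive).
#' @param G Numeric vector of expected free energies per policy.
#' @param F_val Numeric vector of variational free energies per policy
#'   (default 0).
#' @return Categorical vector over policies.
#' @export
policy_posterior <- function(bias, G, F_val = 0) {
  if (length(G) != length(bias) ||
      (length(F_val) > 1 && length(F_val) != length(bias))) {
    stop("policy_posterior: length mismatch", call. = FALSE)
  }
  e <- normalize(bias)   # errors on all-zero bias
  softmax(log(e) - G - F_val)
}

#' Select the action at a time step
#'
#' Marginalises the policy posterior over the action each policy prescribes
#' at step `t` and returns, per controllable factor, the most probable
#' control level (ties broken towards the lowest index).
#'
#' @param model An [mdp_model()].
#' @param q_pi Categorical vector over `model$policies`.
#' @param t Time step (action governs the transition from `t` to `t + 1`).
#' @return Named integer vector of control-level indices, one per
#'   controllable factor.
#' @export
select_action <- function(model, q_pi, t) {
  ctrl <- names(model$factors)[model$controllable]
  out <- integer(length(ctrl)); names(out) <- ctrl
  for (i in seq_along(ctrl)) {
    na <- length(model$actions[[ctrl[i]]])
    w <- vapply(seq_len(na), function(a) {
      sum(q_pi[model$policies[, t, i] == a])
    }, 0)
    out[i] <- which_max_tie(w)
  }
  out
}

#' Reflexively generate an outcome
#'
#' For an agent-generated modality (such as a spoken word), picks the
#' outcome level that maximises the expected log-likelihood under the
#' current factorised beliefs — the agent emits the observation it most
#' strongly predicts. Ties break towards the lowest index.
#'
#' @param marginals Named list of categorical beliefs, one per hidden-state
#'   factor (beliefs about the time step at which the outcome is emitted).
#' @param model An [mdp_model()].
#' @param modality Name of the generated modality.
#' @return Integer outcome index, named with the outcome label when the
#'   model carries outcome names.
#' @export
reflexive_outcome <- function(marginals, model, modality) {
  lnA <- model$lnA[[modality]]
  d <- dim(lnA)
  e <- as.vector(matrix(lnA, nrow = d[1]) %*% outer_product(marginals))
  idx <- which_max_tie(e)
  if (!is.null(model$outcomes[[modality]])) {
    names(idx) <- model$outcomes[[modality]][idx]
  }
  idx
}
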