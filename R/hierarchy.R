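# Two-level (deep temporal) composition: level-2 narrative states predict
# level-1 initial states and the policy bias; level-1 evidence updates
# level-2 beliefs once per epoch; level-2 beliefs propagate across epochs as
# empirical priors.

#' Descend level-2 beliefs into level-1 empirical priors
#'
#' Averages each between-level link table under the (factorised) level-2
#' posterior, producing an empirical initial-state prior for every level-1
#' factor and an empirical policy bias.
#'
#' @param level2_posterior Named list of categorical marginals, one per
#'   level-2 factor.
#' @param link Link object from [build_model()] (`$link`): per level-1
#'   factor a conditional table over level-2 tuples, plus a policy-bias
#'   table conditioned on the two move factors.
#' @return List with `D` (per level-1 factor, the empirical prior) and `E`
#'   (the empirical policy bias).
#' @export
descend <- function(level2_posterior, link) {
  q2 <- level2_posterior
  D <- lapply(link$states, function(tab) expect_over_factors(tab, q2))
  E <- expect_over_factors(link$policy_bias,
                           lapply(link$bias_parents, function(f) q2[[f]]))
  list(D = D, E = E)
}

#' Ascend level-1 evidence to the level-2 tuples
#'
#' Scores every level-2 factor tuple by how well its link predictions
#' explain the completed epoch: the expected log-probability of the
#' (policy-averaged) level-1 initial-state posteriors under each tuple's
#' state predictions, plus the expected log-probability of the final policy
#' posterior under the tuple's policy bias.
#'
#' @param level1_record A `"trial_record"` from [run_trial()].
#' @param link Link object from [build_model()].
#' @return Log-evidence array with one dimension per level-2 factor.
#' @export
ascend <- function(level1_record, link) {
  tr <- level1_record
  q_pi <- tr$q_pi_final
  sizes2 <- dim(link$states[[1]])[-1]
  ev <- array(0, dim = sizes2)
  for (f in names(link$states)) {
    qf <- 0
    for (p in seq_along(tr$final)) {
      qf <- qf + q_pi[p] * tr$final[[p]]$marginals[[f]][, 1]
    }
    tab <- link$states[[f]]
    n1 <- dim(tab)[1]
    ev <- ev + array(colSums(matrix(log_guard(tab), nrow = n1) * qf),
                     dim = sizes2)
  }
  nP <- dim(link$policy_bias)[1]
  ev_pol <- colSums(matrix(log_guard(link$policy_bias), nrow = nP) * q_pi)
  pos <- match(link$bias_parents, link$factor_names)
  other <- setdiff(seq_along(sizes2), pos)
  if (length(other) == 0L) {
    ev <- ev + array(ev_pol, dim = sizes2)
  } else {
    # broadcast the policy evidence over the non-parent level-2 dims
    full <- array(rep(ev_pol, times = prod(sizes2[other])),
                  dim = c(sizes2[pos], sizes2[other]))
    ev <- ev + aperm(full, order(c(pos, other)))
  }
  ev
}

#' Update level-2 beliefs from ascended evidence
#'
#' Combines the epoch's level-2 prior with the ascended log-evidence over
#' tuples and projects the joint posterior back onto per-factor marginals
#' (the mean-field representation used everywhere else at level 2).
#'
#' @param prior Named list of per-factor level-2 prior marginals.
#' @param log_evidence Log-evidence array from [ascend()].
#' @return List with `marginals` (named list per factor) and `joint` (the
#'   full posterior over tuples before projection).
#' @export
update_level2 <- function(prior, log_evidence) {
  sizes <- dim(log_evidence)
  lp <- log_guard(outer_product(prior)) + as.vector(log_evidence)
  joint <- array(softmax(lp), dim = sizes)
  marg <- lapply(seq_along(sizes), function(d) as.vector(apply(joint, d, sum)))
  names(marg) <- names(prior)
  for (f in names(prior)) names(marg[[f]]) <- names(prior[[f]])
  list(marginals = marg, joint = joint)
}

#' Propagate level-2 beliefs to the next epoch
#'
#' Pushes each level-2 factor through its transition table: the narrative
#' factor advances along solve -> query -> answer (answer absorbing), the
#' move, reward-location and query-type factors have identity dynamics and
#' are carried over unchanged.
#'
#' @param level2_posterior Named list of per-factor marginals.
#' @param transitions Named list of square transition matrices per factor.
#' @return Named list of prior marginals for the next epoch.
#' @export
advance_epoch <- function(level2_posterior, transitions) {
  out <- lapply(names(level2_posterior), function(f) {
    as.vector(transitions[[f]] %*% level2_posterior[[f]])
  })
  names(out) <- names(level2_posterior)
  out
}

#' Run the full two-level simulation
#'
#' For each epoch: descend level-2 beliefs into level-1 empirical priors and
#' a policy bias, run the level-1 trial to its horizon (with action
#' selection and environment stepping), ascend the epoch's evidence, update
#' the level-2 posterior, and advance it to the next epoch. Belief updating
#' across levels is asynchronous: level-2 beliefs change only at epoch
#' boundaries.
#'
#' @param hmodel A `"hier_model"` from [build_model()].
#' @param env Environment (defaults to [build_environment()] of the model's
#'   config).
#' @param epochs Character vector of epoch types (defaults to the config's).
#' @param seed Integer seed for any stochastic components.
#' @param sever_bias If `TRUE`, the descending policy bias is replaced by a
#'   uniform bias (a lesion of the between-level policy channel; negative
#'   control for replay).
#' @param max_iter,tol Passed to [infer_states()].
#' @return List of class `"hier_record"`; element `epochs` holds one record
#'   per epoch with the level-1 `"trial_record"`, the level-2 prior and
#'   posterior marginals, the posterior joint, the descended priors/bias and
#'   the epoch index at which the level-2 update happened.
#' @export
run_hierarchy <- function(hmodel, env = build_environment(hmodel$config),
                          epochs = hmodel$epochs,
                          seed = hmodel$config$seed,
                          sever_bias = FALSE,
                          max_iter = 16L, tol = 1e-4) {
  if (length(epochs) < 1L) stop("run_hierarchy: need >= 1 epoch",
                                call. = FALSE)
  if (!is.null(seed)) set.seed(seed %% .Machine$integer.max)
  q2 <- hmodel$level2$D
  records <- vector("list", length(epochs))
  for (e in seq_along(epochs)) {
    type <- epochs[e]
    if (inherits(env, "tmaze_env")) env <- begin_epoch(env, type)
    dn <- descend(q2, hmodel$link)
    if (sever_bias) dn$E <- rep(1 / length(dn$E), length(dn$E))
    H <- if (!is.null(hmodel$horizons) && type %in% names(hmodel$horizons))
      hmodel$horizons[[type]] else hmodel$level1$horizon
    m1 <- extend_horizon(hmodel$level1, H)
    m1$D <- dn$D
    m1$E <- dn$E
    tr <- run_trial(m1, env, max_iter = max_iter, tol = tol)
    env <- tr$env
    ev <- ascend(tr, hmodel$link)
    upd <- update_level2(q2, ev)
    records[[e]] <- list(epoch = e, type = type, trial = tr,
                         level2_prior = q2,
                         level2_posterior = upd$marginals,
                         level2_joint = upd$joint,
                         descended = dn,
                         level2_updated_at = e)
    q2 <- advance_epoch(upd$marginals, hmodel$level2$B)
  }
  structure(list(epochs = records, model = hmodel), class = "hier_record")
}

#' @export
print.hier_record <- function(x, ...) {
  cat("<hier_record: ", length(x$epochs), " epochs (",
      paste(vapply(x$epochs, `[[`, "", "type"), collapse = ", "), ")>\n",
      sep = "")
  invisible(x)
}
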