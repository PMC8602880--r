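#' Construct a single-level factorised POMDP model
#'
#' Bundles the components of a discrete-state partially observed Markov
#' decision process with factorised hidden states: per-modality likelihood
#' tables, per-factor action-conditioned transition tables, log prior
#' preferences over outcomes, initial-state priors, an allowable policy set
#' and a prior policy bias.
#'
#' @param factors Named list; one character vector of level names per hidden
#'   state factor.
#' @param controllable Logical vector, one entry per factor (recycled names
#'   checked against `factors`).
#' @param actions Named list; for each controllable factor, a character
#'   vector of action (control level) names. Uncontrollable factors have a
#'   single implicit "static" control level.
#' @param A Named list of likelihood arrays, one per outcome modality; each
#'   has dim `c(n_outcomes, <factor sizes in factor order>)` and is
#'   column-stochastic over outcomes.
#' @param B Named list of transition arrays, one per factor; each has dim
#'   `c(n_levels, n_levels, n_controls)` (next state x previous state x
#'   control) and is column-stochastic over next states.
#' @param C Named list of numeric log-preference vectors, one per modality
#'   (finite entries; only differences matter).
#' @param D Named list of categorical initial priors, one per factor.
#' @param policies Integer array `c(n_policies, horizon - 1, n_controllable)`
#'   of control-level indices; the allowable policy set.
#' @param E Non-negative numeric vector of prior policy weights (at least one
#'   positive).
#' @param horizon Integer number of time steps in a trial.
#' @param outcomes Named list of outcome level names per modality.
#' @param generated Character vector of modalities generated reflexively by
#'   the agent itself (e.g. a spoken word) rather than by the environment.
#' @return A list of class `"mdp_model"`.
#' @seealso [infer_states()], [expected_free_energy()], [run_trial()]
#' @export
mdp_model <- function(factors, controllable, actions, A, B, C, D,
                      policies, E, horizon, outcomes = NULL,
                      generated = character()) {
  m <- structure(
    list(factors = factors, controllable = controllable, actions = actions,
         A = A, B = B, C = C, D = D, policies = policies, E = E,
         horizon = as.integer(horizon), outcomes = outcomes,
         generated = generated),
    class = "mdp_model")
  validate_mdp_model(m)
  # Cache guarded log-likelihoods and per-state outcome entropies: these are
  # reused in every inference sweep and every expected-free-energy call.
  m$lnA <- lapply(m$A, log_guard)
  m$H_A <- lapply(m$A, function(a) {
    d <- dim(a)
    h <- -colSums(matrix(a, nrow = d[1]) * matrix(log_guard(a), nrow = d[1]))
    array(h, dim = d[-1])
  })
  m
}

#' Validate an mdp_model
#'
#' Checks factor/modality shape consistency, column-stochasticity of all
#' tables, policy index ranges and the policy-bias positivity invariant.
#'
#' @param m An `"mdp_model"`.
#' @return `m`, invisibly, if valid.
#' @export
validate_mdp_model <- function(m) {
  nf <- length(m$factors)
  sizes <- vapply(m$factors, length, 1L)
  if (is.null(names(m$factors)) || anyDuplicated(names(m$factors))) {
    stop("mdp_model: factors must have unique names", call. = FALSE)
  }
  if (length(m$controllable) != nf) {
    stop("mdp_model: controllable flag per factor required", call. = FALSE)
  }
  for (mod in names(m$A)) {
    d <- dim(m$A[[mod]])
    if (length(d) != nf + 1L || !all(d[-1] == sizes)) {
      stop("mdp_model: likelihood '", mod, "' has wrong parent dims",
           call. = FALSE)
    }
    validate_cond_table(m$A[[mod]])
  }
  for (f in names(m$factors)) {
    d <- dim(m$B[[f]])
    if (length(d) != 3L || d[1] != sizes[[f]] || d[2] != sizes[[f]]) {
      stop("mdp_model: transition for factor '", f, "' must be ",
           "next x prev x control", call. = FALSE)
    }
    cs <- colSums(matrix(m$B[[f]], nrow = d[1]))
    if (any(abs(cs - 1) > PROB_TOL) || any(m$B[[f]] < -PROB_TOL)) {
      stop("mdp_model: transition for factor '", f,
           "' is not column-stochastic", call. = FALSE)
    }
  }
  for (f in names(m$factors)) validate_categorical(m$D[[f]])
  for (mod in names(m$C)) {
    if (any(!is.finite(m$C[[mod]]))) {
      stop("mdp_model: preferences must be finite", call. = FALSE)
    }
  }
  dp <- dim(m$policies)
  if (length(dp) != 3L || dp[2] != m$horizon - 1L) {
    stop("mdp_model: policies must be n_policies x (horizon - 1) x ",
         "n_controllable", call. = FALSE)
  }
  ctrl <- names(m$factors)[m$controllable]
  if (dp[3] != length(ctrl)) {
    stop("mdp_model: one policy column block per controllable factor",
         call. = FALSE)
  }
  for (i in seq_along(ctrl)) {
    na <- length(m$actions[[ctrl[i]]])
    if (any(m$policies[, , i] < 1L) || any(m$policies[, , i] > na)) {
      stop("mdp_model: policy action index out of range", call. = FALSE)
    }
  }
  if (length(m$E) != dp[1] || all(m$E <= 0) || any(m$E < 0)) {
    stop("mdp_model: policy bias E needs >= 1 positive weight and none ",
         "negative", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.mdp_model <- function(x, ...) {
  cat("<mdp_model>\n")
  cat("  factors:   ",
      paste(sprintf("%s(%d%s)", names(x$factors),
                    vapply(x$factors, length, 1L),
                    ifelse(x$controllable, "*", "")),
            collapse = ", "),
      "  [* = controllable]\n", sep = "")
  cat("  modalities:",
      paste(sprintf("%s(%d)", names(x$A), vapply(x$A, function(a) dim(a)[1], 1L)),
            collapse = ", "), "\n")
  cat("  policies:  ", dim(x$policies)[1], " over horizon ", x$horizon, "\n",
      sep = "")
  invisible(x)
}

# Control-level indices applied to factor f at step `step` under policy `p`
# (an index into m$policies). Uncontrollable factors always use control 1.
policy_action <- function(m, p, step, factor) {
  ctrl <- names(m$factors)[m$controllable]
  i <- match(factor, ctrl)
  if (is.na(i)) return(1L)
  m$policies[p, step, i]
}

#' Serialize an mdp_model to JSON
#'
#' Writes every table (factors, actions, likelihoods, transitions,
#' preferences, priors, policies, bias, horizon) as a plain-text JSON
#' structure with full double precision, so that [model_from_json()]
#' reconstructs a bit-exact copy.
#'
#' @param m An `"mdp_model"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
model_to_json <- function(m, path = NULL) {
  spec <- list(
    factors = m$factors,
    controllable = as.logical(m$controllable),
    actions = m$actions,
    outcomes = m$outcomes,
    A = lapply(m$A, unclass_array),
    B = lapply(m$B, unclass_array),
    C = m$C,
    D = m$D,
    policies = unclass_array(m$policies),
    E = as.numeric(m$E),
    horizon = m$horizon,
    generated = m$generated
  )
  js <- jsonlite::toJSON(spec, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

unclass_array <- function(a) {
  list(dim = dim(a), data = as.numeric(a))
}

reclass_array <- function(l) {
  array(as.numeric(l$data), dim = as.integer(l$dim))
}

#' Read an mdp_model from JSON
#'
#' Inverse of [model_to_json()].
#'
#' @param path File path or JSON string.
#' @return An `"mdp_model"`.
#' @export
model_from_json <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_chr_list <- function(x) lapply(x, as.character)
  mdp_model(
    factors = as_chr_list(s$factors),
    controllable = as.logical(s$controllable),
    actions = as_chr_list(s$actions),
    A = lapply(s$A, reclass_array),
    B = lapply(s$B, reclass_array),
    C = lapply(s$C, as.numeric),
    D = lapply(s$D, as.numeric),
    policies = array(as.integer(s$policies$data),
                     dim = as.integer(s$policies$dim)),
    E = as.numeric(s$E),
    horizon = s$horizon,
    outcomes = if (!is.null(s$outcomes)) as_chr_list(s$outcomes),
    generated = as.character(s$generated)
  )
}
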