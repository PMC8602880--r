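#' @keywords internal
"_PACKAGE"

# Guard added inside every logarithm so that structural zeros yield large
# finite penalties instead of -Inf (standard practice in discrete
# active-inference implementations).
LOG_EPS <- 1e-16

# Tolerance for probability-sum invariants on construction.
PROB_TOL <- 1e-10

#' Guarded natural logarithm
#'
#' Computes `log(x + 1e-16)`, the epsilon-guarded logarithm used throughout
#' the package so that Kullback-Leibler divergences and log-likelihoods stay
#' finite in the presence of structural zeros.
#'
#' @param x Numeric vector or array of non-negative values.
#' @return `log(x + 1e-16)`, same shape as `x`.
#' @export
log_guard <- function(x) log(x + LOG_EPS)

#' Construct a categorical distribution
#'
#' A categorical distribution is a non-negative numeric vector summing to
#' one, optionally carrying level names. All posterior and prior marginals in
#' the package are categoricals.
#'
#' @param probs Non-negative numeric vector summing to 1 (within `1e-10`).
#' @param labels Optional character vector of level names.
#' @return A numeric vector of class `"categorical"`.
#' @examples
#' categorical(c(0.25, 0.75), c("left", "right"))
#' @export
categorical <- function(probs, labels = names(probs)) {
  probs <- as.numeric(probs)
  if (!is.null(labels)) names(probs) <- labels
  validate_categorical(probs)
  structure(probs, class = "categorical")
}

#' Validate a categorical distribution
#'
#' Checks non-negativity and that the entries sum to one within `1e-10`.
#'
#' @param p Numeric vector.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_categorical <- function(p) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("categorical: need a non-empty numeric vector", call. = FALSE)
  }
  if (any(p < -PROB_TOL)) {
    stop("categorical: negative probability entries", call. = FALSE)
  }
  if (abs(sum(p) - 1) > PROB_TOL) {
    stop("categorical: entries must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.categorical <- function(x, ...) {
  cat("<categorical over", length(x), "levels>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Normalize non-negative weights to a categorical distribution
#'
#' @param weights Non-negative numeric vector with at least one positive
#'   entry.
#' @return Numeric vector proportional to `weights` and summing to 1.
#' @examples
#' normalize(c(1, 3)) # 0.25 0.75
#' @export
normalize <- function(weights) {
  if (any(weights < 0)) stop("normalize: negative weights", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("normalize: all weights are zero", call. = FALSE)
  weights / s
}

#' Softmax of log-weights
#'
#' Exponentiates and normalizes a vector of log-weights. Invariant to adding
#' a constant to all entries; `-Inf` entries denote excluded options.
#'
#' @param log_weights Numeric vector; `-Inf` allowed, `NaN`/`NA` not.
#' @return Categorical probability vector.
#' @examples
#' softmax(c(log(1), log(3))) # 0.25 0.75
#' @export
softmax <- function(log_weights) {
  if (any(is.na(log_weights)) || any(log_weights == Inf)) {
    stop("softmax: entries must be finite or -Inf", call. = FALSE)
  }
  m <- max(log_weights)
  if (m == -Inf) stop("softmax: all entries are -Inf", call. = FALSE)
  w <- exp(log_weights - m)
  w / sum(w)
}

#' Kullback-Leibler divergence between categorical distributions
#'
#' Computes `sum(p * (log(p) - log(q)))` with epsilon-guarded logarithms, so
#' the divergence is finite even where `q` has structural zeros.
#'
#' @param p,q Categorical probability vectors of equal length.
#' @return Non-negative scalar; zero iff `p == q`.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("kl_divergence: length mismatch", call. = FALSE)
  }
  sum(p * (log_guard(p) - log_guard(q)))
}

#' Shannon entropy of a categorical distribution
#'
#' `-sum(p * log(p))` in nats, with the `0 * log(0) = 0` convention.
#'
#' @param p Categorical probability vector.
#' @return Non-negative scalar.
#' @examples
#' entropy(rep(0.25, 4)) # log(4)
#' @export
entropy <- function(p) {
  -sum(p * log_guard(p))
}

#' Construct a conditional probability table
#'
#' Stores the probability of each outcome level conditioned on a tuple of
#' parent-variable levels, as an array whose first dimension indexes
#' outcomes and remaining dimensions index parents. Every conditional slice
#' (outcome distribution for a fixed parent tuple) must be a valid
#' categorical.
#'
#' @param table Numeric array; `dim(table)[1]` is the number of outcome
#'   levels, remaining dimensions are parent factor sizes.
#' @param outcomes Optional character vector of outcome level names.
#' @param parents Optional named list of parent level names (one character
#'   vector per parent, in dimension order).
#' @return The array with class `"cond_table"` and attributes `outcomes`
#'   and `parents`.
#' @export
cond_table <- function(table, outcomes = NULL, parents = NULL) {
  if (is.null(dim(table))) dim(table) <- c(length(table), 1L)
  tab <- structure(as.array(table), class = "cond_table",
                   outcomes = outcomes, parents = parents)
  validate_cond_table(tab)
  tab
}

#' Validate a conditional probability table
#'
#' Checks that, for every parent tuple, the outcome probabilities are
#' non-negative and sum to one within `1e-10`.
#'
#' @param tab Array as produced by [cond_table()].
#' @return `tab`, invisibly, if valid.
#' @export
validate_cond_table <- function(tab) {
  d <- dim(tab)
  m <- matrix(tab, nrow = d[1])
  if (any(m < -PROB_TOL)) {
    stop("cond_table: negative entries", call. = FALSE)
  }
  s <- colSums(m)
  if (any(abs(s - 1) > PROB_TOL)) {
    stop("cond_table: conditional distributions must sum to 1", call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.cond_table <- function(x, ...) {
  d <- dim(x)
  cat("<cond_table: ", d[1], " outcomes | parents [",
      paste(d[-1], collapse = " x "), "]>\n", sep = "")
  invisible(x)
}

#' Expected outcome distribution under factorised parent marginals
#'
#' Averages a conditional table under the product of per-parent categorical
#' marginals: the mean-field expectation of the outcome distribution.
#'
#' @param table A [cond_table()] (or plain array, outcomes first).
#' @param marginals List with one categorical vector per parent factor, in
#'   the table's parent dimension order.
#' @return Categorical vector over outcome levels.
#' @export
expect_over_factors <- function(table, marginals) {
  d <- dim(table)
  np <- length(d) - 1L
  if (length(marginals) != np) {
    stop("expect_over_factors: need one marginal per parent factor",
         call. = FALSE)
  }
  for (i in seq_len(np)) {
    if (length(marginals[[i]]) != d[i + 1L]) {
      stop("expect_over_factors: marginal ", i, " has length ",
           length(marginals[[i]]), ", expected ", d[i + 1L], call. = FALSE)
    }
  }
  w <- outer_product(marginals)
  out <- as.vector(matrix(table, nrow = d[1]) %*% w)
  names(out) <- attr(table, "outcomes")
  out
}

# Flattened outer product of a list of vectors, in dimension order
# (first vector varies fastest, matching R array layout).
outer_product <- function(vs) {
  as.vector(Reduce(outer, vs))
}

# Sum over all dimensions of `arr` except `keep`, weighting each remaining
# dimension d by marginals[[d]]:
#   result(s_keep) = sum_{others} arr[...] * prod_{f != keep} marg[[f]][s_f]
contract_except <- function(arr, marginals, keep) {
  ms <- marginals
  ms[[keep]] <- rep(1, dim(arr)[keep])
  w <- array(outer_product(ms), dim = dim(arr))
  apply(arr * w, keep, sum)
}

# Full contraction: E over all factor marginals of `arr`.
contract_all <- function(arr, marginals) {
  sum(arr * array(outer_product(marginals), dim = dim(arr)))
}

# Index of the maximum with ties (within an absolute tolerance band, so that
# exact mathematical ties are not resolved by floating-point accumulation
# noise) broken towards the lowest index.
which_max_tie <- function(x, tol = 1e-9) {
  which(x >= max(x) - tol)[1]
}
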