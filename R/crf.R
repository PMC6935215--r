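# Linear-chain CRF on top of the emission score matrix P: path scoring,
# log-partition via the forward recursion, NLL, Viterbi decoding.
#
# Conventions: P is n x |L| (one row per token); T is (|L|+2) x (|L|+2) over
# the label set in its documented order with the start tag at index |L|+1
# and the end tag at index |L|+2. Transitions into start and out of end are
# -Inf masks. Label sequences are 1-based indices into the label order.

.check_PT <- function(P, T) {
  stopifnot(is.matrix(P), is.matrix(T))
  L <- ncol(P)
  if (nrow(T) != L + 2L || ncol(T) != L + 2L)
    stop("T must be (|L|+2) x (|L|+2) with start and end tags appended")
  if (nrow(P) < 1L) stop("at least one position is required")
  invisible(L)
}

#' Build a transition matrix skeleton
#'
#' Returns a zero transition matrix over `n_labels` labels plus start and
#' end tags, with the structurally impossible entries (into start, out of
#' end) masked to `-Inf`.
#'
#' @param n_labels Number of real labels.
#' @return A `(n_labels+2) x (n_labels+2)` matrix.
#' @export
transition_matrix <- function(n_labels) {
  L <- as.integer(n_labels)
  T <- matrix(0, L + 2L, L + 2L)
  T[, L + 1L] <- -Inf   # nothing transitions into start
  T[L + 2L, ] <- -Inf   # nothing transitions out of end
  T
}

#' Score of one label path
#'
#' The sentence score is the sum of the transition scores along the path
#' (including start -> y_1 and y_n -> end) plus the emission scores
#' `P[i, y_i]`.
#'
#' @param P Emission score matrix, `n x |L|`.
#' @param T Transition matrix, `(|L|+2) x (|L|+2)`.
#' @param y Integer label sequence (1-based), length `n`.
#' @return The path score (a scalar).
#' @export
path_score <- function(P, T, y) {
  L <- .check_PT(P, T)
  y <- as.integer(y)
  if (length(y) != nrow(P)) stop("label sequence length must match nrow(P)")
  if (any(y < 1L | y > L)) stop("label index out of range")
  cpp_crf_path_score(P, T, y)
}

#' Log-partition function of the CRF
#'
#' `log` of the sum over all `|L|^n` label sequences of `exp(path_score)`,
#' computed by the forward recursion in log space (log-sum-exp, safe against
#' overflow).
#'
#' @inheritParams path_score
#' @return `log Z(x)`.
#' @export
log_partition <- function(P, T) {
  .check_PT(P, T)
  cpp_crf_logZ(P, T)
}

#' Negative log-likelihood of a gold path
#'
#' `log Z - path_score`; non-negative, and zero only in the degenerate limit
#' where the gold path carries all probability mass.
#'
#' @inheritParams path_score
#' @param y_gold Gold label sequence (1-based).
#' @return The NLL (a scalar `>= 0` up to floating-point rounding).
#' @export
nll_loss <- function(P, T, y_gold) {
  log_partition(P, T) - path_score(P, T, y_gold)
}

#' Viterbi decoding
#'
#' Returns the label sequence maximizing [path_score()] and its score. Ties
#' are broken deterministically toward the lowest label index at the latest
#' differing position.
#'
#' @inheritParams path_score
#' @return A list with `path` (integer labels, 1-based) and `score`.
#' @export
viterbi_decode <- function(P, T) {
  .check_PT(P, T)
  out <- cpp_crf_viterbi(P, T)
  out$path <- as.integer(out$path)
  out
}

#' Conditional probability of a label sequence
#'
#' `exp(path_score - log_partition)`; over all sequences these sum to one.
#'
#' @inheritParams nll_loss
#' @param y Label sequence (1-based).
#' @return A probability in `(0, 1)`.
#' @export
sequence_probability <- function(P, T, y) {
  exp(path_score(P, T, y) - log_partition(P, T))
}

# Posterior marginals p(y_t = j | x); used in training via the gradient
# logZ' = marginals - gold indicators.
crf_marginals <- function(P, T) {
  .check_PT(P, T)
  cpp_crf_marginals(P, T)
}

# Hard IOB-constraint mask: -Inf on transitions that IOB forbids
# (start -> I-x, O -> I-x, B-x/I-x -> I-y for y != x). Applied at decode
# time when requested; off by default since the CRF learns transitions.
iob_constraint_mask <- function(labels) {
  L <- length(labels)
  T <- matrix(0, L + 2L, L + 2L)
  pre <- substr(labels, 1L, 1L)
  typ <- ifelse(pre == "O", "", substr(labels, 3L, nchar(labels)))
  for (j in seq_len(L)) {
    if (pre[j] != "I") next
    T[L + 1L, j] <- -Inf                     # start -> I
    for (i in seq_len(L)) {
      ok <- pre[i] %in% c("B", "I") && typ[i] == typ[j]
      if (!ok) T[i, j] <- -Inf
    }
  }
  T
}
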