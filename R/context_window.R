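# N-gram extraction and the contextual window concatenation that
# distinguishes the contextual LSTM from a plain BiLSTM: each position's
# input becomes the ordered concatenation of the embeddings of its d
# neighbors (d odd), after padding both ends with floor(d/2) padding vectors.

.check_window <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 1)
    stop("window size must be a positive integer")
  d <- as.integer(d)
  if (d %% 2L == 0L)
    stop("window size must be odd (even windows would be asymmetric)")
  d
}

#' Character-level n-grams of a word
#'
#' All `nchar(word) - n + 1` contiguous n-character slices, in order; empty
#' when the word is shorter than `n`.
#'
#' @param word A character string.
#' @param n N-gram size (>= 1).
#' @return Character vector of n-grams.
#' @examples
#' char_ngrams("disease", 3)
#' @export
char_ngrams <- function(word, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  L <- nchar(word)
  if (L < n) return(character())
  starts <- seq_len(L - n + 1L)
  substring(word, starts, starts + n - 1L)
}

#' Word-level n-grams of a token sequence
#'
#' All contiguous n-token windows, in order, as a list of character vectors.
#'
#' @param tokens Character vector of tokens.
#' @param n N-gram size (>= 1).
#' @return List of length `max(0, length(tokens) - n + 1)`; each element a
#'   character vector of `n` tokens.
#' @examples
#' word_ngrams(c("biomedical", "named", "entity", "recognition"), 2)
#' @export
word_ngrams <- function(tokens, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  L <- length(tokens)
  if (L < n) return(list())
  lapply(seq_len(L - n + 1L), function(i) tokens[i:(i + n - 1L)])
}

#' Pad a vector sequence for a context window
#'
#' Concatenates `floor(d/2)` padding columns to each end of the sequence, so
#' a length-n sequence becomes length `n + 2 * floor(d/2)`.
#'
#' @param seq_mat A `k x n` numeric matrix, one column per position.
#' @param d Odd window size.
#' @param pad Padding vector of length `k` (default zeros). The model learns
#'   a shared padding embedding; zeros are its initialization.
#' @return A `k x (n + 2*floor(d/2))` matrix.
#' @export
pad_sequence <- function(seq_mat, d, pad = NULL) {
  d <- .check_window(d)
  stopifnot(is.matrix(seq_mat))
  h <- d %/% 2L
  if (h == 0L) return(seq_mat)
  k <- nrow(seq_mat)
  if (is.null(pad)) pad <- numeric(k)
  stopifnot(length(pad) == k)
  padm <- matrix(pad, nrow = k, ncol = h)
  cbind(padm, seq_mat, padm, deparse.level = 0)
}

#' Contextual window concatenation
#'
#' For a padded sequence, forms for each original position the ordered
#' concatenation of the `d` neighboring columns centered there, turning
#' `k`-vectors into `d*k`-vectors. With `d = 1` this is the identity, which
#' is exactly how the contextual model degenerates to a plain BiLSTM.
#'
#' @param padded_mat A `k x (n + 2*floor(d/2))` matrix as produced by
#'   [pad_sequence()] with the same `d`.
#' @param d Odd window size used for padding.
#' @return A `(d*k) x n` matrix.
#' @export
contextualize <- function(padded_mat, d) {
  d <- .check_window(d)
  stopifnot(is.matrix(padded_mat))
  h <- d %/% 2L
  n <- ncol(padded_mat) - 2L * h
  if (n < 0L)
    stop("padded sequence shorter than 2*floor(d/2): padding mismatch")
  k <- nrow(padded_mat)
  out <- matrix(0, nrow = d * k, ncol = n)
  if (n == 0L) return(out)
  for (j in seq_len(d)) {
    out[((j - 1L) * k + 1L):(j * k), ] <-
      padded_mat[, j:(j + n - 1L), drop = FALSE]
  }
  out
}
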