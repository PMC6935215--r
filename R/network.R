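# The neural scorer: character-level contextual BiLSTM producing per-word
# character representations, a word-level contextual BiLSTM over the
# concatenated word + character vectors, and an affine projection to the
# CRF emission score matrix P.

#' Model configuration
#'
#' Dimensions and window sizes of the contextual BiLSTM-CRF. The defaults
#' follow the standard BiLSTM-CRF lineage: 200-dimensional word embeddings
#' and word-level hidden states, 25-dimensional character embeddings and
#' character-level hidden states, dropout 0.5 on the word input vector.
#' `d_word` and `d_char` are the odd context-window sizes; setting both to 1
#' recovers a plain BiLSTM-CRF exactly. `d_word > 1, d_char = 1` is the
#' word-level contextual variant, `d_word = 1, d_char > 1` the
#' character-level variant, both `> 1` the word+char variant.
#'
#' @param word_emb_dim,word_hidden Word embedding / word LSTM hidden size.
#' @param char_emb_dim,char_hidden Character embedding / char LSTM hidden size.
#' @param d_word,d_char Odd context-window sizes (>= 1).
#' @param dropout Dropout rate on the word input vector, in `[0, 1)`;
#'   applied at training time only.
#' @param seed Integer seed governing weight initialization and dropout.
#' @param replace_singletons Replace training-set singleton words by UNK
#'   with probability 0.5 during training (helps the model learn an UNK
#'   representation).
#' @param iob_constraint Apply a hard IOB transition mask at decode time.
#' @return A list of class `clstm_config`.
#' @export
model_config <- function(word_emb_dim = 200L, char_emb_dim = 25L,
                         word_hidden = 200L, char_hidden = 25L,
                         d_word = 5L, d_char = 3L, dropout = 0.5,
                         seed = 1L, replace_singletons = TRUE,
                         iob_constraint = FALSE) {
  d_word <- .check_window(d_word)
  d_char <- .check_window(d_char)
  stopifnot(word_emb_dim >= 1, char_emb_dim >= 1, word_hidden >= 1,
            char_hidden >= 1, dropout >= 0, dropout < 1)
  structure(list(word_emb_dim = as.integer(word_emb_dim),
                 char_emb_dim = as.integer(char_emb_dim),
                 word_hidden = as.integer(word_hidden),
                 char_hidden = as.integer(char_hidden),
                 d_word = d_word, d_char = d_char,
                 dropout = dropout, seed = as.integer(seed),
                 replace_singletons = isTRUE(replace_singletons),
                 iob_constraint = isTRUE(iob_constraint)),
            class = "clstm_config")
}

# Uniform(-sqrt(3/dim), +sqrt(3/dim)) rows: the random-embedding scheme.
.init_embedding <- function(n_rows, dim) {
  r <- sqrt(3 / dim)
  matrix(runif(n_rows * dim, -r, r), nrow = n_rows, ncol = dim)
}

# Glorot-uniform weight matrix.
.init_weight <- function(n_out, n_in) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -r, r), nrow = n_out, ncol = n_in)
}

.init_lstm <- function(input_dim, H) {
  list(Wx = .init_weight(3L * H, input_dim),
       Wh = .init_weight(3L * H, H),
       Wci = .init_weight(H, H),
       Wco = .init_weight(H, H),
       b = numeric(3L * H))
}

#' Label set for a set of entity types
#'
#' The documented label order: `"O"` first, then `B-<type>`, `I-<type>` for
#' each type in sorted order. The CRF start and end tags are appended after
#' these at indices `|L|+1` and `|L|+2`.
#'
#' @param types Character vector of entity types.
#' @return Character vector of IOB labels.
#' @export
label_set <- function(types) {
  types <- sort(unique(as.character(types)))
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' Initialize a contextual BiLSTM-CRF model
#'
#' Builds vocabularies and randomly initialized parameters. Word embeddings
#' are taken from `pretrained` where available (a table read by
#' [read_word2vec()]), otherwise drawn uniform on
#' `(-sqrt(3/dim), +sqrt(3/dim))`; the same scheme initializes every
#' character embedding. Out-of-vocabulary tokens map to a dedicated UNK
#' row. All embeddings are fine-tuned during training. Padding embeddings
#' (one per level, shared between the left and right ends) start at zero,
#' which makes the `d = 1` configuration exactly a plain BiLSTM-CRF at
#' initialization.
#'
#' @param word_vocab Character vector of known words.
#' @param char_vocab Character vector of known characters.
#' @param types Character vector of entity types.
#' @param config A [model_config()].
#' @param pretrained Optional embedding table from [read_word2vec()]; its
#'   dimension must equal `config$word_emb_dim`.
#' @return An object of class `clstm_model`.
#' @export
clstm_model <- function(word_vocab, char_vocab, types, config = model_config(),
                        pretrained = NULL) {
  stopifnot(inherits(config, "clstm_config"))
  word_vocab <- unique(as.character(word_vocab))
  char_vocab <- unique(as.character(char_vocab))
  labels <- label_set(types)
  L <- length(labels)
  set.seed(config$seed)
  Dw <- config$word_emb_dim; Dc <- config$char_emb_dim
  Hw <- config$word_hidden; Hc <- config$char_hidden
  Dwin <- Dw + 2L * Hc
  E_word <- .init_embedding(length(word_vocab) + 1L, Dw)  # last row = UNK
  if (!is.null(pretrained)) {
    if (ncol(pretrained$vectors) != Dw)
      stop(sprintf("pretrained embedding dimension %d != word_emb_dim %d",
                   ncol(pretrained$vectors), Dw))
    hit <- match(word_vocab, pretrained$tokens)
    ok <- which(!is.na(hit))
    E_word[ok, ] <- pretrained$vectors[hit[ok], , drop = FALSE]
    E_word[length(word_vocab) + 1L, ] <- pretrained$unk
  }
  params <- list(
    E_word = E_word,
    E_char = .init_embedding(length(char_vocab) + 1L, Dc),
    pad_word = numeric(Dwin),
    pad_char = numeric(Dc),
    char_f = .init_lstm(config$d_char * Dc, Hc),
    char_b = .init_lstm(config$d_char * Dc, Hc),
    word_f = .init_lstm(config$d_word * Dwin, Hw),
    word_b = .init_lstm(config$d_word * Dwin, Hw),
    W_proj = .init_weight(L, 2L * Hw),
    b_proj = numeric(L),
    T = transition_matrix(L)
  )
  structure(list(params = params, config = config,
                 word_vocab = word_vocab, char_vocab = char_vocab,
                 types = sort(unique(as.character(types))), labels = labels),
            class = "clstm_model")
}

#' @export
print.clstm_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(paste0("<clstm_model: %d labels (%s), vocab %d words / %d chars,\n",
                     "  d_word=%d d_char=%d, word dim %d/%d, char dim %d/%d, %s parameters>\n"),
              length(x$labels), paste(x$types, collapse = ", "),
              length(x$word_vocab), length(x$char_vocab),
              x$config$d_word, x$config$d_char,
              x$config$word_emb_dim, x$config$word_hidden,
              x$config$char_emb_dim, x$config$char_hidden,
              format(np, big.mark = ",")))
  invisible(x)
}

.cpp_cfg <- function(model) {
  list(d_word = model$config$d_word, d_char = model$config$d_char)
}

# 1-based row indices into the embedding matrices; unknown tokens map to
# the UNK row (last).
.word_indices <- function(model, words) {
  idx <- match(words, model$word_vocab)
  idx[is.na(idx)] <- length(model$word_vocab) + 1L
  as.integer(idx)
}

.char_indices <- function(model, word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  idx <- match(ch, model$char_vocab)
  idx[is.na(idx)] <- length(model$char_vocab) + 1L
  as.integer(idx)
}

#' One step of the coupled-gate LSTM cell
#'
#' The input gate `i_t` is a sigmoid with peephole on the previous cell
#' state; the forget coefficient is `1 - i_t` by construction (coupled
#' gates); the output gate also takes its peephole from the previous cell
#' state; `h_t = o_t * tanh(c_t)`.
#'
#' @param x_ctx Contextual input vector (dimension must equal
#'   `ncol(params$Wx)`).
#' @param prev List with `h` and `c`, the previous cell state.
#' @param params List with `Wx`, `Wh`, `Wci`, `Wco` (matrices, gate row
#'   order: input gate, candidate, output gate) and `b`.
#' @return List with the new `h`, `c`, plus the gate activations `i`,
#'   `forget` (`= 1 - i`) and `o`.
#' @export
clstm_cell_step <- function(x_ctx, prev, params) {
  stopifnot(length(x_ctx) == ncol(params$Wx),
            length(prev$h) == ncol(params$Wh),
            length(prev$c) == length(prev$h))
  out <- cpp_lstm_cell_step(as.numeric(x_ctx), as.numeric(prev$h),
                            as.numeric(prev$c), params)
  out <- lapply(out, as.numeric)
  if (!all(is.finite(out$h)) || !all(is.finite(out$c)))
    stop("non-finite cell state")
  out
}

#' Run one LSTM direction over a sequence
#'
#' State is initialized to zeros. With `reverse = TRUE` the sequence is
#' processed back-to-front and the outputs are re-aligned to input order.
#'
#' @param inputs A `k x n` matrix of (contextualized) input columns.
#' @param params LSTM parameter list (see [clstm_cell_step()]).
#' @param reverse Process the sequence in reverse?
#' @return An `H x n` matrix of hidden states in input order.
#' @export
run_direction <- function(inputs, params, reverse = FALSE) {
  stopifnot(is.matrix(inputs), nrow(inputs) == ncol(params$Wx))
  cpp_lstm_run(inputs, params, isTRUE(reverse))
}

#' Bidirectional LSTM encoding
#'
#' Concatenates the forward and backward runs position-wise: rows `1..H`
#' are the forward hidden states, rows `H+1..2H` the backward ones.
#'
#' @param inputs A `k x n` matrix.
#' @param fwd_params,bwd_params Parameter lists for the two directions.
#' @return A `2H x n` matrix.
#' @export
bilstm_encode <- function(inputs, fwd_params, bwd_params) {
  rbind(run_direction(inputs, fwd_params, reverse = FALSE),
        run_direction(inputs, bwd_params, reverse = TRUE))
}

#' Character-level representation of a word
#'
#' Embeds the characters, pads and contextualizes with `d_char`, runs the
#' character BiLSTM, and concatenates the final states of the forward and
#' backward runs (dimension `2 * char_hidden`).
#'
#' @param model A `clstm_model`.
#' @param word A non-empty character string.
#' @return Numeric vector of length `2 * char_hidden`.
#' @export
char_representation <- function(model, word) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) > 0L)
  as.numeric(cpp_char_rep(model$params, .char_indices(model, word),
                          .cpp_cfg(model)))
}

#' Word input vector
#'
#' Concatenation of the word embedding (UNK row for out-of-vocabulary
#' words) and the character-level representation. Dropout is applied to
#' this vector at training time only, so this accessor returns the
#' deterministic value.
#'
#' @inheritParams char_representation
#' @return Numeric vector of length `word_emb_dim + 2 * char_hidden`.
#' @export
word_input_vector <- function(model, word) {
  idx <- .word_indices(model, word)
  c(as.numeric(model$params$E_word[idx, ]), char_representation(model, word))
}

#' Emission score matrix
#'
#' Runs the full network (character-level contextual BiLSTM, word-level
#' contextual BiLSTM, affine projection) and returns the per-position
#' per-label scores P consumed by the CRF layer. Deterministic: dropout is
#' disabled outside training.
#'
#' @param model A `clstm_model`.
#' @param tokens Character vector of token texts, or a [tagged_sentence()].
#' @return An `n x |L|` matrix with the label set as column names.
#' @export
emissions <- function(model, tokens) {
  if (inherits(tokens, "tagged_sentence")) tokens <- tokens$tokens$text
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) {
    P <- matrix(0, 0L, length(model$labels))
    colnames(P) <- model$labels
    return(P)
  }
  widx <- .word_indices(model, tokens)
  cidx <- lapply(tokens, function(w) .char_indices(model, w))
  P <- cpp_emissions(model$params, widx, cidx, .cpp_cfg(model))
  if (!all(is.finite(P))) stop("non-finite emission scores")
  colnames(P) <- model$labels
  P
}

#' Read a word-embedding table in word2vec text format
#'
#' Each line is a token followed by whitespace-separated real values; an
#' optional first line `count dim` is skipped. The UNK fallback vector is
#' the mean of all vectors.
#'
#' @param path Path to the embedding file.
#' @param expected_dim If given, a dimension mismatch is a hard error.
#' @return A list with `tokens`, `vectors` (matrix, one row per token) and
#'   `unk`.
#' @export
read_word2vec <- function(path, expected_dim = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty embedding file")
  parts <- strsplit(trimws(lines), "\\s+")
  if (length(parts[[1]]) == 2L &&
      !anyNA(suppressWarnings(as.numeric(parts[[1]]))))
    parts <- parts[-1L]
  toks <- vapply(parts, `[[`, character(1), 1L)
  vecs <- lapply(parts, function(p) as.numeric(p[-1L]))
  dims <- lengths(vecs)
  if (length(unique(dims)) != 1L)
    stop("inconsistent vector dimensions in embedding file")
  if (!is.null(expected_dim) && dims[1] != expected_dim)
    stop(sprintf("embedding dimension %d does not match expected %d",
                 dims[1], expected_dim))
  V <- do.call(rbind, vecs)
  rownames(V) <- NULL
  list(tokens = toks, vectors = V, unk = colMeans(V))
}
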