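# Independent pure-R reference implementations used as oracles. These are
# deliberately naive (direct formula evaluation, explicit enumeration) and
# share no code with the package internals.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# Direct evaluation of the coupled-gate cell equations: input gate with
# peephole on the previous cell state, forget coefficient 1 - i, output
# gate with peephole on the previous cell state.
ref_cell_step <- function(x, h0, c0, p) {
  H <- length(h0)
  i <- ref_sigmoid(p$Wx[1:H, , drop = FALSE] %*% x +
                   p$Wh[1:H, , drop = FALSE] %*% h0 +
                   p$Wci %*% c0 + p$b[1:H])
  g <- tanh(p$Wx[(H + 1):(2 * H), , drop = FALSE] %*% x +
            p$Wh[(H + 1):(2 * H), , drop = FALSE] %*% h0 +
            p$b[(H + 1):(2 * H)])
  cn <- (1 - i) * c0 + i * g
  o <- ref_sigmoid(p$Wx[(2 * H + 1):(3 * H), , drop = FALSE] %*% x +
                   p$Wh[(2 * H + 1):(3 * H), , drop = FALSE] %*% h0 +
                   p$Wco %*% c0 + p$b[(2 * H + 1):(3 * H)])
  hn <- o * tanh(cn)
  list(h = as.numeric(hn), c = as.numeric(cn), i = as.numeric(i))
}

# Naive unidirectional run (loop of ref_cell_step), state starts at zero.
ref_lstm_run <- function(X, p, reverse = FALSE) {
  n <- ncol(X)
  H <- ncol(p$Wh)
  idx <- if (reverse) rev(seq_len(n)) else seq_len(n)
  h <- numeric(H); c <- numeric(H)
  out <- matrix(0, H, n)
  for (t in idx) {
    st <- ref_cell_step(X[, t], h, c, p)
    h <- st$h; c <- st$c
    out[, t] <- h
  }
  out
}

# Plain BiLSTM emissions built naively from one shared weight set: word
# embedding + char-BiLSTM final states, no windows, affine projection.
ref_plain_bilstm_emissions <- function(model, tokens) {
  p <- model$params
  widx <- clstm:::.word_indices(model, tokens)
  crep <- sapply(tokens, function(w) {
    ci <- clstm:::.char_indices(model, w)
    Xc <- t(p$E_char[ci, , drop = FALSE])
    c(ref_lstm_run(Xc, p$char_f)[, length(ci)],
      ref_lstm_run(Xc, p$char_b, reverse = TRUE)[, 1])
  })
  Win <- rbind(t(p$E_word[widx, , drop = FALSE]), crep)
  H2 <- rbind(ref_lstm_run(Win, p$word_f),
              ref_lstm_run(Win, p$word_b, reverse = TRUE))
  t(p$W_proj %*% H2 + p$b_proj)
}

# --- brute-force CRF oracles (enumerate all |L|^n paths) ------------------

ref_path_score <- function(P, T, y) {
  n <- nrow(P); L <- ncol(P)
  s <- T[L + 1, y[1]] + P[1, y[1]]
  if (n > 1) for (t in 2:n) s <- s + T[y[t - 1], y[t]] + P[t, y[t]]
  s + T[y[n], L + 2]
}

ref_all_paths <- function(n, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), n)))
}

ref_log_partition <- function(P, T) {
  paths <- ref_all_paths(nrow(P), ncol(P))
  sc <- apply(paths, 1, function(y) ref_path_score(P, T, y))
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

# Brute-force argmax with the deterministic tie rule: among maximal paths,
# prefer the lowest label index at the latest differing position (i.e. the
# path whose reversed label sequence is lexicographically smallest).
ref_viterbi <- function(P, T) {
  paths <- ref_all_paths(nrow(P), ncol(P))
  sc <- apply(paths, 1, function(y) ref_path_score(P, T, y))
  best <- max(sc)
  cand <- paths[sc >= best - 1e-12, , drop = FALSE]
  rev_keys <- apply(cand, 1, function(y)
    paste(sprintf("%03d", rev(y)), collapse = ""))
  list(path = as.integer(cand[order(rev_keys)[1], ]), score = best)
}

# Second, independent token-level tally for the IOB matching cross-check.
ref_iob_tally <- function(gold, pred) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in seq_along(gold)) {
    if (gold[k] != "O" && gold[k] == pred[k]) tp <- tp + 1L
    if (gold[k] != "O" && gold[k] != pred[k]) fn <- fn + 1L
    if (pred[k] != "O" && pred[k] != gold[k]) fp <- fp + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# --- small fixtures -------------------------------------------------------

tiny_config <- function(d_word = 3L, d_char = 3L, dropout = 0, seed = 11L,
                        ...) {
  model_config(word_emb_dim = 6L, char_emb_dim = 4L, word_hidden = 5L,
               char_hidden = 3L, d_word = d_word, d_char = d_char,
               dropout = dropout, seed = seed, ...)
}

tiny_model <- function(...) {
  clstm_model(word_vocab = c("alpha", "beta", "gammax", "deltaol"),
              char_vocab = letters, types = c("Chemical", "Disease"),
              config = tiny_config(...))
}

random_PT <- function(n, L) {
  P <- matrix(rnorm(n * L), n, L)
  T <- transition_matrix(L)
  T[is.finite(T)] <- rnorm(sum(is.finite(T)))
  list(P = P, T = T)
}

random_mention_set <- function(n_tokens, types = c("Disease", "Chemical")) {
  # random non-overlapping typed spans over n_tokens tokens
  ty <- character(); s <- integer(); e <- integer()
  pos <- 0L
  while (pos < n_tokens) {
    if (runif(1) < 0.35) {
      len <- sample(1:min(3, n_tokens - pos), 1)
      ty <- c(ty, sample(types, 1)); s <- c(s, pos); e <- c(e, pos + len)
      pos <- pos + len
    } else pos <- pos + 1L
  }
  mentions(ty, s, e)
}

random_tagged_corpus <- function(n_sentences, n_tokens = 8L) {
  lapply(seq_len(n_sentences), function(i) {
    m <- random_mention_set(n_tokens)
    tagged_sentence(sprintf("w%02d", sample(30, n_tokens, TRUE)),
                    mentions_to_iob(n_tokens, m))
  })
}
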