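test_that("the coupled cell has the forced zero and half-decay fixed points", {
  H <- 3L
  zero <- list(Wx = matrix(0, 3 * H, 4), Wh = matrix(0, 3 * H, H),
               Wci = matrix(0, H, H), Wco = matrix(0, H, H),
               b = numeric(3 * H))
  st <- clstm_cell_step(numeric(4), list(h = numeric(H), c = numeric(H)), zero)
  expect_equal(st$h, numeric(H))
  expect_equal(st$c, numeric(H))
  expect_equal(st$i, rep(0.5, H))          # sigma(0)
  expect_equal(st$forget, rep(0.5, H))     # coupled: 1 - i
  # with zero params and prior cell c0: c' = c0/2, h' = tanh(c0/2)/2
  c0 <- c(1, -2, 0.5)
  st2 <- clstm_cell_step(numeric(4), list(h = numeric(H), c = c0), zero)
  expect_equal(st2$c, 0.5 * c0)
  expect_equal(st2$h, 0.5 * tanh(0.5 * c0))
})

test_that("the scalar cell matches the closed-form gate expressions", {
  # H = 1, all weights 1, biases 0, x = 1, zero initial state:
  # i = sigma(1), c = i * tanh(1), o = sigma(1) (output-gate peephole reads
  # the previous cell state, which is 0), h = o * tanh(c)
  ones <- list(Wx = matrix(1, 3, 1), Wh = matrix(1, 3, 1),
               Wci = matrix(1, 1, 1), Wco = matrix(1, 1, 1), b = numeric(3))
  st <- clstm_cell_step(1, list(h = 0, c = 0), ones)
  i <- 1 / (1 + exp(-1))
  cexp <- i * tanh(1)
  o <- 1 / (1 + exp(-1))
  expect_equal(st$c, cexp, tolerance = 1e-6)
  expect_equal(st$h, o * tanh(cexp), tolerance = 1e-6)
  # and a second step exposes both peepholes on the now-nonzero cell state
  st2 <- clstm_cell_step(1, list(h = st$h, c = st$c), ones)
  want <- ref_cell_step(1, st$h, st$c, ones)
  expect_equal(st2$h, want$h, tolerance = 1e-12)
  expect_equal(st2$c, want$c, tolerance = 1e-12)
})

test_that("cell steps agree with the naive reference on random weights", {
  set.seed(201)
  for (trial in 1:25) {
    H <- sample(1:4, 1); k <- sample(1:5, 1)
    p <- list(Wx = matrix(rnorm(3 * H * k), 3 * H, k),
              Wh = matrix(rnorm(3 * H * H), 3 * H, H),
              Wci = matrix(rnorm(H * H), H, H),
              Wco = matrix(rnorm(H * H), H, H),
              b = rnorm(3 * H))
    x <- rnorm(k); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- clstm_cell_step(x, list(h = h0, c = c0), p)
    want <- ref_cell_step(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$forget, 1 - want$i, tolerance = 1e-12)
  }
})

test_that("directional runs are length-preserving, symmetric and match the reference", {
  set.seed(202)
  H <- 3L; k <- 4L
  p <- list(Wx = matrix(rnorm(3 * H * k), 3 * H, k),
            Wh = matrix(rnorm(3 * H * H), 3 * H, H) * 0.3,
            Wci = matrix(rnorm(H * H), H, H) * 0.3,
            Wco = matrix(rnorm(H * H), H, H) * 0.3,
            b = rnorm(3 * H))
  expect_equal(dim(run_direction(matrix(0, k, 0), p)), c(H, 0L))
  x1 <- matrix(rnorm(k), k, 1)
  expect_equal(run_direction(x1, p, reverse = FALSE),
               run_direction(x1, p, reverse = TRUE))
  X <- matrix(rnorm(k * 6), k, 6)
  # reversing input and direction are the same thing
  expect_equal(run_direction(X[, 6:1], p, reverse = FALSE)[, 6:1],
               run_direction(X, p, reverse = TRUE), tolerance = 1e-12)
  expect_equal(run_direction(X, p), ref_lstm_run(X, p), tolerance = 1e-10)
  expect_equal(run_direction(X, p, reverse = TRUE),
               ref_lstm_run(X, p, reverse = TRUE), tolerance = 1e-10)
})

test_that("the bidirectional encoding stacks the two directional runs", {
  set.seed(203)
  H <- 2L; k <- 3L
  mk <- function() list(Wx = matrix(rnorm(3 * H * k), 3 * H, k),
                        Wh = matrix(rnorm(3 * H * H), 3 * H, H) * 0.3,
                        Wci = matrix(rnorm(H * H), H, H) * 0.3,
                        Wco = matrix(rnorm(H * H), H, H) * 0.3,
                        b = rnorm(3 * H))
  pf <- mk(); pb <- mk()
  X <- matrix(rnorm(k * 5), k, 5)
  enc <- bilstm_encode(X, pf, pb)
  expect_equal(nrow(enc), 2L * H)
  expect_equal(enc[1:H, ], run_direction(X, pf))
  expect_equal(enc[(H + 1):(2 * H), ], run_direction(X, pb, reverse = TRUE))
  zero <- list(Wx = matrix(0, 3 * H, k), Wh = matrix(0, 3 * H, H),
               Wci = matrix(0, H, H), Wco = matrix(0, H, H),
               b = numeric(3 * H))
  expect_true(all(bilstm_encode(X, zero, zero) == 0))
})

test_that("character representations are pure, fixed-size, and robust to unseen characters", {
  m <- tiny_model()
  v <- char_representation(m, "alpha")
  expect_length(v, 2L * m$config$char_hidden)
  expect_identical(char_representation(m, "alpha"), v)
  expect_length(char_representation(m, "Z9!"), 2L * m$config$char_hidden)
  expect_error(char_representation(m, ""), "nchar")
})

test_that("word input vectors concatenate the embedding (or UNK) with the char representation", {
  m <- tiny_model()
  Dw <- m$config$word_emb_dim
  v <- word_input_vector(m, "alpha")
  expect_length(v, Dw + 2L * m$config$char_hidden)
  expect_equal(v[1:Dw], as.numeric(m$params$E_word[1, ]))
  # out-of-vocabulary: first block is the UNK row
  v2 <- word_input_vector(m, "zzzz")
  expect_equal(v2[1:Dw],
               as.numeric(m$params$E_word[length(m$word_vocab) + 1L, ]))
  expect_equal(v[(Dw + 1):length(v)], char_representation(m, "alpha"))
})

test_that("emission matrices have one row per token and the label columns", {
  m <- tiny_model()
  P <- emissions(m, c("alpha", "beta", "zzz"))
  expect_equal(dim(P), c(3L, length(m$labels)))
  expect_identical(colnames(P), m$labels)
  expect_true(all(is.finite(P)))
  P0 <- emissions(m, character(0))
  expect_equal(dim(P0), c(0L, length(m$labels)))
  # purity
  expect_identical(P, emissions(m, c("alpha", "beta", "zzz")))
  # zero projection forces all-zero scores
  m2 <- tiny_model()
  m2$params$W_proj[] <- 0
  m2$params$b_proj[] <- 0
  expect_true(all(emissions(m2, c("alpha", "beta")) == 0))
})

test_that("with d = 1 windows the model is exactly a plain BiLSTM-CRF", {
  for (seed in c(31L, 32L)) {
    m <- tiny_model(d_word = 1L, d_char = 1L, seed = seed)
    toks <- c("alpha", "qq", "beta", "gammax")
    got <- emissions(m, toks)
    want <- ref_plain_bilstm_emissions(m, toks)
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
})

test_that("analytic gradients agree with finite differences on a 3-token sentence", {
  set.seed(204)
  m <- tiny_model()
  toks <- c("alpha", "zz", "beta")
  widx <- clstm:::.word_indices(m, toks)
  cidx <- lapply(toks, function(w) clstm:::.char_indices(m, w))
  gold <- match(c("B-Chemical", "I-Chemical", "O"), m$labels)
  cfg <- clstm:::.cpp_cfg(m)
  g <- clstm:::cpp_loss_grads(m$params, widx, cidx, gold, cfg, NULL)
  loss_at <- function(p) clstm:::cpp_loss_grads(p, widx, cidx, gold, cfg,
                                                NULL)$loss
  eps <- 1e-5
  get_leaf <- function(p, path) if (length(path) == 1) p[[path]]
                                else p[[path[1]]][[path[2]]]
  perturb <- function(path, i, h) {
    p2 <- rapply(m$params, function(x) x + 0, how = "replace")
    if (length(path) == 1) p2[[path]][i] <- p2[[path]][i] + h
    else p2[[path[1]]][[path[2]]][i] <- p2[[path[1]]][[path[2]]][i] + h
    p2
  }
  blocks <- c(list("E_word", "E_char", "pad_word", "pad_char", "W_proj",
                   "b_proj"),
              unlist(lapply(c("char_f", "char_b", "word_f", "word_b"),
                            function(l) lapply(c("Wx", "Wh", "Wci", "Wco",
                                                 "b"),
                                               function(w) c(l, w))),
                     recursive = FALSE))
  for (path in blocks) {
    arr <- get_leaf(m$params, path)
    ga <- get_leaf(g, path)
    for (i in sample(length(arr), min(4, length(arr)))) {
      fd <- (loss_at(perturb(path, i, eps)) -
               loss_at(perturb(path, i, -eps))) / (2 * eps)
      denom <- max(abs(fd), abs(ga[i]), 1e-6)
      expect_lt(abs(fd - ga[i]) / denom, 1e-4)
    }
  }
  # transition entries (finite ones only)
  finite_ix <- which(is.finite(m$params$T))
  for (i in sample(finite_ix, 6)) {
    fd <- (loss_at(perturb("T", i, eps)) -
             loss_at(perturb("T", i, -eps))) / (2 * eps)
    denom <- max(abs(fd), abs(g$T[i]), 1e-6)
    expect_lt(abs(fd - g$T[i]) / denom, 1e-4)
  }
})

test_that("word2vec text tables load, with and without a header line", {
  path <- withr::local_tempfile()
  writeLines(c("2 3", "alpha 0.1 0.2 0.3", "beta -1 0 1"), path)
  tb <- read_word2vec(path)
  expect_identical(tb$tokens, c("alpha", "beta"))
  expect_equal(tb$vectors[2, ], c(-1, 0, 1))
  expect_equal(tb$unk, colMeans(tb$vectors))
  path2 <- withr::local_tempfile()
  writeLines(c("alpha 1 2", "beta 3 4"), path2)
  expect_equal(dim(read_word2vec(path2)$vectors), c(2L, 2L))
  expect_error(read_word2vec(path, expected_dim = 5), "dimension")
  # a model built on pretrained vectors picks them up for known words
  cfg <- model_config(word_emb_dim = 3L, char_emb_dim = 2L, word_hidden = 2L,
                      char_hidden = 2L, d_word = 1L, d_char = 1L, seed = 5L)
  m <- clstm_model(c("alpha", "nu"), letters, "Disease", cfg,
                   pretrained = tb)
  expect_equal(as.numeric(m$params$E_word[1, ]), c(0.1, 0.2, 0.3))
  expect_equal(as.numeric(m$params$E_word[3, ]), tb$unk)
})
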