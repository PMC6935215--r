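# Training loop (sentence-level SGD on the CRF negative log-likelihood with
# gradient clipping), prediction, multi-trial harness, checkpointing and
# run configuration.

#' Tuned context-window presets
#'
#' The window sizes selected on the development sets of the three standard
#' corpora: word-level variant `d_word = 5` everywhere; character-level
#' variant `d_char` 3/5/7 for NCBI/GM/CDR; word+char variant (5,5) for NCBI
#' and (3,3) for GM and CDR.
#'
#' @param variant One of `"word"`, `"char"`, `"word+char"`.
#' @param corpus One of `"ncbi"`, `"gm"`, `"cdr"`.
#' @return Named integer vector with `d_word` and `d_char`.
#' @export
window_preset <- function(variant = c("word+char", "word", "char"),
                          corpus = c("ncbi", "gm", "cdr")) {
  variant <- match.arg(variant)
  corpus <- match.arg(corpus)
  switch(variant,
    "word" = c(d_word = 5L, d_char = 1L),
    "char" = c(d_word = 1L,
               d_char = c(ncbi = 3L, gm = 5L, cdr = 7L)[[corpus]]),
    "word+char" = if (corpus == "ncbi") c(d_word = 5L, d_char = 5L)
                  else c(d_word = 3L, d_char = 3L))
}

.corpus_vocab <- function(corpus) {
  words <- unlist(lapply(corpus, function(s) s$tokens$text))
  tab <- table(words)
  list(words = names(tab),
       singletons = names(tab)[tab == 1L],
       chars = sort(unique(unlist(strsplit(names(tab), "", fixed = TRUE)))))
}

.corpus_types <- function(corpus) {
  labs <- unlist(lapply(corpus, `[[`, "labels"))
  labs <- labs[labs != "O"]
  sort(unique(substr(labs, 3L, nchar(labs))))
}

.copy_params <- function(p) rapply(p, function(x) x + 0, how = "replace")

.decode_T <- function(model) {
  T <- model$params$T
  if (model$config$iob_constraint)
    T <- T + iob_constraint_mask(model$labels)
  T
}

#' Train a contextual BiLSTM-CRF tagger
#'
#' Minimizes the CRF negative log-likelihood by plain SGD, one sentence per
#' step, with global-norm gradient clipping. After each epoch the
#' development set is decoded and scored with strict matching; the
#' best-scoring parameters are kept, and training stops early when the dev
#' F-score has not improved for `patience` epochs. Word, character and
#' padding embeddings, all LSTM weights, the projection and the transition
#' matrix are updated. Training-set singleton words are stochastically
#' replaced by UNK (see [model_config()]) so the UNK embedding is trained.
#'
#' @param train,dev Lists of [tagged_sentence()] objects (`dev` may be
#'   `NULL`, disabling model selection and early stopping).
#' @param config A [model_config()].
#' @param lr,clip SGD learning rate and gradient-clipping threshold.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience, in epochs, on dev strict F.
#' @param pretrained Optional embedding table from [read_word2vec()].
#' @param verbose Emit one structured log line per epoch to stderr.
#' @return A trained `clstm_model`; `$log` holds the per-epoch data frame
#'   (epoch, mean train NLL, dev p/r/f).
#' @export
train_clstm <- function(train, dev = NULL, config = model_config(),
                        lr = 0.01, clip = 5, epochs = 100L, patience = 10L,
                        pretrained = NULL, verbose = TRUE) {
  stopifnot(epochs >= 1, lr > 0)
  if (!length(train)) stop("empty training set")
  voc <- .corpus_vocab(train)
  types <- .corpus_types(c(train, dev))
  if (!length(types)) stop("training data contain no entity mentions")
  model <- clstm_model(voc$words, voc$chars, types, config, pretrained)
  params <- model$params
  cfg <- .cpp_cfg(model)
  lab_idx <- function(s) match(s$labels, model$labels)
  sent_data <- lapply(train, function(s) {
    list(words = s$tokens$text,
         widx = .word_indices(model, s$tokens$text),
         cidx = lapply(s$tokens$text, function(w) .char_indices(model, w)),
         gold = as.integer(lab_idx(s)))
  })
  sent_data <- Filter(function(d) length(d$widx) > 0L, sent_data)
  singleton <- lapply(sent_data, function(d) d$words %in% voc$singletons)
  unk_w <- length(model$word_vocab) + 1L
  Dwin <- config$word_emb_dim + 2L * config$char_hidden
  p_drop <- config$dropout
  best <- list(f = -Inf, params = NULL, epoch = 0L)
  log <- data.frame(epoch = integer(), loss = numeric(), dev_p = numeric(),
                    dev_r = numeric(), dev_f = numeric())
  set.seed(config$seed + 1L)  # training stream (init used config$seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(sent_data))
    total <- 0
    for (k in ord) {
      d <- sent_data[[k]]
      widx <- d$widx
      if (config$replace_singletons && any(singleton[[k]])) {
        flip <- singleton[[k]] & stats::runif(length(widx)) < 0.5
        widx[flip] <- unk_w
      }
      n <- length(widx)
      mask <- NULL
      if (p_drop > 0)
        mask <- matrix((stats::runif(Dwin * n) >= p_drop) / (1 - p_drop),
                       nrow = Dwin, ncol = n)
      total <- total + cpp_train_step(params, widx, d$cidx, d$gold, cfg,
                                      mask, lr, clip)
    }
    mean_loss <- total / length(sent_data)
    dev_m <- list(p = NA_real_, r = NA_real_, f = NA_real_)
    if (length(dev)) {
      pred <- predict_clstm(model, dev)
      dev_m <- evaluate_corpus(dev, pred, "strict")$metrics
      if (dev_m$f > best$f) {
        best <- list(f = dev_m$f, params = .copy_params(params), epoch = ep)
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean_loss,
                                 dev_p = dev_m$p, dev_r = dev_m$r,
                                 dev_f = dev_m$f))
    if (verbose)
      message(sprintf("epoch %d loss %.4f dev_f %s", ep, mean_loss,
                      if (is.na(dev_m$f)) "NA"
                      else sprintf("%.4f", dev_m$f)))
    if (length(dev) && ep - best$epoch >= patience) break
  }
  if (!is.null(best$params)) model$params <- best$params
  model$log <- log
  model
}

#' Decode a corpus with a trained model
#'
#' Deterministic (dropout off): runs the network, then Viterbi decoding,
#' for every sentence. When the model was configured with
#' `iob_constraint = TRUE`, a hard mask forbidding ill-formed IOB
#' transitions is added to the transition matrix at decode time.
#'
#' @param model A trained `clstm_model`.
#' @param corpus List of [tagged_sentence()] objects (labels, if any, are
#'   ignored).
#' @return A list of [tagged_sentence()] objects with predicted labels,
#'   aligned token-for-token with the input.
#' @export
predict_clstm <- function(model, corpus) {
  T <- .decode_T(model)
  lapply(corpus, function(s) {
    n <- nrow(s$tokens)
    if (n == 0L) return(tagged_sentence(s$tokens, character(0)))
    P <- emissions(model, s$tokens$text)
    v <- viterbi_decode(P, T)
    tagged_sentence(s$tokens, model$labels[v$path])
  })
}

#' Repeated independent training runs
#'
#' Trains `n_trials` models that differ only in the seed (trial `i` uses
#' `config$seed + i`), evaluates each on the test set with strict matching,
#' and averages the resulting metrics.
#'
#' @inheritParams train_clstm
#' @param test Held-out corpus for the per-trial evaluation.
#' @param n_trials Number of independent trainings (>= 1).
#' @param ... Passed on to [train_clstm()] (`lr`, `epochs`, `patience`, ...).
#' @return A list with `trials` (per-trial `clstm_metrics`), `summary`
#'   (their [robustness_summary()]) and `models`.
#' @export
run_trials <- function(train, dev, test, config = model_config(),
                       n_trials = 5L, ...) {
  stopifnot(n_trials >= 1)
  base_seed <- config$seed
  models <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg_i <- config
    cfg_i$seed <- base_seed + i
    models[[i]] <- train_clstm(train, dev, cfg_i, ...)
    pred <- predict_clstm(models[[i]], test)
    trials[[i]] <- evaluate_corpus(test, pred, "strict")$metrics
  }
  list(trials = trials, summary = robustness_summary(trials),
       models = models)
}

.CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A single serialized file holding the format version, configuration,
#' vocabularies, label set and all parameters.
#'
#' @param model A `clstm_model`.
#' @param path Checkpoint file path.
#' @return `save_clstm`: `path`, invisibly. `load_clstm`: the restored
#'   `clstm_model`.
#' @export
save_clstm <- function(model, path) {
  stopifnot(inherits(model, "clstm_model"))
  obj <- unclass(model)
  obj$checkpoint_version <- .CHECKPOINT_VERSION
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_clstm
#' @export
load_clstm <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$checkpoint_version, .CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$checkpoint_version)
  obj$checkpoint_version <- NULL
  structure(obj, class = "clstm_model")
}

.TRAIN_CFG_KEYS <- c("word_emb_dim", "char_emb_dim", "word_hidden",
                     "char_hidden", "d_word", "d_char", "dropout", "seed",
                     "replace_singletons", "iob_constraint", "lr", "clip",
                     "epochs", "patience", "train", "dev", "test",
                     "embeddings", "output_dir", "n_trials")

#' Read a training run configuration
#'
#' One flat YAML document; every field has a default (the [model_config()]
#' and [train_clstm()] defaults); unknown keys are errors.
#'
#' @param path Path to a YAML file.
#' @return A list with `model` (a [model_config()]), `train` (optimizer and
#'   loop settings) and `paths`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), .TRAIN_CFG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  model <- model_config(
    word_emb_dim = pick("word_emb_dim", 200L),
    char_emb_dim = pick("char_emb_dim", 25L),
    word_hidden = pick("word_hidden", 200L),
    char_hidden = pick("char_hidden", 25L),
    d_word = pick("d_word", 5L),
    d_char = pick("d_char", 3L),
    dropout = pick("dropout", 0.5),
    seed = pick("seed", 1L),
    replace_singletons = pick("replace_singletons", TRUE),
    iob_constraint = pick("iob_constraint", FALSE))
  list(model = model,
       train = list(lr = pick("lr", 0.01), clip = pick("clip", 5),
                    epochs = pick("epochs", 100L),
                    patience = pick("patience", 10L),
                    n_trials = pick("n_trials", 5L)),
       paths = list(train = pick("train", NULL), dev = pick("dev", NULL),
                    test = pick("test", NULL),
                    embeddings = pick("embeddings", NULL),
                    output_dir = pick("output_dir", ".")))
}
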