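# Deterministic generator of tagged corpora with the structure the model
# assumes: multi-token typed mentions, ambiguous surface forms that occur
# both as entities and as plain text, boundary-adjacent entities, and a
# PubTator document rendering. Every other module is testable against this
# generator without external corpora.

.SYLLABLES <- c("ba", "co", "de", "fi", "ga", "he", "ki", "lo", "mu", "na",
                "pe", "qui", "ro", "sa", "tu", "ve", "xi", "zo", "bra", "cli",
                "dro", "fla", "gre", "pla", "ste", "tri")
.TYPE_SUFFIX <- list(Disease = c("itis", "oma", "osis", "pathy"),
                     Chemical = c("ine", "ol", "ate", "ide"),
                     Gene = c("gene", "ase", "orf", "fak"))

# Independent stream per (purpose, seed): adding a sampling site under one
# purpose does not shift draws under another.
.stream <- function(seed, purpose) {
  offs <- c(lexicon = 1L, sentences = 2L, corrupt = 3L)
  set.seed((offs[[purpose]] * 1000003L + as.integer(seed)) %% .Machine$integer.max)
}

#' Synthetic corpus configuration
#'
#' @param n_sentences Total sentences generated (then split).
#' @param vocab_size Number of general (non-entity) word types.
#' @param types Entity types; each gets its own surface-form lexicon with a
#'   type-characteristic final-token suffix, so both word identity and
#'   character shape carry signal.
#' @param lexicon_size Surface forms per entity type.
#' @param mention_len_probs Distribution of mention length in tokens
#'   (1 to 4).
#' @param density Expected mentions per sentence (Poisson draw, capped by
#'   what fits in the sentence).
#' @param ambiguity Fraction of entity surface forms that also occur as
#'   plain non-entity text.
#' @param sent_len_range Inclusive range of sentence lengths in tokens.
#' @param split_props Proportions of the train/dev/test split.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sentences = 2500L, vocab_size = 300L,
                         types = c("Disease", "Chemical"), lexicon_size = 25L,
                         mention_len_probs = c(0.5, 0.3, 0.15, 0.05),
                         density = 1.0, ambiguity = 0.2,
                         sent_len_range = c(5L, 15L),
                         split_props = c(train = 0.8, dev = 0.1, test = 0.1),
                         seed = 1L) {
  stopifnot(n_sentences >= 1, vocab_size >= 1, length(types) >= 1,
            lexicon_size >= 1, length(mention_len_probs) == 4L,
            abs(sum(mention_len_probs) - 1) < 1e-8, density >= 0,
            ambiguity >= 0, ambiguity <= 1,
            length(sent_len_range) == 2L, sent_len_range[1] >= 2L,
            abs(sum(split_props) - 1) < 1e-8)
  mean_len <- sum(mention_len_probs * (1:4))
  if (density * mean_len > 0.8 * sent_len_range[1])
    stop("infeasible config: expected mention tokens per sentence (",
         round(density * mean_len, 2), ") exceed sentence capacity")
  structure(list(n_sentences = as.integer(n_sentences),
                 vocab_size = as.integer(vocab_size),
                 types = as.character(types),
                 lexicon_size = as.integer(lexicon_size),
                 mention_len_probs = mention_len_probs,
                 density = density, ambiguity = ambiguity,
                 sent_len_range = as.integer(sent_len_range),
                 split_props = split_props, seed = as.integer(seed)),
            class = "synth_config")
}

.make_word <- function(n_syll) {
  paste(sample(.SYLLABLES, n_syll, replace = TRUE), collapse = "")
}

.synth_lexicons <- function(cfg) {
  .stream(cfg$seed, "lexicon")
  vocab <- character(0)
  while (length(vocab) < cfg$vocab_size)
    vocab <- unique(c(vocab, .make_word(sample(2:4, 1))))
  vocab <- vocab[seq_len(cfg$vocab_size)]
  lex <- list()
  for (ty in cfg$types) {
    sfx <- .TYPE_SUFFIX[[ty]]
    if (is.null(sfx)) sfx <- c("um", "ex")
    entries <- list()
    seen <- character(0)
    while (length(entries) < cfg$lexicon_size) {
      len <- sample(1:4, 1, prob = cfg$mention_len_probs)
      head_tok <- paste0(.make_word(sample(1:2, 1)), sample(sfx, 1))
      toks <- c(if (len > 1) sample(vocab, len - 1, replace = TRUE), head_tok)
      key <- paste(toks, collapse = " ")
      if (key %in% seen) next
      seen <- c(seen, key)
      entries[[length(entries) + 1L]] <- toks
    }
    lex[[ty]] <- entries
  }
  n_amb <- floor(cfg$ambiguity * cfg$lexicon_size)
  amb <- lapply(lex, function(entries) seq_len(n_amb))
  # cue words: context tokens that tend to precede true mentions and never
  # precede an ambiguous surface form used as plain text -- the contextual
  # signal that makes ambiguous forms resolvable from their neighbors
  cues <- character(0)
  while (length(cues) < 6L) {
    w <- paste0(.make_word(2), "ed")
    if (!(w %in% vocab)) cues <- unique(c(cues, w))
  }
  list(vocab = vocab, lexicons = lex, ambiguous = amb, cues = cues)
}

.place_spans <- function(n, lens) {
  # place spans of the given token lengths without overlap; returns starts
  # (0-based) aligned with lens, NA where a span did not fit
  free <- rep(TRUE, n)
  starts <- rep(NA_integer_, length(lens))
  for (i in seq_along(lens)) {
    len <- lens[i]
    ok <- which(vapply(seq_len(n - len + 1L),
                       function(s) all(free[s:(s + len - 1L)]), logical(1)))
    if (!length(ok)) next
    s <- if (length(ok) == 1L) ok else sample(ok, 1)
    free[s:(s + len - 1L)] <- FALSE
    starts[i] <- s - 1L
  }
  starts
}

#' Generate a synthetic tagged corpus
#'
#' Draws sentences over a controlled vocabulary with planted entity
#' mentions, splits them into disjoint train/dev/test sets, and renders the
#' same sentences as PubTator documents (five sentences per document, the
#' first as title). Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `train`, `dev`, `test` (lists of
#'   [tagged_sentence()]), `documents` (list of `pubtator_document`
#'   covering all sentences in order), `lexicons`, and `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  lx <- .synth_lexicons(config)
  .stream(config$seed, "sentences")
  n_types <- length(config$types)
  sentences <- vector("list", config$n_sentences)
  for (si in seq_len(config$n_sentences)) {
    n <- sample(config$sent_len_range[1]:config$sent_len_range[2], 1)
    m <- stats::rpois(1, config$density)
    men <- .empty_mentions()
    toks <- rep(NA_character_, n)
    if (m > 0) {
      tys <- config$types[sample.int(n_types, m, replace = TRUE)]
      eix <- sample.int(config$lexicon_size, m, replace = TRUE)
      entry <- lapply(seq_len(m), function(i) lx$lexicons[[tys[i]]][[eix[i]]])
      lens <- lengths(entry)
      starts <- .place_spans(n, lens)
      keep <- !is.na(starts)
      for (i in which(keep))
        toks[(starts[i] + 1L):(starts[i] + lens[i])] <- entry[[i]]
      if (any(keep))
        men <- mentions(tys[keep], starts[keep], starts[keep] + lens[keep],
                        vapply(entry[keep], paste, character(1),
                               collapse = " "))
      # cue word immediately before a mention (when that slot is free)
      for (i in which(keep)) {
        pos <- starts[i]  # 0-based start; cue goes at token index pos
        if (pos >= 1L && is.na(toks[pos]) && stats::runif(1) < 0.7)
          toks[pos] <- lx$cues[sample.int(length(lx$cues), 1)]
      }
    }
    # fill the rest: mostly general vocabulary, occasionally an ambiguous
    # entity surface form emitted as plain text
    holes <- which(is.na(toks))
    i <- 1L
    while (i <= length(holes)) {
      pos <- holes[i]
      placed <- FALSE
      after_cue <- pos > 1L && !is.na(toks[pos - 1L]) &&
        toks[pos - 1L] %in% lx$cues
      if (!after_cue && stats::runif(1) < 0.25 * (config$ambiguity > 0)) {
        ty <- config$types[sample.int(n_types, 1)]
        amb_ix <- lx$ambiguous[[ty]]
        if (length(amb_ix)) {
          ent <- lx$lexicons[[ty]][[amb_ix[sample.int(length(amb_ix), 1)]]]
          len <- length(ent)
          run <- i + len - 1L
          if (run <= length(holes) &&
              holes[run] == pos + len - 1L) {  # contiguous free run
            toks[pos:(pos + len - 1L)] <- ent
            i <- i + len
            placed <- TRUE
          }
        }
      }
      if (!placed) {
        toks[pos] <- lx$vocab[sample.int(config$vocab_size, 1)]
        i <- i + 1L
      }
    }
    sentences[[si]] <- tagged_sentence(toks, mentions_to_iob(n, men))
  }
  n_tr <- round(config$split_props[["train"]] * config$n_sentences)
  n_de <- round(config$split_props[["dev"]] * config$n_sentences)
  idx_tr <- seq_len(n_tr)
  idx_de <- seq_len(n_de) + n_tr
  idx_te <- setdiff(seq_len(config$n_sentences), c(idx_tr, idx_de))
  docs <- .sentences_to_documents(sentences)
  list(train = sentences[idx_tr], dev = sentences[idx_de],
       test = sentences[idx_te], documents = docs,
       lexicons = lx, config = config)
}

# Render sentences as PubTator documents, doc_size sentences per document,
# the first sentence as title.
.sentences_to_documents <- function(sentences, doc_size = 5L) {
  groups <- split(seq_along(sentences),
                  (seq_along(sentences) - 1L) %/% doc_size)
  lapply(seq_along(groups), function(gi) {
    ix <- groups[[gi]]
    texts <- vapply(sentences[ix], function(s)
      paste(s$tokens$text, collapse = " "), character(1))
    title <- texts[1]
    abstract <- if (length(texts) > 1L) paste(texts[-1], collapse = " . ")
                else ""
    full <- paste(title, abstract)
    # character offset of each sentence within the document text
    sent_off <- cumsum(c(0L, nchar(texts) + 3L))[seq_along(texts)]
    sent_off[1] <- 0L
    if (length(texts) > 1L)
      sent_off[-1] <- nchar(title) + 1L +
        cumsum(c(0L, nchar(texts[-c(1, length(texts))]) + 3L))
    mrows <- list()
    for (k in seq_along(ix)) {
      s <- sentences[[ix[k]]]
      men <- iob_to_mentions(s$labels, s$tokens$text)
      if (!nrow(men)) next
      tok_off <- cumsum(c(0L, nchar(s$tokens$text) + 1L))
      for (j in seq_len(nrow(men))) {
        cs <- sent_off[k] + tok_off[men$token_start[j] + 1L]
        ce <- sent_off[k] + tok_off[men$token_end[j] + 1L] - 1L
        mrows[[length(mrows) + 1L]] <-
          data.frame(start = cs, end = ce,
                     text = substring(full, cs + 1L, ce),
                     type = men$type[j],
                     concept_id = paste0("SYN:", men$type[j]),
                     stringsAsFactors = FALSE)
      }
    }
    document(sprintf("SYNTH%04d", gi), title, abstract,
             if (length(mrows)) do.call(rbind, mrows) else NULL)
  })
}

#' Corrupt a gold corpus into a synthetic prediction
#'
#' Applies, per mention and independently, boundary shifts (one endpoint
#' moved by one token, keeping the span non-empty and overlapping its
#' original), entity-type swaps, and deletions, each at the stated rate.
#' This yields predictions with a known error composition against which the
#' evaluation criteria can be checked.
#'
#' @param corpus List of [tagged_sentence()] objects (the gold standard).
#' @param boundary_error_rate,type_error_rate,deletion_rate Rates in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A corrupted corpus of the same shape.
#' @export
corrupt_corpus <- function(corpus, boundary_error_rate = 0,
                           type_error_rate = 0, deletion_rate = 0,
                           seed = 1L) {
  stopifnot(boundary_error_rate >= 0, boundary_error_rate <= 1,
            type_error_rate >= 0, type_error_rate <= 1,
            deletion_rate >= 0, deletion_rate <= 1)
  all_types <- sort(unique(unlist(lapply(corpus, function(s)
    iob_to_mentions(s$labels)$type))))
  .stream(seed, "corrupt")
  lapply(corpus, function(s) {
    n <- length(s$labels)
    m <- iob_to_mentions(s$labels)
    if (!nrow(m)) return(s)
    keep <- stats::runif(nrow(m)) >= deletion_rate
    shift <- stats::runif(nrow(m)) < boundary_error_rate
    swap <- stats::runif(nrow(m)) < type_error_rate
    m <- m[keep, , drop = FALSE]
    shift <- shift[keep]; swap <- swap[keep]
    if (nrow(m)) for (i in seq_len(nrow(m))) {
      if (swap[i] && length(all_types) > 1L) {
        others <- setdiff(all_types, m$type[i])
        m$type[i] <- others[sample.int(length(others), 1)]
      }
      if (shift[i]) {
        s0 <- m$token_start[i]; e0 <- m$token_end[i]
        cand <- list(c(s0 - 1L, e0), c(s0 + 1L, e0),
                     c(s0, e0 - 1L), c(s0, e0 + 1L))
        ok <- Filter(function(se) {
          if (se[1] < 0L || se[2] > n || se[1] >= se[2]) return(FALSE)
          others <- m[-i, , drop = FALSE]
          !any(others$token_start < se[2] & others$token_end > se[1])
        }, cand)
        if (length(ok)) {
          se <- ok[[sample.int(length(ok), 1)]]
          m$token_start[i] <- se[1]; m$token_end[i] <- se[2]
        }
      }
    }
    tagged_sentence(s$tokens, mentions_to_iob(n, m))
  })
}
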