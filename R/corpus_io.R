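# Corpus input/output: tokenization, IOB <-> mention conversion, CoNLL and
# PubTator readers/writers.

# Punctuation characters that are split into their own single-character
# tokens. Fixed set: , - . ; : ( ) /
.punct_chars <- c(",", "-", ".", ";", ":", "(", ")", "/")
.token_regex <- "[^\\s,\\-.;:()/]+|[,\\-.;:()/]"

#' Tokenize a sentence
#'
#' Splits a sentence on whitespace, and additionally splits the punctuation
#' characters `, - . ; : ( ) /` into their own single-character tokens, so
#' that e.g. `"T-cell leukaemia"` becomes `"T"`, `"-"`, `"cell"`,
#' `"leukaemia"`. Character offsets into the input are recorded so that token
#' slices reconstruct the input exactly (minus whitespace).
#'
#' @param text A single character string (may be empty).
#' @return A data frame with columns `text`, `char_start`, `char_end`
#'   (0-based, end-exclusive offsets into `text`). Zero rows for empty or
#'   all-whitespace input.
#' @examples
#' tokenize("breast cancer")$text
#' tokenize("T-cell leukaemia")$text
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(text = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE)
  if (nchar(text) == 0L) return(empty)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    text = substring(text, starts, starts + lens - 1L),
    char_start = starts - 1L,
    char_end = starts + lens - 1L,
    stringsAsFactors = FALSE
  )
}

#' Construct a mention table
#'
#' A mention is a typed entity span over token indices: `token_start` is
#' 0-based inclusive, `token_end` exclusive. Mention sets are represented as
#' data frames with one row per mention.
#'
#' @param type Character vector of entity types (e.g. `"Disease"`).
#' @param token_start,token_end Integer vectors, 0-based, end-exclusive.
#' @param text Optional surface strings.
#' @return A `data.frame` with columns `type`, `token_start`, `token_end`,
#'   `text`.
#' @export
mentions <- function(type = character(), token_start = integer(),
                     token_end = integer(), text = NULL) {
  if (is.null(text)) text <- rep(NA_character_, length(type))
  df <- data.frame(type = as.character(type),
                   token_start = as.integer(token_start),
                   token_end = as.integer(token_end),
                   text = as.character(text),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$token_start >= df$token_end))
    stop("mention spans must satisfy token_start < token_end")
  df
}

.empty_mentions <- function() {
  mentions()
}

#' Construct a tagged sentence
#'
#' The unit of training and decoding: the tokens of one sentence together
#' with per-token IOB labels.
#'
#' @param tokens Either a character vector of token texts or a data frame as
#'   returned by [tokenize()].
#' @param labels Character vector of IOB labels (`"O"`, `"B-<type>"`,
#'   `"I-<type>"`), same length as `tokens`.
#' @return An object of class `tagged_sentence` with elements `tokens`
#'   (data frame) and `labels`.
#' @export
tagged_sentence <- function(tokens, labels) {
  if (is.character(tokens)) {
    tokens <- data.frame(text = tokens, char_start = NA_integer_,
                         char_end = NA_integer_, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(tokens), "text" %in% names(tokens))
  labels <- as.character(labels)
  if (nrow(tokens) != length(labels))
    stop("tokens and labels must have equal length")
  if (length(labels)) .check_iob_alphabet(labels)
  structure(list(tokens = tokens, labels = labels),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(sprintf("<tagged_sentence: %d tokens, %d mention(s)>\n",
              nrow(x$tokens), nrow(iob_to_mentions(x$labels))))
  print(data.frame(token = x$tokens$text, label = x$labels))
  invisible(x)
}

.check_iob_alphabet <- function(labels) {
  bad <- !grepl("^(O|[BI]-.+)$", labels)
  if (any(bad))
    stop("unknown IOB label(s): ", paste(unique(labels[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Convert mention spans to IOB labels
#'
#' The first token of each mention receives `B-<type>`, interior tokens
#' `I-<type>`, and all remaining tokens `O`.
#'
#' @param n_tokens Number of tokens in the sentence.
#' @param mention_df Mention table (see [mentions()]); spans must be
#'   non-overlapping and lie within `[0, n_tokens)`.
#' @return Character vector of `n_tokens` IOB labels.
#' @export
mentions_to_iob <- function(n_tokens, mention_df) {
  n_tokens <- as.integer(n_tokens)
  labels <- rep("O", n_tokens)
  if (is.null(mention_df) || nrow(mention_df) == 0L) return(labels)
  m <- mention_df[order(mention_df$token_start), , drop = FALSE]
  if (any(m$token_start < 0L) || any(m$token_end > n_tokens))
    stop("invalid annotation: mention span outside [0, n_tokens)")
  if (any(m$token_start >= m$token_end))
    stop("invalid annotation: empty mention span")
  if (nrow(m) > 1L && any(m$token_end[-nrow(m)] > m$token_start[-1L]))
    stop("invalid annotation: overlapping mentions")
  for (i in seq_len(nrow(m))) {
    s <- m$token_start[i] + 1L
    e <- m$token_end[i]
    labels[s] <- paste0("B-", m$type[i])
    if (e > s) labels[(s + 1L):e] <- paste0("I-", m$type[i])
  }
  labels
}

#' Recover mention spans from IOB labels
#'
#' Exact inverse of [mentions_to_iob()] on well-formed sequences. Malformed
#' sequences are normalized first: an `I-<type>` following `O`, or following
#' a label of a different type, is treated as beginning a new mention.
#'
#' @param labels Character vector of IOB labels.
#' @param token_texts Optional token texts used to fill the mention `text`
#'   column (joined with single spaces).
#' @return A mention table (see [mentions()]).
#' @export
iob_to_mentions <- function(labels, token_texts = NULL) {
  .check_iob_alphabet(labels)
  n <- length(labels)
  type <- character(); ts <- integer(); te <- integer()
  cur_type <- NULL; cur_start <- NA_integer_
  close_cur <- function(end) {
    if (!is.null(cur_type)) {
      type[[length(type) + 1L]] <<- cur_type
      ts[[length(ts) + 1L]] <<- cur_start
      te[[length(te) + 1L]] <<- end
    }
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") {
      close_cur(i - 1L); cur_type <- NULL
    } else {
      pre <- substr(lab, 1L, 1L)
      typ <- substr(lab, 3L, nchar(lab))
      starts_new <- pre == "B" || is.null(cur_type) || typ != cur_type
      if (starts_new) {
        close_cur(i - 1L)
        cur_type <- typ; cur_start <- i - 1L
      }
    }
  }
  close_cur(n)
  out <- mentions(type, ts, te)
  if (!is.null(token_texts) && nrow(out)) {
    out$text <- vapply(seq_len(nrow(out)), function(i) {
      paste(token_texts[(out$token_start[i] + 1L):out$token_end[i]],
            collapse = " ")
    }, character(1))
  }
  out
}

#' Normalize an IOB label sequence
#'
#' Rewrites any `I-<type>` that follows `O` or a different type as
#' `B-<type>`, yielding a well-formed sequence.
#'
#' @param labels Character vector of IOB labels.
#' @return Normalized character vector.
#' @export
normalize_iob <- function(labels) {
  m <- iob_to_mentions(labels)
  mentions_to_iob(length(labels), m)
}

#' Read a CoNLL-style corpus
#'
#' One token per line as `token<TAB>label`, blank line between sentences.
#'
#' @param path Path to a UTF-8 text file.
#' @return A list of [tagged_sentence()] objects.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- list()
  toks <- character(); labs <- character()
  flush <- function() {
    if (length(toks)) {
      sentences[[length(sentences) + 1L]] <<- tagged_sentence(toks, labs)
      toks <<- character(); labs <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("parse error at line %d of %s: expected 2 tab-separated fields, got %d",
                   i, path, length(parts)))
    toks[[length(toks) + 1L]] <- parts[1]
    labs[[length(labs) + 1L]] <- parts[2]
  }
  flush()
  sentences
}

#' Write a CoNLL-style corpus
#'
#' @param sentences A list of [tagged_sentence()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    paste(paste(s$tokens$text, s$labels, sep = "\t"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path, sep = "\n\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a document
#'
#' A PubTator-style document: a title, an abstract and a set of
#' character-offset entity mentions. Offsets are 0-based, end-exclusive,
#' over `paste(title, abstract)` (title, one space, abstract).
#'
#' @param doc_id Document identifier string.
#' @param title,abstract Character strings.
#' @param char_mentions Data frame with columns `start`, `end`, `text`,
#'   `type`, `concept_id`. Each `text` must equal the corresponding slice of
#'   the document text.
#' @return An object of class `pubtator_document`.
#' @export
document <- function(doc_id, title, abstract, char_mentions = NULL) {
  if (is.null(char_mentions))
    char_mentions <- data.frame(start = integer(), end = integer(),
                                text = character(), type = character(),
                                concept_id = character(),
                                stringsAsFactors = FALSE)
  full <- paste(title, abstract)
  if (nrow(char_mentions)) {
    sl <- substring(full, char_mentions$start + 1L, char_mentions$end)
    bad <- sl != char_mentions$text
    if (any(bad))
      stop(sprintf("offset mismatch in document %s: mention '%s' != slice '%s'",
                   doc_id, char_mentions$text[which(bad)[1]],
                   sl[which(bad)[1]]))
  }
  structure(list(doc_id = as.character(doc_id), title = title,
                 abstract = abstract, mentions = char_mentions),
            class = "pubtator_document")
}

#' Read a PubTator-format file
#'
#' Documents are blocks of `id|t|title`, `id|a|abstract` lines followed by
#' tab-delimited mention lines `id, start, end, text, type, concept_id`,
#' separated by blank lines. The concept id is preserved verbatim but unused
#' by the model.
#'
#' @param path Path to a PubTator text file.
#' @return A list of `pubtator_document` objects.
#' @export
read_pubtator <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      docs[[length(docs) + 1L]] <<- document(cur$id, cur$title, cur$abstract,
                                             do.call(rbind, cur$mrows))
      cur <<- NULL
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { flush(); next }
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      flush()
      id <- sub("\\|.*$", "", ln)
      cur <- list(id = id, title = sub("^[^|]+\\|t\\|", "", ln),
                  abstract = "", mrows = list())
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      if (is.null(cur)) stop(sprintf("parse error at line %d: abstract before title", i))
      cur$abstract <- sub("^[^|]+\\|a\\|", "", ln)
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 6L)
        stop(sprintf("parse error at line %d of %s: expected 6 tab-separated fields, got %d",
                     i, path, length(parts)))
      if (is.null(cur)) stop(sprintf("parse error at line %d: mention before title", i))
      cur$mrows[[length(cur$mrows) + 1L]] <-
        data.frame(start = as.integer(parts[2]), end = as.integer(parts[3]),
                   text = parts[4], type = parts[5], concept_id = parts[6],
                   stringsAsFactors = FALSE)
    }
  }
  flush()
  docs
}

#' Write documents in PubTator format
#'
#' @param docs A list of `pubtator_document` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(docs, path) {
  blocks <- vapply(docs, function(d) {
    out <- c(paste0(d$doc_id, "|t|", d$title),
             paste0(d$doc_id, "|a|", d$abstract))
    if (nrow(d$mentions)) {
      out <- c(out, paste(d$doc_id, d$mentions$start, d$mentions$end,
                          d$mentions$text, d$mentions$type,
                          d$mentions$concept_id, sep = "\t"))
    }
    paste(out, collapse = "\n")
  }, character(1))
  writeLines(blocks, path, sep = "\n\n", useBytes = TRUE)
  invisible(path)
}

# Sentence boundaries: positions after ". " where the next character is an
# uppercase letter or a digit. A boundary that would cut a mention is
# suppressed so annotation integrity is preserved.
.sentence_bounds <- function(text, char_mentions) {
  m <- gregexpr("\\. (?=[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  p <- as.integer(m) - 1L  # 0-based index of the period
  keep <- vapply(p, function(pp) {
    # next sentence starts at pp + 2 (0-based); suppress if a mention
    # intersects both sides of the cut or contains the period/space
    !any(char_mentions$start < pp + 2L & char_mentions$end > pp)
  }, logical(1))
  p[keep]
}

#' Split a document into tagged sentences
#'
#' The title becomes one sentence; the abstract is split on `". "` followed
#' by an uppercase letter or digit (a split that would cut through a mention
#' is suppressed). Each sentence is tokenized and the document's
#' character-offset mentions are projected onto token spans, then rendered as
#' IOB labels. A mention whose character span starts or ends strictly inside
#' a token is snapped outward to whole-token boundaries; overlapping gold
#' mentions are resolved by keeping the longer one (ties: earlier start).
#'
#' @param doc A `pubtator_document`.
#' @return A list of [tagged_sentence()] objects with an attribute
#'   `snap_warnings` giving the number of boundary snaps performed.
#' @export
document_to_sentences <- function(doc) {
  full <- paste(doc$title, doc$abstract)
  title_end <- nchar(doc$title)
  bounds <- .sentence_bounds(full, doc$mentions)
  # sentence start offsets (0-based): title, abstract, then after each ". "
  starts <- sort(unique(c(0L, title_end + 1L, bounds + 2L)))
  ends <- c(starts[-1L], nchar(full))
  # drop the separator space/period-space from each sentence's tail
  snaps <- 0L
  out <- list()
  for (si in seq_along(starts)) {
    s0 <- starts[si]; e0 <- ends[si]
    sent_text <- substring(full, s0 + 1L, e0)
    toks <- tokenize(sent_text)
    if (nrow(toks) == 0L) next
    toks$char_start <- toks$char_start + s0   # offsets into the document
    toks$char_end <- toks$char_end + s0
    dm <- doc$mentions[doc$mentions$start >= s0 & doc$mentions$end <= e0, ,
                       drop = FALSE]
    tok_m <- .empty_mentions()
    if (nrow(dm)) {
      proj <- lapply(seq_len(nrow(dm)), function(i) {
        hit <- which(toks$char_end > dm$start[i] & toks$char_start < dm$end[i])
        if (!length(hit)) return(NULL)
        a <- min(hit); b <- max(hit)
        snapped <- toks$char_start[a] != dm$start[i] ||
          toks$char_end[b] != dm$end[i]
        list(row = mentions(dm$type[i], a - 1L, b, dm$text[i]),
             snapped = snapped)
      })
      proj <- proj[!vapply(proj, is.null, logical(1))]
      if (length(proj)) {
        snaps <- snaps + sum(vapply(proj, `[[`, logical(1), "snapped"))
        tok_m <- do.call(rbind, lapply(proj, `[[`, "row"))
        tok_m <- .resolve_overlaps(tok_m)
      }
    }
    toks$char_start <- toks$char_start - s0
    toks$char_end <- toks$char_end - s0
    out[[length(out) + 1L]] <-
      tagged_sentence(toks, mentions_to_iob(nrow(toks), tok_m))
  }
  attr(out, "snap_warnings") <- snaps
  out
}

# Keep-longer (ties: earlier start) flattening of overlapping mention sets.
.resolve_overlaps <- function(m) {
  if (nrow(m) < 2L) return(m)
  len <- m$token_end - m$token_start
  ord <- order(-len, m$token_start)
  kept <- m[0, ]
  for (i in ord) {
    ov <- kept$token_start < m$token_end[i] & kept$token_end > m$token_start[i]
    if (!any(ov)) kept <- rbind(kept, m[i, ])
  }
  kept[order(kept$token_start), , drop = FALSE]
}
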