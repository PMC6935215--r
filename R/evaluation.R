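# The three matching criteria (strict, partial, IOB token), precision /
# recall / F, multi-trial robustness summaries and the cross-corpus harness.
# Counts are micro-averaged: tallies are summed globally before the
# precision/recall/F formulas are applied.

.check_no_overlap <- function(m, what) {
  if (nrow(m) < 2L) return(invisible(TRUE))
  m <- m[order(m$token_start), , drop = FALSE]
  if (any(m$token_end[-nrow(m)] > m$token_start[-1L]))
    stop("invalid input: overlapping mentions in ", what)
  invisible(TRUE)
}

# Tally container: data frame of per-type tp/fp/fn; overall = column sums.
eval_counts <- function(by_type) {
  if (is.null(by_type) || nrow(by_type) == 0L)
    by_type <- data.frame(type = character(), tp = integer(),
                          fp = integer(), fn = integer(),
                          stringsAsFactors = FALSE)
  structure(list(by_type = by_type,
                 overall = c(tp = sum(by_type$tp), fp = sum(by_type$fp),
                             fn = sum(by_type$fn))),
            class = "eval_counts")
}

.merge_counts <- function(counts_list) {
  all_types <- sort(unique(unlist(lapply(counts_list,
                                         function(x) x$by_type$type))))
  by <- data.frame(type = all_types, tp = rep(0L, length(all_types)),
                   fp = rep(0L, length(all_types)),
                   fn = rep(0L, length(all_types)), stringsAsFactors = FALSE)
  for (x in counts_list) {
    i <- match(x$by_type$type, all_types)
    by$tp[i] <- by$tp[i] + x$by_type$tp
    by$fp[i] <- by$fp[i] + x$by_type$fp
    by$fn[i] <- by$fn[i] + x$by_type$fn
  }
  eval_counts(by)
}

.counts_by_type <- function(gold, pred, tally_fn) {
  types <- sort(unique(c(gold$type, pred$type)))
  rows <- lapply(types, function(ty) {
    g <- gold[gold$type == ty, , drop = FALSE]
    p <- pred[pred$type == ty, , drop = FALSE]
    tp <- tally_fn(g, p)
    data.frame(type = ty, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp,
               stringsAsFactors = FALSE)
  })
  eval_counts(do.call(rbind, rows))
}

#' Strict mention matching
#'
#' A predicted mention is a true positive only if its start and end
#' boundaries and its type are identical to a gold mention's.
#'
#' @param gold,pred Mention tables (see [mentions()]) for one sentence or
#'   document; each must be internally non-overlapping.
#' @return An `eval_counts` object with per-type and overall TP/FP/FN.
#' @export
match_strict <- function(gold, pred) {
  .check_no_overlap(gold, "gold"); .check_no_overlap(pred, "pred")
  .counts_by_type(gold, pred, function(g, p) {
    length(intersect(paste(g$token_start, g$token_end),
                     paste(p$token_start, p$token_end)))
  })
}

#' Partial (overlap) mention matching
#'
#' A prediction may match a gold mention when their token spans overlap and
#' their types are equal; matched pairs are counted one-to-one under a
#' maximum-cardinality matching, so no mention is counted twice.
#'
#' @inheritParams match_strict
#' @return An `eval_counts` object.
#' @export
match_partial <- function(gold, pred) {
  .check_no_overlap(gold, "gold"); .check_no_overlap(pred, "pred")
  .counts_by_type(gold, pred, function(g, p) {
    # Both sets are non-overlapping intervals: the earliest-end greedy sweep
    # attains the maximum matching.
    g <- g[order(g$token_start), , drop = FALSE]
    p <- p[order(p$token_start), , drop = FALSE]
    i <- 1L; j <- 1L; tp <- 0L
    while (i <= nrow(g) && j <= nrow(p)) {
      if (g$token_start[i] < p$token_end[j] &&
          p$token_start[j] < g$token_end[i]) {
        tp <- tp + 1L; i <- i + 1L; j <- j + 1L
      } else if (g$token_end[i] <= p$token_start[j]) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
    tp
  })
}

#' IOB token-level matching
#'
#' Token-by-token comparison of gold and predicted tags, excluding
#' positions where both are `"O"`: TP are positions where the tags agree
#' and the gold is not `"O"`; FN are gold non-`"O"` positions with a
#' differing prediction; FP are predicted non-`"O"` tags that differ from
#' the gold.
#'
#' @param gold_labels,pred_labels Equal-length character vectors of IOB
#'   labels.
#' @return An `eval_counts` object (per-type: TP/FN attributed to the gold
#'   tag's type, FP to the predicted tag's type).
#' @export
match_iob_tokens <- function(gold_labels, pred_labels) {
  if (length(gold_labels) != length(pred_labels))
    stop("gold and predicted label sequences must have equal length")
  .check_iob_alphabet(c(gold_labels, pred_labels))
  tag_type <- function(l) ifelse(l == "O", NA_character_,
                                 substr(l, 3L, nchar(l)))
  gt <- tag_type(gold_labels); pt <- tag_type(pred_labels)
  agree <- gold_labels == pred_labels
  types <- sort(unique(c(gt[!is.na(gt)], pt[!is.na(pt)])))
  rows <- lapply(types, function(ty) {
    data.frame(type = ty,
               tp = sum(agree & !is.na(gt) & gt == ty),
               fp = sum(!agree & !is.na(pt) & pt == ty),
               fn = sum(!agree & !is.na(gt) & gt == ty),
               stringsAsFactors = FALSE)
  })
  eval_counts(do.call(rbind, rows))
}

#' Round half away from zero
#'
#' Presentation rounding for percentages (unlike [round()], 0.005 rounds
#' up).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Precision, recall and F-score from tallies
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and `f = 2pr/(p+r)`, with the
#' conventions that precision is 0 when `TP+FP = 0`, recall is 0 when
#' `TP+FN = 0`, and
#' `f = 0` when `p + r = 0`.
#'
#' @param counts An `eval_counts` object, or a numeric vector with elements
#'   `tp`, `fp`, `fn`.
#' @return An object of class `clstm_metrics`: list with `p`, `r`, `f` as
#'   fractions in `[0, 1]`. Use [metrics_percent()] for the 2-decimal
#'   percentage rendering.
#' @export
prf <- function(counts) {
  cc <- if (inherits(counts, "eval_counts")) counts$overall else counts
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(p = p, r = r, f = f), class = "clstm_metrics")
}

#' Render metrics as percentages
#'
#' @param m A `clstm_metrics` object.
#' @param digits Decimal places (half-up rounding).
#' @return Named numeric vector `p`, `r`, `f` on the 0-100 scale.
#' @export
metrics_percent <- function(m, digits = 2L) {
  c(p = round_half_up(100 * m$p, digits),
    r = round_half_up(100 * m$r, digits),
    f = round_half_up(100 * m$f, digits))
}

#' @export
print.clstm_metrics <- function(x, ...) {
  v <- metrics_percent(x)
  cat(sprintf("p = %.2f%%  r = %.2f%%  f = %.2f%%\n", v["p"], v["r"], v["f"]))
  invisible(x)
}

.sentence_mentions <- function(s) iob_to_mentions(s$labels)

#' Evaluate a predicted corpus against gold
#'
#' Micro-averaged over all sentences: per-sentence tallies are summed
#' globally before precision/recall/F. Gold and prediction must be aligned
#' sentence-by-sentence (same sentence count and lengths).
#'
#' @param gold,pred Lists of [tagged_sentence()] objects.
#' @param mode `"strict"`, `"partial"` or `"iob"`.
#' @return A list with `metrics` (overall [prf()]), `counts` and `by_type`
#'   (per-type metrics data frame).
#' @export
evaluate_corpus <- function(gold, pred, mode = c("strict", "partial", "iob")) {
  mode <- match.arg(mode)
  if (length(gold) != length(pred))
    stop("alignment error: gold and pred have different sentence counts")
  nlg <- vapply(gold, function(s) length(s$labels), integer(1))
  nlp <- vapply(pred, function(s) length(s$labels), integer(1))
  if (any(nlg != nlp))
    stop("alignment error: sentence lengths differ at sentence ",
         which(nlg != nlp)[1])
  per <- lapply(seq_along(gold), function(i) {
    switch(mode,
      strict = match_strict(.sentence_mentions(gold[[i]]),
                            .sentence_mentions(pred[[i]])),
      partial = match_partial(.sentence_mentions(gold[[i]]),
                              .sentence_mentions(pred[[i]])),
      iob = match_iob_tokens(gold[[i]]$labels, pred[[i]]$labels))
  })
  counts <- .merge_counts(per)
  by_type <- do.call(rbind, lapply(seq_len(nrow(counts$by_type)), function(i) {
    row <- counts$by_type[i, ]
    m <- prf(c(tp = row$tp, fp = row$fp, fn = row$fn))
    data.frame(type = row$type, tp = row$tp, fp = row$fp, fn = row$fn,
               p = m$p, r = m$r, f = m$f, stringsAsFactors = FALSE)
  }))
  list(metrics = prf(counts), counts = counts, by_type = by_type)
}

#' Average metrics over independent trials
#'
#' Arithmetic mean of precision, recall and F across repeated training
#' runs, as used to report robustness to random initialization.
#'
#' @param trials A list of `clstm_metrics` objects (>= 1).
#' @return A `clstm_metrics` object of means.
#' @export
robustness_summary <- function(trials) {
  if (!length(trials)) stop("invalid argument: at least one trial required")
  structure(list(p = mean(vapply(trials, `[[`, numeric(1), "p")),
                 r = mean(vapply(trials, `[[`, numeric(1), "r")),
                 f = mean(vapply(trials, `[[`, numeric(1), "f"))),
            class = "clstm_metrics")
}

#' Cross-corpus evaluation
#'
#' Evaluates a model trained on one corpus against the gold annotation of
#' another, after mapping the test corpus's entity types into the model's
#' label space (e.g. restricting a disease+chemical corpus to its disease
#' mentions). Gold mentions of unmapped types are dropped (and counted);
#' predictions are made by the model as-is.
#'
#' @param model A trained `clstm_model`.
#' @param test_corpus List of [tagged_sentence()] objects.
#' @param type_map Named character vector sending test-corpus types to
#'   model types (e.g. `c(Disease = "Disease")`); types absent from the map
#'   are dropped from the gold standard.
#' @param mode Matching mode, as in [evaluate_corpus()].
#' @return As [evaluate_corpus()], plus `dropped_gold` (count of gold
#'   mentions removed by the mapping).
#' @export
cross_corpus_eval <- function(model, test_corpus, type_map,
                              mode = c("strict", "partial", "iob")) {
  mode <- match.arg(mode)
  dropped <- 0L
  gold <- lapply(test_corpus, function(s) {
    m <- iob_to_mentions(s$labels)
    keep <- m$type %in% names(type_map)
    dropped <<- dropped + sum(!keep)
    m <- m[keep, , drop = FALSE]
    m$type <- unname(type_map[m$type])
    tagged_sentence(s$tokens, mentions_to_iob(length(s$labels), m))
  })
  if (sum(vapply(gold, function(s) sum(s$labels != "O"), integer(1))) == 0L)
    warning("type mapping removed every gold mention; recall is 0 by convention")
  pred <- predict_clstm(model, gold)
  out <- evaluate_corpus(gold, pred, mode)
  out$dropped_gold <- dropped
  out
}
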