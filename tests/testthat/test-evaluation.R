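test_that("strict matching requires identical boundaries and type", {
  g <- mentions(c("Disease", "Chemical"), c(1, 5), c(3, 6))
  same <- match_strict(g, g)
  expect_equal(unname(same$overall), c(2L, 0L, 0L))
  off <- mentions(c("Disease", "Chemical"), c(2, 5), c(4, 6))
  c1 <- match_strict(g, off)
  expect_equal(unname(c1$overall), c(1L, 1L, 1L))
  # boundary off by one only
  c2 <- match_strict(mentions("Disease", 1, 3), mentions("Disease", 1, 4))
  expect_equal(unname(c2$overall), c(0L, 1L, 1L))
  # same span, different type
  c3 <- match_strict(mentions("Disease", 1, 3), mentions("Chemical", 1, 3))
  expect_equal(unname(c3$overall), c(0L, 1L, 1L))
  expect_error(match_strict(mentions(c("A", "A"), c(0, 1), c(2, 3)),
                            mentions()), "overlapping")
})

test_that("partial matching counts overlapping same-type pairs one-to-one", {
  # prediction inside the gold span
  c1 <- match_partial(mentions("Disease", 0, 4), mentions("Disease", 1, 2))
  expect_equal(unname(c1$overall), c(1L, 0L, 0L))
  # one prediction overlapping two golds: only one TP under one-to-one
  c2 <- match_partial(mentions(c("Disease", "Disease"), c(0, 3), c(2, 5)),
                      mentions("Disease", 1, 4))
  expect_equal(unname(c2$overall), c(1L, 0L, 1L))
  # overlap but wrong type
  c3 <- match_partial(mentions("Disease", 0, 3), mentions("Chemical", 1, 2))
  expect_equal(unname(c3$overall), c(0L, 1L, 1L))
})

test_that("greedy partial matching attains the maximum bipartite matching", {
  skip_if_not_installed("igraph")
  set.seed(301)
  for (trial in 1:200) {
    n <- sample(4:14, 1)
    g <- random_mention_set(n, types = "T")
    p <- random_mention_set(n, types = "T")
    got <- match_partial(g, p)$overall[["tp"]]
    if (nrow(g) == 0 || nrow(p) == 0) {
      expect_equal(got, 0L)
      next
    }
    ov <- outer(seq_len(nrow(g)), seq_len(nrow(p)), Vectorize(function(i, j)
      g$token_start[i] < p$token_end[j] && p$token_start[j] < g$token_end[i]))
    gr <- igraph::graph_from_biadjacency_matrix(ov)
    want <- igraph::max_bipartite_match(gr)$matching_size
    expect_equal(got, as.integer(want))
  }
})

test_that("IOB token matching follows the stated counting rules", {
  c1 <- match_iob_tokens(c("B-D", "I-D", "O", "B-D"), c("B-D", "I-D", "O", "B-D"))
  expect_equal(unname(c1$overall), c(3L, 0L, 0L))
  c2 <- match_iob_tokens(c("B-D", "I-D"), c("B-D", "O"))
  expect_equal(unname(c2$overall), c(1L, 0L, 1L))
  c3 <- match_iob_tokens(c("O", "O"), c("B-D", "O"))
  expect_equal(unname(c3$overall), c(0L, 1L, 0L))
  expect_error(match_iob_tokens(c("O"), c("O", "O")), "equal length")
})

test_that("IOB token counts agree with an independent tally on random pairs", {
  set.seed(302)
  pool <- c("O", "B-D", "I-D", "B-C", "I-C")
  for (trial in 1:1000) {
    n <- sample(1:12, 1)
    g <- sample(pool, n, replace = TRUE)
    p <- sample(pool, n, replace = TRUE)
    expect_equal(match_iob_tokens(g, p)$overall, ref_iob_tally(g, p))
  }
})

test_that("precision/recall/F follow the harmonic-mean formula and conventions", {
  # printed table row: p = 78.91, r = 82.60 gives f = 80.71
  m <- structure(list(p = 0.7891, r = 0.8260,
                      f = 2 * 0.7891 * 0.8260 / (0.7891 + 0.8260)),
                 class = "clstm_metrics")
  expect_equal(metrics_percent(m)[["f"]], 80.71)
  # equal p and r collapse to that value
  m2 <- prf(c(tp = 3, fp = 1, fn = 1))
  expect_equal(m2$f, m2$p)
  expect_equal(prf(c(tp = 0, fp = 0, fn = 0))[c("p", "r", "f")],
               list(p = 0, r = 0, f = 0))
  expect_equal(prf(c(tp = 0, fp = 2, fn = 1))$f, 0)
  # rounding is half-up at 2 decimals
  expect_equal(round_half_up(85.305, 2), 85.31)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("conservation and symmetry laws hold for mention-level matching", {
  set.seed(303)
  for (trial in 1:200) {
    n <- sample(3:12, 1)
    g <- random_mention_set(n)
    p <- random_mention_set(n)
    for (fn in list(match_strict, match_partial)) {
      cc <- fn(g, p)$overall
      expect_equal(cc[["tp"]] + cc[["fn"]], nrow(g))
      expect_equal(cc[["tp"]] + cc[["fp"]], nrow(p))
      sw <- fn(p, g)$overall
      expect_equal(sw[["tp"]], cc[["tp"]])
      expect_equal(sw[["fp"]], cc[["fn"]])
      expect_equal(sw[["fn"]], cc[["fp"]])
      mm <- prf(cc); ms <- prf(sw)
      expect_equal(mm$p, ms$r)
      expect_equal(mm$f, ms$f, tolerance = 1e-12)
    }
    # strict matches are partial matches
    expect_lte(match_strict(g, p)$overall[["tp"]],
               match_partial(g, p)$overall[["tp"]])
  }
})

test_that("corpus evaluation micro-averages and detects misalignment", {
  set.seed(304)
  gold <- random_tagged_corpus(30)
  expect_equal(evaluate_corpus(gold, gold, "strict")$metrics$f, 1)
  expect_equal(evaluate_corpus(gold, gold, "partial")$metrics$f, 1)
  expect_equal(evaluate_corpus(gold, gold, "iob")$metrics$f, 1)
  allO <- lapply(gold, function(s)
    tagged_sentence(s$tokens, rep("O", length(s$labels))))
  ev <- evaluate_corpus(gold, allO, "strict")
  expect_equal(ev$metrics$r, 0)
  # strict F never exceeds partial F
  pred <- corrupt_corpus(gold, boundary_error_rate = 0.4, seed = 9)
  fs <- evaluate_corpus(gold, pred, "strict")$metrics$f
  fp <- evaluate_corpus(gold, pred, "partial")$metrics$f
  expect_lte(fs, fp)
  # micro-averaging: summed counts, not averaged per-sentence scores
  cs <- evaluate_corpus(gold, pred, "strict")$counts$overall
  per <- lapply(seq_along(gold), function(i)
    match_strict(iob_to_mentions(gold[[i]]$labels),
                 iob_to_mentions(pred[[i]]$labels))$overall)
  expect_equal(cs, Reduce(`+`, per))
  expect_error(evaluate_corpus(gold, gold[-1], "strict"), "alignment")
  bad <- gold
  bad[[3]] <- tagged_sentence("x", "O")
  expect_error(evaluate_corpus(gold, bad, "strict"), "alignment")
})

test_that("per-type tallies sum to the overall tallies", {
  set.seed(305)
  gold <- random_tagged_corpus(40)
  pred <- corrupt_corpus(gold, boundary_error_rate = 0.3,
                         type_error_rate = 0.3, deletion_rate = 0.1,
                         seed = 11)
  for (mode in c("strict", "partial", "iob")) {
    ev <- evaluate_corpus(gold, pred, mode)
    expect_equal(sum(ev$by_type$tp), unname(ev$counts$overall["tp"]))
    expect_equal(sum(ev$by_type$fp), unname(ev$counts$overall["fp"]))
    expect_equal(sum(ev$by_type$fn), unname(ev$counts$overall["fn"]))
  }
})

test_that("trial averages reproduce printed robustness summaries", {
  # five independent trials reported for the word+char model, NCBI corpus
  trials <- Map(function(p, r, f)
    structure(list(p = p / 100, r = r / 100, f = f / 100),
              class = "clstm_metrics"),
    c(84.73, 84.43, 86.18, 85.56, 84.62),
    c(86.67, 85.83, 84.48, 85.21, 85.42),
    c(85.68, 85.12, 85.32, 85.39, 85.02))
  avg <- metrics_percent(robustness_summary(trials))
  expect_equal(unname(avg), c(85.10, 85.52, 85.31))
  one <- robustness_summary(trials[1])
  expect_equal(one$f, trials[[1]]$f)
  same <- robustness_summary(rep(trials[2], 4))
  expect_equal(same$p, trials[[2]]$p)
  expect_error(robustness_summary(list()), "at least one")
})

test_that("cross-corpus evaluation maps and restricts entity types", {
  set.seed(306)
  corp <- generate_corpus(synth_config(n_sentences = 120, seed = 5,
                                       density = 1.2))
  cfg <- tiny_config(seed = 8)
  m <- train_clstm(corp$train, NULL, cfg, epochs = 2, verbose = FALSE)
  test <- corp$test
  # identity mapping over all types equals plain evaluation
  full_map <- setNames(m$types, m$types)
  cc <- cross_corpus_eval(m, test, full_map)
  pred <- predict_clstm(m, test)
  expect_equal(cc$metrics$f, evaluate_corpus(test, pred, "strict")$metrics$f)
  expect_equal(cc$dropped_gold, 0L)
  # restricting to one type equals evaluating the single-type sub-corpus
  one <- cross_corpus_eval(m, test, c(Disease = "Disease"))
  sub <- lapply(test, function(s) {
    mm <- iob_to_mentions(s$labels)
    mm <- mm[mm$type == "Disease", , drop = FALSE]
    tagged_sentence(s$tokens, mentions_to_iob(length(s$labels), mm))
  })
  pred_sub <- predict_clstm(m, sub)
  by <- evaluate_corpus(sub, pred_sub, "strict")$by_type
  dis <- by[by$type == "Disease", ]
  one_dis <- one$by_type[one$by_type$type == "Disease", ]
  expect_equal(one_dis$tp, dis$tp)
  expect_equal(one_dis$fn, dis$fn)
  expect_gt(one$dropped_gold, 0L)
  # mapping that drops everything: recall 0 by convention, with a warning
  expect_warning(none <- cross_corpus_eval(m, test, c(Nope = "Disease")),
                 "removed every gold mention")
  expect_equal(none$metrics$r, 0)
})
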