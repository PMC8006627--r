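test_that("precision/recall/F1 arithmetic and degenerate conventions", {
  m <- prf(3, 1, 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_false(m$degenerate)

  z <- prf(0, 0, 0)
  expect_equal(unlist(z[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_true(z$degenerate)

  p <- prf(5, 0, 0)
  expect_equal(unlist(p[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_error(prf(-1, 0, 0), "non-negative")
})

test_that("prf agrees with an expansion-based oracle on random counts", {
  # oracle: expand counts into label vectors, score with base table()
  oracle <- function(tp, fp, fn) {
    gold <- c(rep(1, tp + fn), rep(0, fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(1, fp))
    p <- if (sum(pred) > 0) sum(gold & pred) / sum(pred) else 0
    r <- if (sum(gold) > 0) sum(gold & pred) / sum(gold) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  set.seed(70)
  for (i in 1:100) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    got <- unlist(prf(tp, fp, fn)[c("precision", "recall", "f1")])
    expect_equal(unname(got), oracle(tp, fp, fn))
  }
})

test_that("token confusion separates category and binary layers", {
  g <- tibble::tibble(token = c("Ana", "hoy"), tag = c("B-NAME", "O"))
  p <- tibble::tibble(token = c("Ana", "hoy"), tag = c("B-FECHA", "O"))
  cc <- token_confusion(g, p)
  expect_equal(cc$fn[cc$label == "NAME"], 1L)
  expect_equal(cc$fp[cc$label == "FECHA"], 1L)
  expect_equal(cc$tp[cc$label == "identifying"], 1L)  # cross-category TP

  # CAB is not identifying: a missed header is a category FN only
  g <- tibble::tibble(token = "INFORME", tag = "B-CAB")
  p <- tibble::tibble(token = "INFORME", tag = "O")
  cc <- token_confusion(g, p)
  expect_equal(cc$fn[cc$label == "CAB"], 1L)
  bin <- cc[cc$label == "identifying", ]
  expect_equal(bin$tp + bin$fp + bin$fn, 0L)

  # identical sequences: zero FP/FN everywhere
  g <- tibble::tibble(token = c("a", "b"), tag = c("B-NUM", "I-NUM"))
  cc <- token_confusion(g, g)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  expect_equal(cc$tp[cc$label == "NUM"], 2L)  # B/I prefixes ignored

  expect_error(
    token_confusion(g, tibble::tibble(token = "a", tag = "O")),
    "align"
  )
})

test_that("global metric counts identifying tokens across categories", {
  mk <- function(tags) {
    tibble::tibble(token = sprintf("t%d", seq_along(tags)), tag = tags)
  }
  gold <- mk(c(rep("B-NAME", 4), rep("B-FECHA", 3), rep("B-NUM", 3),
               "O", "O"))
  # 9 of 10 identifying tokens recovered (one as the wrong category),
  # plus one spurious
  pred <- mk(c(rep("B-NAME", 3), "O", rep("B-FECHA", 2), "B-LOC",
               rep("B-NUM", 3), "B-NAME", "O"))
  m <- global_deid(gold, pred)
  expect_equal(m$recall, 0.9)
  expect_equal(m$precision, 0.9)

  all_o <- mk(rep("O", 12))
  m <- global_deid(gold, all_o)
  expect_equal(m$recall, 0)
  expect_true(m$degenerate)

  expect_equal(global_deid(gold, gold)$f1, 1)
})

test_that("corpus evaluation micro-averages counts in fixed row order", {
  # two documents with NAME counts (1,0,1) and (1,1,0)
  corp <- deid_corpus(
    c("a", "b"), c("Ana Gil aqui", "Eva hoy"),
    spans = list(
      entity_spans(c(0, 4), c(3, 7), c("NAME", "NAME"), c("Ana", "Gil")),
      entity_spans(0, 3, "NAME", "Eva")
    )
  )
  pred <- list(
    entity_spans(0, 3, "NAME", "Ana"),                 # misses Gil
    entity_spans(c(0, 4), c(3, 7), c("NAME", "NAME"), c("Eva", "hoy"))
  )
  ev <- evaluate_corpus(pred, corp)
  td <- tidy(ev)
  expect_equal(td$label, c(deid_labels(), "identifying"))
  nm <- td[td$label == "NAME", ]
  expect_equal(nm$tp, 2L)
  expect_equal(nm$precision, 2 / 3)
  expect_equal(nm$recall, 2 / 3)

  # micro-additivity: pooled counts equal the sum of per-document counts
  ev_a <- evaluate_corpus(pred[1], corp[1, ])
  ev_b <- evaluate_corpus(pred[2], corp[2, ])
  expect_equal(tidy(ev)$tp, tidy(ev_a)$tp + tidy(ev_b)$tp)
  expect_equal(tidy(ev)$fn, tidy(ev_a)$fn + tidy(ev_b)$fn)

  # binary TP is at least the summed per-category TP
  expect_gte(td$tp[td$label == "identifying"],
             sum(td$tp[td$label %in% identifying_labels()]))

  # per-category conservation: TP + FN equals the gold token count
  gold_name_tokens <- 3L
  expect_equal(nm$tp + nm$fn, gold_name_tokens)

  g <- glance(ev)
  expect_equal(g$n_documents, 2L)
  expect_error(evaluate_corpus(pred, corp[0, ]), "empty")
})

test_that("strict span-level mode requires exact boundaries and category", {
  corp <- deid_corpus("a", "Ana Gil aqui",
                      spans = list(entity_spans(c(0, 4), c(3, 7),
                                                c("NAME", "NAME"),
                                                c("Ana", "Gil"))))
  # one exact match, one boundary error
  pred <- list(entity_spans(c(0, 4), c(3, 12), c("NAME", "NAME"),
                            c("Ana", "Gil aqui")))
  td <- tidy(evaluate_corpus(pred, corp, level = "span"))
  nm <- td[td$label == "NAME", ]
  expect_equal(nm$tp, 1L)
  expect_equal(nm$fp, 1L)
  expect_equal(nm$fn, 1L)
})

test_that("evaluation reports render to plot and file", {
  corp <- deid_corpus("a", "Ana",
                      spans = list(entity_spans(0, 3, "NAME", "Ana")))
  ev <- evaluate_corpus(list(corp$spans[[1]]), corp)
  expect_s3_class(autoplot(ev), "ggplot")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, f)
  expect_equal(nrow(utils::read.delim(f)), 8L)
})
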