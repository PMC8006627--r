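test_that("surrogates follow their category rules", {
  gz <- toy_gazetteers()
  set.seed(60)
  # headers are preserved verbatim
  expect_equal(make_surrogate("CAB", "INFORME:", gz), "INFORME:")
  # numbers keep their character-class mask
  for (r in 1:200) {
    s <- make_surrogate("NUM", "1234-AB", gz)
    expect_match(s, "^\\d{4}-[A-Z]{2}$")
    expect_false(s == "1234-AB")
  }
  # dates stay in their format family and remain valid
  for (r in 1:100) {
    s <- make_surrogate("FECHA", "14/03/2018", gz)
    expect_match(s, "^\\d{2}/\\d{2}/\\d{4}$")
    expect_true(deidr:::parse_fecha(s))
    s <- make_surrogate("FECHA", "3 de marzo de 1999", gz)
    expect_match(s, "^\\d{1,2} de [a-z]+ de \\d{4}$")
  }
  # gazetteer categories draw members; never the original
  for (r in 1:100) {
    s <- make_surrogate("LOC", "Valencia", gz)
    expect_true(s %in% gz$LOC$surface)
    expect_false(s == "Valencia")
  }
  # multi-token names keep their token count
  s <- make_surrogate("NAME", "Ana Maria Vila", gz)
  expect_equal(length(strsplit(s, " ")[[1]]), 3L)
  expect_error(make_surrogate("XX", "x", gz), "substitution rule")
})

test_that("exhausted gazetteers fall back to synthesized values", {
  gz <- toy_gazetteers()
  gz$NAME <- gazetteer("Maria", 1, "NAME")
  set.seed(61)
  for (r in 1:50) {
    s <- make_surrogate("NAME", "Maria", gz)
    expect_false(s == "Maria")
    expect_true(nchar(s) > 0)
  }
})

test_that("deidentify replaces exactly the entity regions", {
  gz <- toy_gazetteers()
  corp <- deid_corpus(
    "d1", "INFORME:\nPaciente Ana Vila visto el 14/03/2018\nfin",
    3L,
    list(entity_spans(c(0, 18, 36), c(8, 26, 46),
                      c("CAB", "NAME", "FECHA"),
                      c("INFORME:", "Ana Vila", "14/03/2018")))
  )
  out <- deidentify(corp, gz, seed = 7)
  new_text <- out$text[1]
  new_spans <- out$spans[[1]]
  # spans valid against the new text, same categories, same order
  expect_identical(substring(new_text, new_spans$start + 1L, new_spans$end),
                   new_spans$surface)
  expect_equal(new_spans$label, c("CAB", "NAME", "FECHA"))
  # CAB untouched, identifying surfaces changed
  expect_equal(new_spans$surface[1], "INFORME:")
  expect_false(new_spans$surface[2] == "Ana Vila")
  expect_false(new_spans$surface[3] == "14/03/2018")
  # line count preserved
  expect_equal(length(strsplit(new_text, "\n")[[1]]), 3L)
  # residual text conservation: removing span regions from both texts
  # leaves identical strings
  strip <- function(text, spans) {
    for (i in rev(order(spans$start))) {
      text <- paste0(substr(text, 1, spans$start[i]),
                     substr(text, spans$end[i] + 1, nchar(text)))
    }
    text
  }
  expect_identical(strip(corp$text[1], corp$spans[[1]]),
                   strip(new_text, new_spans))
  # audit discloses lengths and categories only
  expect_named(out$audit[[1]],
               c("label", "original_length", "surrogate_length"))
  expect_false(any(unlist(out$audit[[1]]) %in% corp$spans[[1]]$surface))
})

test_that("documents without spans pass through unchanged", {
  gz <- toy_gazetteers()
  corp <- deid_corpus("d1", "sin hallazgos\nfin")
  out <- deidentify(corp, gz, seed = 1)
  expect_identical(out$text, corp$text)
  expect_equal(nrow(out$audit[[1]]), 0L)
})

test_that("different seeds give different surrogates on unchanged scaffolds", {
  gz <- example_gazetteers()
  corp <- generate_corpus(4, seed = 62)
  a <- deidentify(corp, gz, seed = 1)
  b <- deidentify(corp, gz, seed = 2)
  expect_false(identical(a$text, b$text))
  strip_all <- function(out) {
    vapply(seq_len(nrow(out)), function(i) {
      sp <- out$spans[[i]]
      text <- out$text[i]
      for (k in rev(order(sp$start))) {
        text <- paste0(substr(text, 1, sp$start[k]),
                       substr(text, sp$end[k] + 1, nchar(text)))
      }
      text
    }, "")
  }
  expect_identical(strip_all(a), strip_all(b))
})

test_that("model-based de-identification composes predict and substitute", {
  corp <- overfit_corpus()
  cfg <- tagger_config("lstm-lstm-crf", word_dim = 16, char_dim = 8,
                       char_hidden = 8, word_hidden = 16, dropout = 0,
                       epochs = 40, patience = 40, learning_rate = 5e-2,
                       seed = 4)
  mod <- train_tagger(corp, corp, cfg, quiet = TRUE)
  out <- deidentify_with_model(corp, mod, toy_gazetteers(), seed = 5)
  # the overfit model recovers every gold span, so no gold identifying
  # surface survives in the output
  for (surf in corp$spans[[1]]$surface) {
    expect_false(grepl(surf, out$text[1], fixed = TRUE))
  }
})
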