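# Small configurations keep these tests fast; the end-to-end recovery
# check lives in test-acceptance.R.

small_config <- function(arch, ...) {
  tagger_config(arch, word_dim = 12, char_dim = 6, char_hidden = 6,
                word_hidden = 10, dropout = 0, epochs = 2, patience = 2,
                learning_rate = 5e-2, seed = 3, ...)
}

test_that("parameter allocation matches the closed-form count", {
  corp <- overfit_corpus()
  vocab <- deidr:::build_vocab(corp)
  for (arch in c("lstm-crf", "lstm-lstm-crf", "conv-lstm-crf")) {
    cfg <- small_config(arch)
    p <- deidr:::init_params(cfg, vocab)
    expect_equal(sum(vapply(p, length, 1L)),
                 tagger_parameter_count(cfg, length(vocab$words),
                                        length(vocab$chars)),
                 info = arch)
  }
})

test_that("encoding is deterministic and routes unknown words through UNK", {
  mod <- train_tagger(overfit_corpus(), overfit_corpus(),
                      small_config("lstm-crf"), quiet = TRUE)
  em1 <- encode_tokens(mod, c("paciente", "zzxy"))
  em2 <- encode_tokens(mod, c("paciente", "zzxy"))
  expect_identical(em1, em2)
  expect_equal(ncol(em1), length(deidr:::bio_tags()))
  expect_true(all(is.finite(em1)))
  # without a character channel, two distinct OOV words are identical
  em3 <- encode_tokens(mod, c("paciente", "qqwv"))
  expect_equal(em1, em3)
  # the character-aware architectures distinguish OOV words whose
  # characters are in the vocabulary
  modc <- train_tagger(overfit_corpus(), overfit_corpus(),
                       small_config("lstm-lstm-crf"), quiet = TRUE)
  expect_false(isTRUE(all.equal(encode_tokens(modc, c("paciente", "nana")),
                                encode_tokens(modc, c("paciente", "lava")))))
  expect_error(encode_tokens(mod, character()), "empty")
})

test_that("EMA combination follows its closed form", {
  s <- list(w = matrix(0, 2, 2))
  cur <- list(w = matrix(1, 2, 2))
  expect_equal(apply_ema(s, cur, 0)$w, cur$w)          # decay 0: copy
  expect_equal(apply_ema(cur, cur, 0.9)$w, cur$w)      # fixed point
  two <- apply_ema(apply_ema(s, cur, 0.9), cur, 0.9)
  expect_equal(two$w, matrix(1 - 0.9^2, 2, 2))         # 0.19
  expect_error(apply_ema(s, list(w = matrix(1, 3, 2)), 0.9), "shape")
  expect_error(apply_ema(s, list(v = matrix(1, 2, 2)), 0.9), "congruent")
})

test_that("training is reproducible and EMA leaves the raw trajectory alone", {
  corp <- overfit_corpus()
  m1 <- train_tagger(corp, corp, small_config("lstm-lstm-crf"), quiet = TRUE)
  m2 <- train_tagger(corp, corp, small_config("lstm-lstm-crf"), quiet = TRUE)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$params, m2$params)
  # EMA only changes which parameters are used for prediction: the raw
  # first-epoch loss (before any validation feedback) is unchanged
  m3 <- train_tagger(corp, corp, small_config("lstm-lstm-crf", use_ema = TRUE),
                     quiet = TRUE)
  expect_equal(tidy(m3)$train_nll[1], tidy(m1)$train_nll[1])
  expect_false(is.null(m3$ema))
  expect_true(is.null(m1$ema))
})

test_that("training loss decreases on a single-document corpus", {
  corp <- overfit_corpus()
  cfg <- tagger_config("lstm-crf", word_dim = 12, word_hidden = 10,
                       dropout = 0, epochs = 5, patience = 5,
                       learning_rate = 5e-2, seed = 3)
  mod <- train_tagger(corp, corp, cfg, quiet = TRUE)
  nll <- tidy(mod)$train_nll
  expect_equal(length(nll), 5L)
  expect_true(all(diff(nll) < 0))
})

test_that("prediction is pure, total on empty input, and overfit-exact", {
  corp <- overfit_corpus()
  cfg <- tagger_config("lstm-lstm-crf", word_dim = 16, char_dim = 8,
                       char_hidden = 8, word_hidden = 16, dropout = 0,
                       epochs = 40, patience = 40, learning_rate = 5e-2,
                       seed = 4)
  mod <- train_tagger(corp, corp, cfg, quiet = TRUE)
  sp <- predict(mod, corp)[[1]]
  expect_equal(as.data.frame(sp), as.data.frame(corp$spans[[1]]))
  expect_identical(predict(mod, corp), predict(mod, corp))
  expect_equal(nrow(predict(mod, "")[[1]]), 0L)
})

test_that("checkpoints round-trip through plain text files", {
  corp <- overfit_corpus()
  mod <- train_tagger(corp, corp, small_config("conv-lstm-crf",
                                               use_ema = TRUE),
                      quiet = TRUE)
  dir <- withr::local_tempdir()
  save_tagger(mod, dir)
  expect_false(any(grepl("\\.(rds|rda|RData)$", list.files(dir))))
  back <- load_tagger(dir)
  expect_equal(back$config$architecture, "conv-lstm-crf")
  expect_equal(back$vocab, mod$vocab)
  expect_equal(back$params, mod$params, tolerance = 1e-15)
  expect_identical(predict(back, corp), predict(mod, corp))
  expect_error(load_tagger(withr::local_tempdir()), "checkpoint")
})
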