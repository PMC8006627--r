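# token/tag/line triples of every document: the content CoNLL must keep
token_tags <- function(corpus) {
  lapply(seq_len(nrow(corpus)), function(i) {
    tg <- spans_to_bio(corpus$text[i], corpus$spans[[i]])
    tg[c("token", "tag", "line")]
  })
}

test_that("CoNLL write/read round trip preserves tokens, tags and structure", {
  corp <- tiny_corpus()
  f <- withr::local_tempfile(fileext = ".conll")
  write_conll(corp, f)
  back <- read_conll(f)
  expect_equal(back$doc_id, corp$doc_id)
  expect_equal(back$department, corp$department)
  # token/tag content is lossless; text is normalized to single spaces
  expect_equal(token_tags(back), token_tags(corp))
  # read -> write reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".conll")
  write_conll(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # normalization is a fixed point: a second round trip changes nothing
  expect_equal(read_conll(f2)$text, back$text)
})

test_that("CoNLL reader reports malformed lines and unknown tags", {
  f <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("-DOCSTART-\tO\t# id=x dept=1", "Maria\tB-NAME\tI-NAME"), f)
  expect_error(read_conll(f), ":2")

  writeLines(c("-DOCSTART-\tO\t# id=x dept=1", "Maria\tB-PERSONA"), f)
  expect_error(read_conll(f), "unknown tag")

  writeLines(character(), f)
  expect_equal(nrow(read_conll(f)), 0L)
})

test_that("empty report lines survive the CoNLL round trip", {
  corp <- deid_corpus("e1", "INFORME:\n\nGarcia", 2L,
                      list(entity_spans(10, 16, "NAME", "Garcia")))
  f <- withr::local_tempfile(fileext = ".conll")
  write_conll(corp, f)
  back <- read_conll(f)
  expect_equal(length(strsplit(back$text, "\n")[[1]]), 3L)
  expect_equal(strsplit(back$text, "\n")[[1]][2], "")
  expect_equal(token_tags(back), token_tags(corp))
})

test_that("BRAT write/read round trip is lossless for text and spans", {
  corp <- tiny_corpus()
  dir <- withr::local_tempdir()
  write_brat(corp, dir)
  expect_true(all(file.exists(file.path(dir, c("r1.txt", "r1.ann",
                                               "r2.txt", "r2.ann")))))
  back <- read_brat_dir(dir)
  expect_equal(sort(back$doc_id), sort(corp$doc_id))
  for (id in corp$doc_id) {
    expect_equal(back$text[back$doc_id == id], corp$text[corp$doc_id == id])
    expect_equal(
      as.data.frame(back$spans[[which(back$doc_id == id)]]),
      as.data.frame(corp$spans[[which(corp$doc_id == id)]])
    )
  }
})

test_that("BRAT reader enforces surface integrity and span validity", {
  dir <- withr::local_tempdir()
  writeLines("Paciente Ana Vila", file.path(dir, "x.txt"))
  writeLines("T1\tNAME 9 17\tPedro Gil", file.path(dir, "x.ann"))
  expect_error(read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann")),
               "T1")

  writeLines(c("T1\tNAME 9 17\tAna Vila", "T2\tNAME 13 17\tVila"),
             file.path(dir, "x.ann"))
  expect_error(read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann")),
               "overlap")

  writeLines(character(), file.path(dir, "x.ann"))
  doc <- read_brat(file.path(dir, "x.txt"), file.path(dir, "x.ann"))
  expect_equal(nrow(doc$spans[[1]]), 0L)
})

test_that("random annotated documents survive both formats", {
  set.seed(13)
  corp <- dplyr::bind_rows(lapply(1:25, function(i) {
    random_annotated_doc(sprintf("io%02d", i))
  }))
  f <- withr::local_tempfile(fileext = ".conll")
  write_conll(corp, f)
  back <- read_conll(f)
  expect_equal(back$text, corp$text)
  for (i in seq_len(nrow(corp))) {
    expect_equal(as.data.frame(back$spans[[i]]),
                 as.data.frame(corp$spans[[i]]))
  }
  dir <- withr::local_tempdir()
  write_brat(corp, dir)
  back2 <- read_brat_dir(dir)
  ord <- match(corp$doc_id, back2$doc_id)
  expect_equal(back2$text[ord], corp$text)
})
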