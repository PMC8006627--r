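test_that("generated documents satisfy all span invariants by construction", {
  set.seed(30)
  gz <- example_gazetteers()
  for (pname in c("headered", "dept7", "meddocan")) {
    doc <- generate_document(structure_profile(pname), gz)
    sp <- doc$spans[[1]]
    expect_gt(nrow(sp), 0)
    expect_identical(substring(doc$text[1], sp$start + 1L, sp$end),
                     sp$surface)
    ord <- order(sp$start)
    expect_true(all(sp$end[ord][-nrow(sp)] <= sp$start[ord][-1]))
    # spans align with token boundaries (projection must not error)
    expect_silent(spans_to_bio(doc$text[1], sp))
  }
})

test_that("profiles produce their structural signatures", {
  set.seed(31)
  gz <- example_gazetteers()
  # dept7 with orphan rate 1: at least one line is exactly a NAME surface
  found_name_line <- FALSE
  for (r in 1:12) {
    doc <- generate_document(structure_profile("dept7",
                                               orphan_entity_rate = 1), gz)
    lines <- strsplit(doc$text[1], "\n")[[1]]
    sp <- doc$spans[[1]]
    orphan_surfaces <- sp$surface[sp$label %in% identifying_labels()]
    expect_true(any(lines %in% orphan_surfaces))
    if (any(lines %in% sp$surface[sp$label == "NAME"])) {
      found_name_line <- TRUE
      break
    }
  }
  expect_true(found_name_line)
  expect_equal(doc$department, 7L)

  # headered: CAB spans exactly cover their header lines
  doc <- generate_document(structure_profile("headered"), gz)
  sp <- doc$spans[[1]]
  lines <- strsplit(doc$text[1], "\n")[[1]]
  cab <- sp$surface[sp$label == "CAB"]
  expect_true(all(cab %in% lines))

  # meddocan: every identifying span is preceded by its CAB descriptor
  doc <- generate_document(structure_profile("meddocan"), gz)
  sp <- doc$spans[[1]]
  idents <- sp[sp$label %in% identifying_labels(), ]
  cabs <- sp[sp$label == "CAB", ]
  expect_true(all(idents$start %in% (cabs$end + 1L)))

  # ambiguity: the anatomical reading is tagged O
  doc <- generate_document(structure_profile("headered",
                                             ambiguity_rate = 1), gz)
  expect_match(doc$text[1], "cabeza")
  tagged <- spans_to_bio(doc$text[1], doc$spans[[1]])
  expect_true(all(tagged$tag[tagged$token == "cabeza"] == "O"))
})

test_that("generated dates parse and generated codes match the grammar", {
  set.seed(32)
  for (r in 1:200) {
    expect_true(deidr:::parse_fecha(deidr:::random_fecha()))
    expect_match(deidr:::random_num(),
                 "^[A-Z]{0,2}[0-9][-0-9]*[0-9][A-Z]?$|^[0-9]{6,10}$")
  }
  expect_false(deidr:::parse_fecha("31/02/2001"))
  expect_false(deidr:::parse_fecha("ayer"))
})

test_that("corpus generation is deterministic and hits the share targets", {
  corp1 <- generate_corpus(40, seed = 33)
  corp2 <- generate_corpus(40, seed = 33)
  expect_identical(corp1$text, corp2$text)
  expect_identical(corp1$spans, corp2$spans)
  corp3 <- generate_corpus(40, seed = 34)
  expect_false(identical(corp1$text, corp3$text))

  expect_equal(nrow(generate_corpus(0, seed = 1)), 0L)

  # convergence at moderate size: within 3 pp per category
  corp <- generate_corpus(400, seed = 35)
  shares <- corpus_entity_shares(corp)
  target <- entity_share_targets("training")
  dev <- abs(shares$share - target[shares$label])
  expect_true(all(dev < 3))
})

test_that("share targets are normalized and generation needs gazetteers", {
  for (s in c("training", "validation", "test")) {
    expect_equal(sum(entity_share_targets(s)), 100, tolerance = 1e-9)
  }
  gz <- example_gazetteers()
  gz$NAME <- gazetteer(character(), numeric(), "NAME")
  expect_error(generate_document(structure_profile("headered"), gz),
               "NAME gazetteer")
})
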