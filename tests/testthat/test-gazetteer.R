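test_that("gazetteer loader filters by weight and merges duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "Maria\t25", "Pons\t19", "Garcia\t40"), f)
  gz <- read_gazetteer(f, "NAME", min_weight = 20)
  expect_equal(nrow(gz), 2L)
  expect_setequal(gz$surface, c("Maria", "Garcia"))

  writeLines(c("Garcia\t10", "Maria\t7", "Garcia\t5"), f)
  gz <- read_gazetteer(f, "NAME")
  expect_equal(gz$weight[gz$surface == "Garcia"], 15)
  # conservation: total weight equals the column sum of retained rows
  expect_equal(sum(gz$weight), 22)

  writeLines(character(), f)
  expect_warning(gz <- read_gazetteer(f, "NAME"), "empty")
  expect_equal(nrow(gz), 0L)

  writeLines(c("Maria\tmucho"), f)
  expect_error(read_gazetteer(f, "NAME"), "non-numeric")
  writeLines(c("Maria 25"), f)
  expect_error(read_gazetteer(f, "NAME"), "TAB")
})

test_that("bundled miniature gazetteer set loads with all four categories", {
  gz <- example_gazetteers()
  expect_named(gz, c("NAME", "LOC", "INST", "DIR"))
  expect_true(all(vapply(gz, nrow, 1L) >= 20))
  expect_true(all(vapply(gz, function(g) all(g$weight > 0), TRUE)))
})

test_that("weighted sampling respects exclusion and weights", {
  gz <- gazetteer("Valencia", 1, "LOC")
  expect_equal(weighted_sample(gz), "Valencia")
  expect_error(weighted_sample(gz, exclude = "Valencia"),
               class = "deidr_gazetteer_exhausted")

  # empirical frequency within 3 binomial standard deviations
  gz2 <- gazetteer(c("a", "b"), c(0.9, 0.1), "NAME")
  set.seed(20)
  draws <- replicate(10000, weighted_sample(gz2))
  phat <- mean(draws == "a")
  expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))

  # excluded mass is renormalized over the rest
  gz3 <- gazetteer(c("a", "b", "c"), c(5, 3, 2), "NAME")
  set.seed(21)
  draws <- replicate(10000, weighted_sample(gz3, exclude = "a"))
  expect_false(any(draws == "a"))
  expect_lt(abs(mean(draws == "b") - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
})

test_that("dictionary matching is longest-match, case-insensitive and bounded", {
  gz <- gazetteer(c("Maria", "Maria Garcia", "Garcia"), 1, "NAME")
  sp <- match_entities("vista por maria garcia ayer", gz)
  expect_equal(sp$surface, "maria garcia")   # longest match wins
  expect_equal(sp$label, "NAME")

  # word-boundary anchoring: no match inside a longer token
  expect_equal(nrow(match_entities("mariana", gz)), 0L)

  # accent-sensitive: a different lexical item is not matched
  gz2 <- gazetteer("Pena", 1, "NAME")
  expect_equal(nrow(match_entities("La peña del rio", gz2)), 0L)
  expect_equal(nrow(match_entities("Sr Pena", gz2)), 1L)

  # context-blind by design: anatomical word matches a surname entry
  gz3 <- gazetteer("Cabeza", 1, "NAME")
  expect_equal(nrow(match_entities("TAC de cabeza normal", gz3)), 1L)

  expect_equal(nrow(match_entities("sin hallazgos", gz)), 0L)
})

test_that("matches never overlap and all match some surface", {
  gz <- gazetteer(c("a b", "b c", "c", "a"), 1, "LOC")
  sp <- match_entities("a b c a b z c", gz)
  sp <- sp[order(sp$start), ]
  if (nrow(sp) > 1) {
    expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  }
  expect_true(all(tolower(sp$surface) %in% tolower(gz$surface)))
  # left-to-right greedy: "a b" taken first, then "c"
  expect_equal(sp$surface[1], "a b")
})
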