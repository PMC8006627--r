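# Gazetteer-based automatic pre-annotation and the corpus-construction
# filters used before manual revision.

# category priority on exact-length conflicts: more specific lists win
preannotate_priority <- c("INST", "DIR", "LOC", "NAME", "NUM", "FECHA")

#' Pre-annotate a corpus with gazetteer matches
#'
#' Runs dictionary matching (see [match_entities()]) for every gazetteer in
#' the set and merges the candidates: longest match wins, exact-length
#' conflicts are resolved by the fixed category priority
#' `INST > DIR > LOC > NAME > NUM > FECHA`, and the survivors are
#' non-overlapping.  This is the cheap, context-blind first pass of corpus
#' construction; it will happily tag an anatomical word that doubles as a
#' surname, which is exactly why pre-annotated corpora are filtered and
#' manually revised afterwards.
#'
#' @param corpus A corpus tibble (existing spans are replaced).
#' @param gazetteers A named list of gazetteers; `NAME` and `INST` must be
#'   present.
#' @return The corpus with `spans` filled from gazetteer matches.
#' @examples
#' gz <- example_gazetteers()
#' corp <- deid_corpus("r1", "Informe firmado por Maria Garcia")
#' preannotate(corp, gz)$spans[[1]]
#' @export
preannotate <- function(corpus, gazetteers) {
  if (is.null(gazetteers$NAME) || is.null(gazetteers$INST)) {
    abort("preannotation requires at least NAME and INST gazetteers")
  }
  corpus$spans <- map(corpus$text, function(text) {
    cand <- bind_rows(map(gazetteers, match_entities, text = text))
    if (nrow(cand) == 0) return(entity_spans())
    cand <- cand[order(-(cand$end - cand$start),
                       match(cand$label, preannotate_priority),
                       cand$start), ]
    keep <- logical(nrow(cand))
    taken_s <- integer(); taken_e <- integer()
    for (i in seq_len(nrow(cand))) {
      if (all(cand$end[i] <= taken_s | cand$start[i] >= taken_e)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, cand$start[i])
        taken_e <- c(taken_e, cand$end[i])
      }
    }
    arrange(cand[keep, ], .data$start)
  })
  corpus
}

#' Keep documents with enough name annotations
#'
#' The corpus-construction filter that guarantees the presence of personal
#' information: only documents with at least `min_count` `NAME` spans are
#' retained (order preserved).  Documents that merely contain ambiguous
#' single matches are dropped by this step, not by the matcher.
#'
#' @param corpus An annotated corpus tibble.
#' @param min_count Minimum number of NAME spans (default 2).
#' @return The filtered corpus.
#' @export
filter_min_names <- function(corpus, min_count = 2) {
  n_names <- map_int(corpus$spans, ~ sum(.x$label == "NAME"))
  corpus[n_names >= min_count, ]
}

#' Sample a fraction of a corpus
#'
#' Uniform sampling without replacement of `floor(fraction * n)` documents,
#' deterministic given the seed; used to select the subset sent to manual
#' annotation.
#'
#' @param corpus A corpus tibble.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return The sampled sub-corpus (original order preserved).
#' @export
sample_fraction <- function(corpus, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- floor(fraction * nrow(corpus))
  idx <- with_seed(seed, sort(sample(nrow(corpus), k)))
  corpus[idx, ]
}
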