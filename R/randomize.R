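# Category-preserving surrogate substitution: detected entities are
# replaced by synthetic values of the same category, so residual detection
# misses cannot be told apart from substituted text.

#' Generate a category-matched surrogate for one entity
#'
#' Applies the substitution rule of the entity's category: `NAME` draws a
#' frequency-weighted name (multi-token names are rebuilt token by token so
#' the surrogate has the original's token count); `LOC` a
#' population-weighted municipality; `INST` a hospital/clinic; `DIR` a
#' street address; `FECHA` a freshly generated valid date rendered in the
#' same format family as the original; `NUM` a random string matching the
#' original's character-class mask (digit for digit, letter for letter,
#' separators preserved); `CAB` is returned unchanged — section headers
#' must survive de-identification.  For every category except `CAB` the
#' result is guaranteed to differ from the original; if a gazetteer is
#' exhausted by that exclusion, a synthetic fallback is built from the
#' generator grammar instead (still different from the original).
#'
#' @param label Entity category.
#' @param surface Original surface string.
#' @param gazetteers Gazetteer set.
#' @return A single surrogate string.
#' @examples
#' set.seed(1)
#' make_surrogate("NUM", "1234-AB", example_gazetteers())
#' make_surrogate("CAB", "HALLAZGOS:", example_gazetteers())
#' @export
make_surrogate <- function(label, surface, gazetteers) {
  if (label == "CAB") return(surface)
  out <- switch(label,
    NAME = surrogate_name(surface, gazetteers$NAME),
    LOC = surrogate_gaz(surface, gazetteers$LOC),
    INST = surrogate_gaz(surface, gazetteers$INST),
    DIR = surrogate_gaz(surface, gazetteers$DIR),
    FECHA = surrogate_fecha(surface),
    NUM = surrogate_mask(surface),
    abort(sprintf("no substitution rule for label %s", label))
  )
  stopifnot(out != surface)
  out
}

surrogate_gaz <- function(surface, gaz) {
  tryCatch(
    weighted_sample(gaz, exclude = surface),
    deidr_gazetteer_exhausted = function(e) fallback_word(surface)
  )
}

surrogate_name <- function(surface, gaz) {
  k <- length(strsplit(trimws(surface), "\\s+")[[1]])
  for (attempt in 1:25) {
    parts <- map_chr(seq_len(k), function(i) {
      tryCatch(weighted_sample(gaz, exclude = surface),
               deidr_gazetteer_exhausted = function(e)
                 fallback_word(surface))
    })
    out <- paste(parts, collapse = " ")
    if (out != surface) return(out)
  }
  fallback_word(surface)
}

surrogate_fecha <- function(surface) {
  family <- if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", surface)) {
    "slash"
  } else if (grepl("^\\d{1,2}-\\d{1,2}-\\d{4}$", surface)) {
    "dash"
  } else if (grepl("^\\d{1,2} de \\p{L}+ de \\d{4}$", surface,
                   perl = TRUE)) {
    "written"
  } else {
    NULL   # unrecognized date rendering: regenerate by character mask
  }
  for (attempt in 1:100) {
    out <- if (is.null(family)) surrogate_mask(surface) else
      random_fecha(family)
    if (out != surface) return(out)
  }
  abort(sprintf("could not produce a date surrogate for %s",
                dQuote(surface, FALSE)))
}

# random string with the same character-class mask as the original:
# digit -> digit, uppercase -> uppercase, lowercase -> lowercase,
# everything else preserved
surrogate_mask <- function(surface) {
  ch <- strsplit(surface, "")[[1]]
  if (!any(grepl("[0-9A-Za-z]", ch))) {
    # nothing mutable in the mask: fall back to the code grammar
    out <- random_num()
    while (out == surface) out <- random_num()
    return(out)
  }
  for (attempt in 1:100) {
    out <- paste(vapply(ch, function(c) {
      if (grepl("[0-9]", c)) as.character(sample(0:9, 1))
      else if (grepl("[A-Z]", c)) sample(LETTERS, 1)
      else if (grepl("[a-z]", c)) sample(letters, 1)
      else c
    }, character(1)), collapse = "")
    if (out != surface) return(out)
  }
  abort("mask regeneration failed to differ from the original")
}

# synthetic pronounceable fallback used when a gazetteer is exhausted
fallback_word <- function(surface) {
  syll <- c("ba", "ce", "da", "fe", "go", "la", "mi", "no", "pa", "ra",
            "sa", "te", "vi", "xa", "zu", "lle", "rra", "nes", "dor", "mar")
  for (attempt in 1:100) {
    w <- paste(sample(syll, sample(2:3, 1), replace = TRUE), collapse = "")
    w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchr(w)))
    if (w != surface) return(w)
  }
  paste0(surface, "X")  # unreachable in practice
}

#' De-identify an annotated document or corpus
#'
#' Replaces every non-`CAB` span's surface with a category-matched
#' surrogate (see [make_surrogate()]).  Replacement proceeds right to
#' left so earlier offsets stay valid; all text between spans is preserved
#' byte for byte, line count is unchanged, and the returned spans point at
#' the surrogates in the new text.  The audit table records only
#' categories and lengths — never the original surfaces, which would
#' defeat the purpose of de-identification.
#'
#' @param corpus A corpus tibble with gold or predicted spans.
#' @param gazetteers Gazetteer set.
#' @param seed Optional integer seed for reproducible surrogates.
#' @return A corpus tibble with substituted `text`, surrogate `spans` and
#'   an `audit` list-column of tibbles
#'   (`label`, `original_length`, `surrogate_length`).
#' @examples
#' corp <- deid_corpus("r1", "Paciente Ana Vila",
#'   spans = list(entity_spans(9, 17, "NAME", "Ana Vila")))
#' deidentify(corp, example_gazetteers(), seed = 1)
#' @export
deidentify <- function(corpus, gazetteers = example_gazetteers(),
                       seed = NULL) {
  with_seed(seed, {
    rows <- map(seq_len(nrow(corpus)), function(i) {
      deidentify_one(corpus$text[i], corpus$spans[[i]], gazetteers)
    })
  })
  out <- corpus
  out$text <- map_chr(rows, "text")
  out$spans <- map(rows, "spans")
  out$audit <- map(rows, "audit")
  out
}

deidentify_one <- function(text, spans, gazetteers) {
  validate_spans(text, spans)
  n_sp <- nrow(spans)
  if (n_sp == 0) {
    return(list(text = text, spans = spans,
                audit = tibble(label = character(),
                               original_length = integer(),
                               surrogate_length = integer())))
  }
  spans <- spans[order(spans$start), ]
  sur <- map_chr(seq_len(n_sp), function(k) {
    make_surrogate(spans$label[k], spans$surface[k], gazetteers)
  })
  new_text <- text
  for (k in rev(seq_len(n_sp))) {   # right-to-left keeps offsets valid
    new_text <- paste0(
      substr(new_text, 1, spans$start[k]), sur[k],
      substr(new_text, spans$end[k] + 1L, nchr(new_text))
    )
  }
  delta <- nchr(sur) - (spans$end - spans$start)
  shift <- c(0L, cumsum(delta))[seq_len(n_sp)]
  new_start <- spans$start + shift
  new_spans <- entity_spans(new_start, new_start + nchr(sur),
                            spans$label, sur)
  validate_spans(new_text, new_spans, "surrogate spans")
  list(text = new_text, spans = new_spans,
       audit = tibble(label = spans$label,
                      original_length = as.integer(spans$end - spans$start),
                      surrogate_length = as.integer(nchr(sur))))
}

#' De-identify raw text with a trained tagger
#'
#' Composition of [predict.deid_tagger()] and [deidentify()]: the model
#' finds the entity spans, the randomizer substitutes them.
#'
#' @param corpus A corpus tibble (spans, if any, are ignored).
#' @param model A trained [deid_tagger] object.
#' @param gazetteers Gazetteer set.
#' @param seed Optional integer seed.
#' @return As [deidentify()].
#' @export
deidentify_with_model <- function(corpus, model,
                                  gazetteers = example_gazetteers(),
                                  seed = NULL) {
  corpus$spans <- predict(model, corpus)
  deidentify(corpus, gazetteers, seed = seed)
}
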