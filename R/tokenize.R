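#' Tokenize Spanish report text with character offsets
#'
#' Splits text into word, code and punctuation tokens while preserving exact
#' character offsets into the original string.  The rule is: tokens are
#' maximal runs of letters/digits, optionally joined through internal `-`,
#' `/` or `.` separators when flanked by letters/digits on both sides (so
#' date-like surfaces such as `14/03/2018` and code-like surfaces such as
#' `1234-AB` stay single tokens), and every other non-space character is a
#' one-character token.  Newlines never fall inside a token; the `line`
#' column records the (1-based) report line each token belongs to, because
#' line structure is signal in this document family.
#'
#' @param text A single string (UTF-8).
#' @return A tibble with columns `token`, `start`, `end` (0-based half-open
#'   code-point offsets) and `line`.
#' @examples
#' es_tokenize("TAC craneal: sin hallazgos.")
#' es_tokenize("Fecha: 14/03/2018")
#' @export
es_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble(token = character(), start = integer(),
                  end = integer(), line = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  # offset of the first character of each line
  line_off <- c(0L, cumsum(nchr(lines) + 1L))[seq_along(lines)]
  pat <- "[\\p{L}\\p{N}]+(?:[-/.][\\p{L}\\p{N}]+)*|[^\\s\\p{L}\\p{N}]"
  res <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    m <- gregexpr(pat, ln, perl = TRUE)[[1]]
    if (m[1] == -1) next
    st <- as.integer(m) - 1L + line_off[i]
    len <- attr(m, "match.length")
    res[[i]] <- tibble(
      token = regmatches(ln, list(m))[[1]],
      start = st, end = st + as.integer(len), line = i
    )
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) empty else out
}

#' Convert entity spans to per-token BIO tags
#'
#' Projects a document's character spans onto its tokens: the first token of
#' a span gets `B-<label>`, subsequent tokens `I-<label>`, everything else
#' `O`.  Every span boundary must coincide with token boundaries; a span
#' that starts or ends mid-token is an annotation defect and raises an
#' error naming the offending span.
#'
#' @param text Document text.
#' @param spans A span tibble (see [entity_spans()]).
#' @param tokens Optional pre-computed token table from [es_tokenize()].
#' @return The token tibble with an added `tag` column.
#' @examples
#' spans_to_bio("Dra. Ana Vila", entity_spans(5, 13, "NAME", "Ana Vila"))
#' @export
spans_to_bio <- function(text, spans, tokens = es_tokenize(text)) {
  validate_spans(text, spans)
  tags <- rep("O", nrow(tokens))
  if (nrow(spans) > 0) {
    spans <- spans[order(spans$start), ]
    for (k in seq_len(nrow(spans))) {
      s <- spans$start[k]; e <- spans$end[k]
      inside <- which(tokens$start >= s & tokens$end <= e)
      ok <- length(inside) > 0 &&
        tokens$start[inside[1]] == s &&
        tokens$end[inside[length(inside)]] == e
      if (!ok) {
        abort(sprintf(
          "span %s [%d,%d) does not align with token boundaries",
          dQuote(spans$surface[k], FALSE), s, e
        ))
      }
      tags[inside] <- c(paste0("B-", spans$label[k]),
                        rep(paste0("I-", spans$label[k]),
                            length(inside) - 1L))
    }
  }
  mutate(tokens, tag = tags)
}

#' Recover entity spans from BIO tags
#'
#' Inverse of [spans_to_bio()] on valid sequences.  Raw tagger output may
#' contain dangling `I-X` tags (an `I-X` not preceded by `B-X` or `I-X`);
#' these are repaired to `B-X` before conversion so the function is total
#' on any tag sequence.
#'
#' @param tagged A tibble with columns `token`, `start`, `end`, `tag`
#'   (as produced by [spans_to_bio()] or a tagger).
#' @param text The document text the offsets index into.
#' @return A span tibble.
#' @examples
#' tg <- spans_to_bio("Ana Vila", entity_spans(0, 8, "NAME", "Ana Vila"))
#' bio_to_spans(tg, "Ana Vila")
#' @export
bio_to_spans <- function(tagged, text) {
  tags <- repair_bio(tagged$tag)
  n <- length(tags)
  if (n == 0) return(entity_spans())
  lab <- ifelse(tags == "O", NA_character_, substring(tags, 3))
  begin <- startsWith(tags, "B-")
  # a span continues while the tag is I-<same label>
  grp <- cumsum(begin | tags == "O")
  keep <- !is.na(lab)
  if (!any(keep)) return(entity_spans())
  idx <- split(which(keep), grp[keep])
  starts <- map_int(idx, ~ tagged$start[.x[1]])
  ends <- map_int(idx, ~ tagged$end[.x[length(.x)]])
  labels <- map_chr(idx, ~ lab[.x[1]])
  entity_spans(starts, ends, labels, str_slice(text, starts, ends))
}

# Repair dangling I-X tags to B-X; also an I-X following a different label.
repair_bio <- function(tags) {
  n <- length(tags)
  if (n == 0) return(tags)
  prev_lab <- c(NA_character_,
                ifelse(tags == "O", NA_character_, substring(tags, 3))[-n])
  dangling <- startsWith(tags, "I-") &
    (is.na(prev_lab) | substring(tags, 3) != prev_lab)
  tags[dangling] <- sub("^I-", "B-", tags[dangling])
  tags
}

# Tag a whole document; returns the tagged token tibble.
tag_document <- function(text, spans) {
  spans_to_bio(text, spans)
}
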