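# Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Character-offset substring, 0-based half-open over code points.
# substring() vectorizes over the offsets; substr() would not.
str_slice <- function(text, start, end) {
  substring(text, start + 1L, end)
}

# Number of code points.
nchr <- function(x) nchar(x, type = "chars")

#' Build an empty entity-span table
#'
#' Spans are tibbles with 0-based, half-open character offsets (`start`,
#' `end`), an entity `label` and the covered `surface` string.  This is the
#' span representation used by every function in the package.
#'
#' @param start,end Integer character offsets, 0-based half-open, counted in
#'   Unicode code points.
#' @param label Entity labels, each one of [deid_labels()].
#' @param surface Covered text slices.
#' @return A tibble with columns `start`, `end`, `label`, `surface`.
#' @examples
#' entity_spans(0, 5, "NAME", "Maria")
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         label = character(), surface = character()) {
  tibble(
    start = as.integer(start), end = as.integer(end),
    label = as.character(label), surface = as.character(surface)
  )
}

# Validate a span table against its text; stops with an informative error.
validate_spans <- function(text, spans, where = "spans") {
  if (nrow(spans) == 0) return(invisible(spans))
  bad_lab <- setdiff(unique(spans$label), deid_labels())
  if (length(bad_lab) > 0) {
    abort(sprintf("%s: unknown entity label(s): %s", where,
                  paste(bad_lab, collapse = ", ")))
  }
  n <- nchr(text)
  if (any(spans$start < 0 | spans$start >= spans$end | spans$end > n)) {
    abort(sprintf("%s: offsets out of range for a %d-character text", where, n))
  }
  got <- str_slice(text, spans$start, spans$end)
  if (any(got != spans$surface)) {
    i <- which(got != spans$surface)[1]
    abort(sprintf(
      "%s: surface mismatch at [%d,%d): expected %s, text has %s",
      where, spans$start[i], spans$end[i],
      dQuote(spans$surface[i], FALSE), dQuote(got[i], FALSE)
    ))
  }
  s <- spans[order(spans$start), ]
  if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
    abort(sprintf("%s: overlapping spans", where))
  }
  invisible(spans)
}

#' Assemble an annotated corpus tibble
#'
#' A corpus is a tibble with one row per document: `doc_id`, `text`,
#' `department` (small integer tag, `NA` for unknown) and a `spans`
#' list-column of span tables (see [entity_spans()]).  All readers,
#' generators and the splitter produce this shape; all taggers and the
#' randomizer consume it.
#'
#' @param doc_id Character document identifiers (non-empty, unique).
#' @param text Document texts (UTF-8, may contain newlines).
#' @param department Integer department markers; `NA` means unknown.
#' @param spans List of span tibbles, one per document.
#' @return A corpus tibble.
#' @examples
#' deid_corpus("r1", "TAC craneal sin hallazgos.", 3, list(entity_spans()))
#' @export
deid_corpus <- function(doc_id, text, department = NA_integer_,
                        spans = NULL) {
  doc_id <- as.character(doc_id)
  if (any(!nzchar(doc_id))) abort("doc_id must be non-empty")
  if (anyDuplicated(doc_id)) abort("doc_id must be unique")
  if (is.null(spans)) spans <- rep(list(entity_spans()), length(doc_id))
  out <- tibble(
    doc_id = doc_id,
    text = as.character(text),
    department = rep_len(as.integer(department), length(doc_id)),
    spans = spans
  )
  purrr::walk2(out$text, out$spans, validate_spans)
  out
}
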