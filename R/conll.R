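#' Read and write CoNLL-2002-style annotated corpora
#'
#' The dialect: one `token<TAB>tag` pair per line; a `-DOCSTART-` header
#' line opens each document and carries the document id and department as a
#' trailing comment (`-DOCSTART-<TAB>O<TAB># id=r001 dept=7`); a blank line
#' closes a document.  Report-line structure — critical for the headerless
#' report profile, where identifying entities sit alone on a line — is
#' preserved through the reserved token `-NL-` (tag `O`), one per line
#' break, so an empty report line appears as two consecutive `-NL-`
#' markers.  Text is reconstructed by joining the tokens of a report line
#' with single spaces, so `write_conll()` then `read_conll()` is the
#' identity up to whitespace normalization, and `read_conll()` then
#' `write_conll()` reproduces the file.
#'
#' @param path File path (UTF-8, LF line endings).
#' @param corpus A corpus tibble (see [deid_corpus()]).
#' @return `read_conll()` returns a corpus tibble; `write_conll()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".conll")
#' corp <- deid_corpus("r1", "Paciente Ana Vila",
#'   spans = list(entity_spans(9, 17, "NAME", "Ana Vila")))
#' write_conll(corp, f)
#' read_conll(f)
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur <- NULL   # list(id, dept, tok, tag, line)
  doc_line <- 1L
  flush <- function() {
    if (!is.null(cur)) docs[[length(docs) + 1L]] <<- cur
  }
  new_doc <- function(id, dept) {
    doc_line <<- 1L
    list(id = id, dept = dept, tok = character(),
         tag = character(), line = integer())
  }
  for (ln_no in seq_along(lines)) {
    raw <- lines[ln_no]
    if (!nzchar(raw)) { flush(); cur <- NULL; next }
    if (startsWith(raw, "-DOCSTART-")) {
      flush()
      id <- if (grepl("id=", raw)) sub(".*id=(\\S+).*", "\\1", raw) else
        sprintf("doc%03d", length(docs) + 1L)
      dept <- if (grepl("dept=", raw)) {
        suppressWarnings(as.integer(sub(".*dept=(\\S+).*", "\\1", raw)))
      } else {
        NA_integer_
      }
      cur <- new_doc(id, dept)
      next
    }
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2) {
      abort(sprintf("%s:%d: expected 2 tab-separated columns, found %d",
                    path, ln_no, length(fields)))
    }
    if (is.null(cur)) {
      cur <- new_doc(sprintf("doc%03d", length(docs) + 1L), NA_integer_)
    }
    if (fields[1] == "-NL-") { doc_line <- doc_line + 1L; next }
    if (!fields[2] %in% bio_tags()) {
      abort(sprintf("%s:%d: unknown tag %s", path, ln_no,
                    dQuote(fields[2], FALSE)))
    }
    cur$tok <- c(cur$tok, fields[1])
    cur$tag <- c(cur$tag, fields[2])
    cur$line <- c(cur$line, doc_line)
  }
  flush()
  if (length(docs) == 0) return(deid_corpus(character(), character()))
  rows <- map(docs, conll_doc_to_row)
  deid_corpus(
    map_chr(rows, "doc_id"), map_chr(rows, "text"),
    map_int(rows, "department"), map(rows, "spans")
  )
}

# rebuild text + spans from token/tag/line triples
conll_doc_to_row <- function(d) {
  max_line <- if (length(d$line)) max(d$line) else 1L
  parts <- rep("", max_line)
  starts <- integer(length(d$tok))
  off <- 0L
  for (i in seq_len(max_line)) {
    idx <- which(d$line == i)
    if (length(idx)) {
      toks <- d$tok[idx]
      starts[idx] <- off + c(0L, cumsum(nchr(toks) + 1L))[seq_along(toks)]
      parts[i] <- paste(toks, collapse = " ")
    }
    off <- off + nchr(parts[i]) + 1L
  }
  text <- paste(parts, collapse = "\n")
  tagged <- tibble(token = d$tok, start = starts,
                   end = starts + nchr(d$tok), tag = d$tag)
  list(doc_id = d$id, text = text, department = d$dept,
       spans = bio_to_spans(tagged, text))
}

#' @rdname read_conll
#' @export
write_conll <- function(corpus, path) {
  out <- character()
  for (i in seq_len(nrow(corpus))) {
    tagged <- tag_document(corpus$text[i], corpus$spans[[i]])
    dept <- corpus$department[i]
    out <- c(out, sprintf("-DOCSTART-\tO\t# id=%s dept=%s", corpus$doc_id[i],
                          if (is.na(dept)) "NA" else dept))
    n_lines <- length(strsplit(paste0(corpus$text[i], " "), "\n",
                               fixed = TRUE)[[1]])
    for (ln in seq_len(n_lines)) {
      rows <- tagged[tagged$line == ln, ]
      if (nrow(rows)) out <- c(out, paste0(rows$token, "\t", rows$tag))
      if (ln < n_lines) out <- c(out, "-NL-\tO")
    }
    out <- c(out, "")
  }
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}
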