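#' Read and write BRAT standoff annotation pairs
#'
#' A document is a `.txt` file plus an `.ann` file whose `T` lines hold one
#' entity each: `T<k><TAB><LABEL> <start> <end><TAB><surface>`, offsets
#' 0-based half-open over Unicode code points (the BRAT convention, which
#' the whole package shares).  Only `T` lines are consumed and produced.
#' Every annotation is validated against the text: a surface that does not
#' equal the text slice is an integrity error naming the annotation id, and
#' overlapping spans are rejected.
#'
#' @param txt_path,ann_path Paths of the text and annotation files.
#' @param doc_id Document id; defaults to the `.txt` file name stem.
#' @param department Department marker, `NA` for unknown (the standoff
#'   format does not carry it).
#' @return `read_brat()` returns a one-row corpus tibble.
#' @examples
#' dir <- tempdir()
#' corp <- deid_corpus("r1", "Paciente Ana Vila",
#'   spans = list(entity_spans(9, 17, "NAME", "Ana Vila")))
#' write_brat(corp, dir)
#' read_brat(file.path(dir, "r1.txt"), file.path(dir, "r1.ann"))
#' @export
read_brat <- function(txt_path, ann_path,
                      doc_id = sub("\\.txt$", "", basename(txt_path)),
                      department = NA_integer_) {
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- if (file.exists(ann_path)) {
    readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  } else {
    character()
  }
  lines <- lines[startsWith(lines, "T")]
  spans <- entity_spans()
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad)) {
      abort(sprintf("%s: malformed T line %s", ann_path,
                    dQuote(lines[bad[1]], FALSE)))
    }
    mid <- strsplit(map_chr(parts, 2), " ", fixed = TRUE)
    spans <- entity_spans(
      start = as.integer(map_chr(mid, 2)),
      end = as.integer(map_chr(mid, 3)),
      label = map_chr(mid, 1),
      surface = map_chr(parts, 3)
    )
    got <- str_slice(text, spans$start, spans$end)
    mism <- which(got != spans$surface)
    if (length(mism)) {
      abort(sprintf(
        "%s: annotation %s surface %s does not match text slice %s",
        ann_path, map_chr(parts, 1)[mism[1]],
        dQuote(spans$surface[mism[1]], FALSE), dQuote(got[mism[1]], FALSE)
      ))
    }
    spans <- spans[order(spans$start), ]
  }
  deid_corpus(doc_id, text, department, list(spans))
}

#' @rdname read_brat
#' @param corpus A corpus tibble; one `.txt`/`.ann` pair is written per row,
#'   named by `doc_id`.
#' @param dir Output directory (created if missing).
#' @return `write_brat()` returns `dir` invisibly.
#' @export
write_brat <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$doc_id[i]
    writeLines(enc2utf8(corpus$text[i]), file.path(dir, paste0(id, ".txt")),
               useBytes = TRUE)
    sp <- corpus$spans[[i]]
    ann <- if (nrow(sp)) {
      sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(sp)), sp$label,
              sp$start, sp$end, sp$surface)
    } else {
      character()
    }
    writeLines(enc2utf8(ann), file.path(dir, paste0(id, ".ann")),
               useBytes = TRUE)
  }
  invisible(dir)
}

#' Read a directory of BRAT pairs as a corpus
#'
#' @param dir Directory containing `<id>.txt` / `<id>.ann` pairs.
#' @return A corpus tibble with one row per pair.
#' @export
read_brat_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  rows <- map(txts, ~ read_brat(.x, sub("\\.txt$", ".ann", .x)))
  if (length(rows) == 0) return(deid_corpus(character(), character()))
  bind_rows(rows)
}
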