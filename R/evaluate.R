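# Token-level per-entity metrics and the global de-identification metric.
#
# The global metric is computed on the binary distinction identifying vs
# non-identifying token: a token is identifying when its gold or predicted
# category is one of NAME, DIR, LOC, NUM, FECHA, INST.  CAB and O are
# non-identifying (headers are deliberately preserved, not removed).  A
# gold NAME token predicted FECHA is therefore a *binary* true positive —
# it still gets substituted — even though it is a category FN plus FP.

#' Precision, recall and F1 from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`.  A zero denominator yields 0 for the affected
#' metric and sets the `degenerate` flag.
#'
#' @param tp,fp,fn Non-negative integer counts (vectorized).
#' @return A tibble with columns `precision`, `recall`, `f1`, `degenerate`.
#' @examples
#' prf(3, 1, 2)
#' prf(0, 0, 0)
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble(precision = p, recall = r, f1 = f,
         degenerate = (tp + fp == 0) | (tp + fn == 0) | (p + r == 0))
}

#' Token-level confusion counts between two taggings
#'
#' Compares gold and predicted BIO tags token by token, ignoring the B/I
#' prefix: per category, TP counts tokens labelled with that category on
#' both sides, FP tokens predicted but not gold, FN tokens gold but not
#' predicted.  The `identifying` row holds the binary layer over the six
#' identifying categories, where any cross-category detection of an
#' identifying token counts as a true positive.
#'
#' @param gold,pred Tagged token tibbles over the same tokens (columns
#'   `token`, `tag`).
#' @return A tibble with columns `label`, `tp`, `fp`, `fn`; one row per
#'   category in report order plus the `identifying` row.
#' @examples
#' g <- tibble::tibble(token = c("Ana", "hoy"), tag = c("B-NAME", "O"))
#' p <- tibble::tibble(token = c("Ana", "hoy"), tag = c("B-FECHA", "O"))
#' token_confusion(g, p)
#' @export
token_confusion <- function(gold, pred) {
  if (nrow(gold) != nrow(pred) || any(gold$token != pred$token)) {
    abort("gold and predicted token sequences do not align")
  }
  cat_of <- function(tags) ifelse(tags == "O", "O", substring(tags, 3))
  g <- cat_of(gold$tag)
  p <- cat_of(pred$tag)
  rows <- map(deid_labels(), function(lab) {
    tibble(label = lab,
           tp = sum(g == lab & p == lab),
           fp = sum(p == lab & g != lab),
           fn = sum(g == lab & p != lab))
  })
  ident <- identifying_labels()
  gi <- g %in% ident
  pi <- p %in% ident
  rows[[length(rows) + 1L]] <- tibble(
    label = "identifying",
    tp = sum(gi & pi), fp = sum(pi & !gi), fn = sum(gi & !pi)
  )
  mutate(bind_rows(rows), dplyr::across(c("tp", "fp", "fn"), as.integer))
}

#' Global de-identification metric
#'
#' Precision, recall and F1 over the binary identifying-vs-not layer of
#' [token_confusion()] — the headline number of a de-identification run,
#' crediting detections regardless of category because a wrongly
#' categorized entity is still substituted.
#'
#' @inheritParams token_confusion
#' @return A one-row tibble (`precision`, `recall`, `f1`, `degenerate`).
#' @export
global_deid <- function(gold, pred) {
  cc <- token_confusion(gold, pred)
  b <- cc[cc$label == "identifying", ]
  prf(b$tp, b$fp, b$fn)
}

#' Evaluate a tagger (or predicted spans) on an annotated corpus
#'
#' Pools token-level counts over all documents (micro-averaging) and
#' reports per-category precision/recall/F1 plus the global
#' de-identification row, in the fixed report order CAB, NAME, DIR, LOC,
#' NUM, FECHA, INST, identifying.
#'
#' @param object A trained [deid_tagger], or a list of predicted span
#'   tibbles of the same length as the corpus.
#' @param corpus An annotated corpus tibble (gold spans).
#' @param level `"token"` (primary; the de-identification literature
#'   counts identifying tokens) or `"span"` (secondary strict
#'   entity-level matching: a span counts only if category and both
#'   boundaries agree).
#' @return A `deid_eval` object; see [tidy.deid_eval()] and
#'   [glance.deid_eval()].
#' @export
evaluate_corpus <- function(object, corpus, level = c("token", "span")) {
  level <- match.arg(level)
  if (nrow(corpus) == 0) abort("cannot evaluate on an empty corpus")
  pred_spans <- if (inherits(object, "deid_tagger")) {
    predict(object, corpus)
  } else {
    object
  }
  stopifnot(length(pred_spans) == nrow(corpus))
  counts <- NULL
  for (i in seq_len(nrow(corpus))) {
    cc <- if (level == "token") {
      toks <- es_tokenize(corpus$text[i])
      gold <- spans_to_bio(corpus$text[i], corpus$spans[[i]], toks)
      pred <- spans_to_bio(corpus$text[i], pred_spans[[i]], toks)
      token_confusion(gold, pred)
    } else {
      span_confusion(corpus$spans[[i]], pred_spans[[i]])
    }
    counts <- if (is.null(counts)) cc else
      mutate(counts, tp = .data$tp + cc$tp, fp = .data$fp + cc$fp,
             fn = .data$fn + cc$fn)
  }
  metrics <- dplyr::bind_cols(counts["label"],
                              prf(counts$tp, counts$fp, counts$fn))
  structure(list(counts = counts, metrics = metrics, level = level,
                 n_documents = nrow(corpus)),
            class = "deid_eval")
}

# strict entity-level confusion: exact boundary + category match
span_confusion <- function(gold, pred) {
  key <- function(s) sprintf("%d:%d:%s", s$start, s$end, s$label)
  gk <- key(gold); pk <- key(pred)
  rows <- map(deid_labels(), function(lab) {
    gl <- gk[gold$label == lab]; pl <- pk[pred$label == lab]
    tibble(label = lab, tp = sum(pl %in% gl),
           fp = sum(!pl %in% gl), fn = sum(!gl %in% pl))
  })
  ident <- identifying_labels()
  gl <- gk[gold$label %in% ident]; pl <- pk[pred$label %in% ident]
  rows[[length(rows) + 1L]] <- tibble(
    label = "identifying", tp = sum(pl %in% gl),
    fp = sum(!pl %in% gl), fn = sum(!gl %in% pl)
  )
  mutate(bind_rows(rows), dplyr::across(c("tp", "fp", "fn"), as.integer))
}

#' @export
print.deid_eval <- function(x, ...) {
  cat(sprintf("<deid_eval> %s-level, %d documents\n",
              x$level, x$n_documents))
  df <- as.data.frame(tidy(x))
  df[c("precision", "recall", "f1")] <-
    lapply(df[c("precision", "recall", "f1")], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy and summarise evaluation reports
#'
#' `tidy()` returns the full per-category table (counts and metrics, one
#' row per category plus the global `identifying` row); `glance()` returns
#' just the global de-identification row.
#'
#' @param x A `deid_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.deid_eval <- function(x, ...) {
  left_join(x$counts, x$metrics, by = "label")
}

#' @rdname tidy.deid_eval
#' @export
glance.deid_eval <- function(x, ...) {
  row <- x$metrics[x$metrics$label == "identifying", ]
  dplyr::bind_cols(row[setdiff(names(row), "label")],
                   tibble(level = x$level, n_documents = x$n_documents))
}

#' Plot an evaluation report
#'
#' Bar chart of precision, recall and F1 per entity category, with the
#' global de-identification row highlighted.
#'
#' @param object A `deid_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deid_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  df$label <- factor(df$label, levels = c(deid_labels(), "identifying"))
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s-level evaluation", object$level)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as a delimited table
#'
#' @param x A `deid_eval` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  df <- tidy(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
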