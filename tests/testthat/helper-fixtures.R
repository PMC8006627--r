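# Shared fixtures and independent oracles.

# Exhaustive-enumeration CRF oracle: scores every tag path directly.
enum_crf <- function(em, tr, tags = NULL) {
  T <- nrow(em)
  K <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  path_score <- function(p) {
    s <- tr[K + 1, p[1]] + em[1, p[1]]
    if (T > 1) {
      for (t in 2:T) s <- s + tr[p[t - 1], p[t]] + em[t, p[t]]
    }
    s + tr[p[T], K + 2]
  }
  scores <- apply(paths, 1, path_score)
  out <- list(
    logZ = log(sum(exp(scores))),
    best_score = max(scores),
    best_path = paths[which.max(scores), ]
  )
  if (!is.null(tags)) out$nll <- out$logZ - path_score(tags)
  out
}

# Random annotated document with token-aligned spans: words drawn from a
# small lexicon, each word independently promoted to a single-token span.
random_annotated_doc <- function(id, n_lines = sample(1:4, 1)) {
  lexicon <- c("informe", "craneal", "sin", "hallazgos", "paciente",
               "Garcia", "Maria", "12345678", "14/03/2018", "Valencia",
               "Hospital", "control", "estudio", "normal")
  lines <- character(n_lines)
  spans <- entity_spans()
  off <- 0L
  for (ln in seq_len(n_lines)) {
    n_tok <- sample(1:7, 1)
    toks <- sample(lexicon, n_tok, replace = TRUE)
    starts <- off + c(0L, cumsum(nchar(toks) + 1L))[seq_len(n_tok)]
    lines[ln] <- paste(toks, collapse = " ")
    for (t in seq_len(n_tok)) {
      if (runif(1) < 0.25) {
        lab <- sample(deid_labels(), 1)
        spans <- rbind(spans, entity_spans(starts[t], starts[t] +
                                             nchar(toks[t]), lab, toks[t]))
      }
    }
    off <- off + nchar(lines[ln]) + 1L
  }
  deid_corpus(id, paste(lines, collapse = "\n"),
              sample(1:17, 1), list(tibble::as_tibble(spans)))
}

# minimal two-document annotated corpus used across IO tests
tiny_corpus <- function() {
  deid_corpus(
    c("r1", "r2"),
    c("INFORME:\nPaciente Ana Vila con historia 12345678",
      "DATA\n14/03/2018\nGarcia"),
    c(3L, 7L),
    list(
      entity_spans(c(0, 18, 40), c(8, 26, 48),
                   c("CAB", "NAME", "NUM"),
                   c("INFORME:", "Ana Vila", "12345678")),
      entity_spans(c(0, 5, 16), c(4, 15, 22),
                   c("CAB", "FECHA", "NAME"),
                   c("DATA", "14/03/2018", "Garcia"))
    )
  )
}

# small deterministic gazetteer set (independent of the bundled files)
toy_gazetteers <- function() {
  list(
    NAME = gazetteer(c("Maria", "Garcia", "Pons", "Vila", "Cabeza"),
                     c(50, 40, 10, 20, 5), "NAME"),
    LOC = gazetteer(c("Valencia", "Alacant", "Xativa"),
                    c(80, 30, 5), "LOC"),
    INST = gazetteer(c("Hospital La Fe", "Hospital General",
                       "Centro de Salud Ruzafa"), 1, "INST"),
    DIR = gazetteer(c("Calle Mayor 1, 46001", "Avenida del Puerto 2, 46002"),
                    1, "DIR")
  )
}

# quick single-document trainer used by model tests
overfit_corpus <- function() {
  deid_corpus(
    "ov1",
    "Paciente Ana Vila ingresa el 14/03/2018 en Valencia con historia 99887",
    3L,
    list(entity_spans(c(9, 29, 43, 65), c(17, 39, 51, 70),
                      c("NAME", "FECHA", "LOC", "NUM"),
                      c("Ana Vila", "14/03/2018", "Valencia", "99887")))
  )
}
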