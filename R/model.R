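# BiLSTM-CRF taggers: configuration, vocabulary, training, decoding and
# persistence.  The numerical core lives in src/nnet.cpp; this file owns
# data preparation, the optimization loop, early stopping and EMA
# bookkeeping.

arch_codes <- c("lstm-crf" = 0L, "lstm-lstm-crf" = 1L,
                "conv-lstm-crf" = 2L)

#' Tagger configuration
#'
#' Three architectures are available, all ending in a linear-chain CRF
#' over BIO tags: `"lstm-crf"` (word embeddings into a word-level BiLSTM,
#' no character channel), `"lstm-lstm-crf"` (adds a character BiLSTM whose
#' final states are concatenated to the word vector) and
#' `"conv-lstm-crf"` (adds a width-3 character CNN with max-over-time
#' pooling instead).  Word embeddings are randomly initialized
#' (uniform ±0.05) by default; `embeddings_path` optionally points to a
#' text-format pretrained vector file (`word v1 ... vd` per line) whose
#' vectors overwrite the random rows for in-vocabulary words.  Words are
#' lowercased for the word channel; the character channel sees original
#' case, which is the key capitalization cue for names.  With `use_ema`,
#' a shadow copy of all parameters is maintained as an exponential moving
#' average and used for validation and prediction.
#'
#' @param architecture One of `"lstm-lstm-crf"`, `"conv-lstm-crf"`,
#'   `"lstm-crf"`.
#' @param word_dim,char_dim,char_hidden,word_hidden Layer sizes.  Char
#'   settings are ignored by `"lstm-crf"`.
#' @param dropout Dropout rate on the word representation during training.
#' @param use_ema,ema_decay Exponential moving average of the weights.
#' @param epochs,batch_size,learning_rate,patience Optimization settings
#'   (Adam; early stopping after `patience` epochs without validation
#'   improvement).
#' @param seed Integer seed; training is bit-reproducible given the seed
#'   (single-threaded).
#' @param embeddings_path Optional pretrained word-vector text file.
#' @return A `tagger_config` list.
#' @examples
#' tagger_config("lstm-lstm-crf", word_dim = 50, word_hidden = 50)
#' @export
tagger_config <- function(architecture = c("lstm-lstm-crf",
                                           "conv-lstm-crf", "lstm-crf"),
                          word_dim = 100, char_dim = 25, char_hidden = 25,
                          word_hidden = 100, dropout = 0.5,
                          use_ema = FALSE, ema_decay = 0.999,
                          epochs = 50, batch_size = 16,
                          learning_rate = 1e-3, patience = 5, seed = 42,
                          embeddings_path = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(word_dim > 0, char_dim > 0, char_hidden > 0, word_hidden > 0,
            dropout >= 0, dropout < 1, ema_decay > 0, ema_decay < 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0, patience >= 1)
  structure(list(
    architecture = architecture, word_dim = as.integer(word_dim),
    char_dim = as.integer(char_dim), char_hidden = as.integer(char_hidden),
    word_hidden = as.integer(word_hidden), dropout = dropout,
    use_ema = isTRUE(use_ema), ema_decay = ema_decay,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, patience = as.integer(patience),
    seed = as.integer(seed), embeddings_path = embeddings_path
  ), class = "tagger_config")
}

# --- vocabulary -------------------------------------------------------

# word/char/tag inventories from a training corpus; index 1 is UNK
build_vocab <- function(corpus) {
  words <- character(); chars <- character()
  for (i in seq_len(nrow(corpus))) {
    toks <- es_tokenize(corpus$text[i])$token
    words <- c(words, tolower(toks))
    chars <- c(chars, unlist(strsplit(toks, "")))
  }
  list(
    words = c("<unk>", sort(unique(words))),
    chars = c("<unk>", sort(unique(chars))),
    tags = bio_tags()
  )
}

# tokenized, indexed training sequences; the training unit is the report
# line (entities in this document family are line-scoped)
prep_sequences <- function(corpus, vocab) {
  seqs <- list()
  for (i in seq_len(nrow(corpus))) {
    tagged <- tag_document(corpus$text[i], corpus$spans[[i]])
    if (nrow(tagged) == 0) next
    for (idx in split(seq_len(nrow(tagged)), tagged$line)) {
      toks <- tagged$token[idx]
      seqs[[length(seqs) + 1L]] <- list(
        words = match(tolower(toks), vocab$words, nomatch = 1L) - 1L,
        chars = map(strsplit(toks, ""), function(ch) {
          match(ch, vocab$chars, nomatch = 1L) - 1L
        }),
        tags = match(tagged$tag[idx], vocab$tags) - 1L
      )
    }
  }
  seqs
}

# --- parameters -------------------------------------------------------

init_params <- function(config, vocab) {
  u <- function(r, c) matrix(runif(r * c, -0.05, 0.05), r, c)
  arch <- arch_codes[[config$architecture]]
  dw <- config$word_dim
  h <- config$word_hidden
  hc <- config$char_hidden
  dc <- config$char_dim
  din <- dw + if (arch >= 1) 2L * hc else 0L
  k <- length(vocab$tags)
  p <- list(
    Ew = u(length(vocab$words), dw),
    Wf = u(din + h, 4 * h), bf = matrix(0, 1, 4 * h),
    Wb = u(din + h, 4 * h), bb = matrix(0, 1, 4 * h),
    P = u(2 * h, k), pb = matrix(0, 1, k),
    Tr = u(k + 2, k + 2)
  )
  if (arch >= 1) p$Ec <- u(length(vocab$chars), dc)
  if (arch == 1) {
    p$Cf <- u(dc + hc, 4 * hc); p$cbf <- matrix(0, 1, 4 * hc)
    p$Cb <- u(dc + hc, 4 * hc); p$cbb <- matrix(0, 1, 4 * hc)
  }
  if (arch == 2) {
    p$Fc <- u(3 * dc, 2 * hc); p$fcb <- matrix(0, 1, 2 * hc)
  }
  if (!is.null(config$embeddings_path)) {
    p$Ew <- load_pretrained(config$embeddings_path, vocab$words, p$Ew)
  }
  p
}

# overwrite embedding rows for words found in a GloVe/word2vec text file
load_pretrained <- function(path, words, Ew) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), " ", fixed = TRUE)[[1]]
    if (length(parts) != ncol(Ew) + 1) next
    i <- match(tolower(parts[1]), words)
    if (!is.na(i)) Ew[i, ] <- as.numeric(parts[-1])
  }
  Ew
}

deep_copy <- function(params) {
  lapply(params, function(m) matrix(as.numeric(m), nrow(m), ncol(m)))
}

zeros_like <- function(params) {
  lapply(params, function(m) matrix(0, nrow(m), ncol(m)))
}

#' Closed-form parameter count of a tagger configuration
#'
#' Guards against wiring errors: the count implied by the configuration
#' and vocabulary sizes must equal the number of allocated parameters.
#'
#' @param config A [tagger_config()].
#' @param n_words,n_chars,n_tags Vocabulary sizes (including the unknown
#'   entries; `n_tags` is the BIO tag inventory without START/STOP).
#' @return Integer parameter count.
#' @export
tagger_parameter_count <- function(config, n_words, n_chars,
                                   n_tags = length(bio_tags())) {
  arch <- arch_codes[[config$architecture]]
  dw <- config$word_dim; h <- config$word_hidden
  dc <- config$char_dim; hc <- config$char_hidden
  din <- dw + if (arch >= 1) 2 * hc else 0
  n <- n_words * dw +                       # word embeddings
    2 * ((din + h) * 4 * h + 4 * h) +       # word BiLSTM
    2 * h * n_tags + n_tags +               # projection
    (n_tags + 2)^2                          # CRF transitions
  if (arch >= 1) n <- n + n_chars * dc
  if (arch == 1) n <- n + 2 * ((dc + hc) * 4 * hc + 4 * hc)
  if (arch == 2) n <- n + 3 * dc * 2 * hc + 2 * hc
  as.integer(n)
}

# --- CRF wrappers -----------------------------------------------------

#' Linear-chain CRF primitives
#'
#' The CRF scores a tag path as the sum of per-token emission scores and
#' tag-transition scores, including transitions from a START state into
#' the first tag and from the last tag into a STOP state.  `transitions`
#' is a `(K+2) x (K+2)` matrix for `K` tags: rows/columns `1..K` are the
#' tags, row `K+1` is START (used as origin only) and column `K+2` is
#' STOP (used as destination only); the START column and STOP row are
#' never read.  `crf_log_partition()` returns the log of the summed
#' exponentiated scores of all `K^T` paths, computed stably in log space;
#' `crf_nll()` the negative log-likelihood of a gold path (non-negative);
#' `viterbi_decode()` an argmax path and its score, breaking ties toward
#' the lowest tag index at every backtrack step.
#'
#' @param emissions `T x K` matrix of per-token tag scores.
#' @param transitions `(K+2) x (K+2)` transition score matrix.
#' @param tags Integer gold path (1-based tag indices, length `T`).
#' @return `crf_log_partition()` and `crf_nll()` return a scalar;
#'   `viterbi_decode()` a list with `path` (1-based) and `score`.
#' @examples
#' em <- matrix(0, 1, 2)
#' tr <- matrix(0, 4, 4)
#' crf_log_partition(em, tr)  # log(2)
#' viterbi_decode(em, tr)$path
#' @export
crf_log_partition <- function(emissions, transitions) {
  check_crf_args(emissions, transitions)
  cpp_crf_log_partition(emissions, transitions)
}

#' @rdname crf_log_partition
#' @export
crf_nll <- function(emissions, transitions, tags) {
  check_crf_args(emissions, transitions)
  tags <- as.integer(tags)
  if (length(tags) != nrow(emissions)) {
    abort("tags must have one entry per emission row")
  }
  if (any(tags < 1 | tags > ncol(emissions))) {
    abort("tag index out of range")
  }
  cpp_crf_nll(emissions, transitions, tags - 1L)
}

#' @rdname crf_log_partition
#' @export
viterbi_decode <- function(emissions, transitions) {
  check_crf_args(emissions, transitions)
  out <- cpp_viterbi(emissions, transitions)
  list(path = out$path + 1L, score = out$score)
}

check_crf_args <- function(emissions, transitions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1) {
    abort("emissions must be a matrix with at least one row")
  }
  k <- ncol(emissions)
  if (!is.matrix(transitions) || any(dim(transitions) != k + 2)) {
    abort(sprintf("transitions must be %d x %d (tags + START/STOP)",
                  k + 2, k + 2))
  }
  if (any(!is.finite(emissions))) abort("emissions must be finite")
  invisible(TRUE)
}

#' Exponential moving average of parameter sets
#'
#' `shadow' = decay * shadow + (1 - decay) * current`, elementwise over
#' congruent named lists of matrices.  With `decay = 0` the shadow equals
#' the current parameters; a constant trajectory is a fixed point.
#'
#' @param shadow,current Congruent named lists of numeric matrices.
#' @param decay EMA decay in `[0, 1)`.
#' @return The updated shadow list.
#' @examples
#' s <- list(w = matrix(0, 1, 1))
#' cur <- list(w = matrix(1, 1, 1))
#' apply_ema(apply_ema(s, cur, 0.9), cur, 0.9)$w  # 1 - 0.9^2 = 0.19
#' @export
apply_ema <- function(shadow, current, decay) {
  stopifnot(decay >= 0, decay < 1)
  if (!identical(names(shadow), names(current))) {
    abort("shadow and current parameter sets are not congruent")
  }
  map2(shadow, current, function(s, c) {
    if (!identical(dim(s), dim(c))) abort("parameter shape mismatch")
    decay * s + (1 - decay) * c
  })
}

# --- training ---------------------------------------------------------

#' Train a BiLSTM-CRF tagger
#'
#' Minibatch Adam on the mean CRF negative log-likelihood, with the
#' report line as training unit.  After every epoch the global
#' de-identification F1 (token-level, binary identifying-vs-not) is
#' computed on the validation corpus — using the EMA shadow parameters
#' when `use_ema` is set — and logged; training stops early after
#' `patience` epochs without improvement and returns the best-validation
#' checkpoint.
#'
#' @param train_corpus,val_corpus Annotated corpus tibbles.
#' @param config A [tagger_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return A `deid_tagger` object: configuration, vocabulary, best
#'   parameters (raw and, when enabled, EMA shadow — the shadow is what
#'   [predict.deid_tagger()] uses), and the per-epoch training log
#'   (see [tidy.deid_tagger()]).
#' @export
train_tagger <- function(train_corpus, val_corpus, config = tagger_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "tagger_config"))
  if (nrow(train_corpus) == 0 || nrow(val_corpus) == 0) {
    abort("training and validation corpora must be non-empty")
  }
  arch <- arch_codes[[config$architecture]]
  vocab <- build_vocab(train_corpus)
  train_seqs <- prep_sequences(train_corpus, vocab)
  val_seqs <- prep_sequences(val_corpus, vocab)
  if (length(train_seqs) == 0) abort("no non-empty training sequences")
  log_rows <- list()
  with_seed(config$seed, {
    params <- init_params(config, vocab)
    m <- zeros_like(params)
    v <- zeros_like(params)
    shadow <- if (config$use_ema) deep_copy(params) else NULL
    step <- 0L
    best <- list(f1 = -Inf, params = NULL, shadow = NULL, epoch = 0L)
    stale <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(train_seqs))
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        step <- step + 1L
        res <- cpp_batch_grad(params, arch, train_seqs[idx],
                              config$dropout,
                              sample.int(.Machine$integer.max, 1))
        if (!is.finite(res$loss)) {
          abort(sprintf(
            "training diverged (non-finite loss at epoch %d, step %d); try a lower learning rate",
            epoch, step
          ))
        }
        cpp_adam_step(params, res$grads, m, v, step,
                      config$learning_rate, 0.9, 0.999, 1e-8)
        if (config$use_ema) {
          cpp_ema_update(shadow, params, config$ema_decay)
        }
        epoch_loss <- epoch_loss + res$loss
        n_batches <- n_batches + 1L
      }
      pred_params <- if (config$use_ema) shadow else params
      val <- validation_metrics(pred_params, arch, val_seqs, vocab)
      log_rows[[epoch]] <- tibble(
        epoch = epoch, train_nll = epoch_loss / n_batches,
        val_precision = val$precision, val_recall = val$recall,
        val_f1 = val$f1
      )
      if (!quiet) {
        message(sprintf(
          "epoch %2d  nll %.4f  val P/R/F1 %.4f/%.4f/%.4f",
          epoch, epoch_loss / n_batches, val$precision, val$recall, val$f1
        ))
      }
      if (val$f1 > best$f1) {
        best <- list(f1 = val$f1, params = deep_copy(params),
                     shadow = if (config$use_ema) deep_copy(shadow),
                     epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })
  structure(list(
    config = config, vocab = vocab, arch = arch,
    params = best$params, ema = best$shadow,
    best_epoch = best$epoch,
    n_parameters = sum(map_int(best$params, length)),
    log = bind_rows(log_rows)
  ), class = "deid_tagger")
}

# token-level binary identifying P/R/F1 over prepped sequences
validation_metrics <- function(params, arch, seqs, vocab) {
  ident_tag <- substring(vocab$tags, 3) %in% identifying_labels() &
    vocab$tags != "O"
  tp <- fp <- fn <- 0L
  for (s in seqs) {
    path <- cpp_predict_tags(params, arch, s) + 1L
    gi <- ident_tag[s$tags + 1L]
    pi <- ident_tag[path]
    tp <- tp + sum(gi & pi)
    fp <- fp + sum(pi & !gi)
    fn <- fn + sum(gi & !pi)
  }
  as.list(prf(tp, fp, fn)[1, ])
}

# parameters used for prediction: EMA shadow when present
prediction_params <- function(model) model$ema %||% model$params

#' Emission scores for a token sequence
#'
#' Runs a trained model's encoder (embeddings, character channel, word
#' BiLSTM, linear projection) on one token sequence and returns the
#' `T x K` matrix of per-token tag scores consumed by the CRF.
#'
#' @param model A `deid_tagger`.
#' @param tokens Character vector of tokens (one report line).
#' @return Numeric matrix with one row per token, columns named by tag.
#' @export
encode_tokens <- function(model, tokens) {
  stopifnot(inherits(model, "deid_tagger"))
  if (length(tokens) == 0) abort("cannot encode an empty token sequence")
  seq <- list(
    words = match(tolower(tokens), model$vocab$words, nomatch = 1L) - 1L,
    chars = map(strsplit(tokens, ""), function(ch) {
      match(ch, model$vocab$chars, nomatch = 1L) - 1L
    })
  )
  em <- cpp_emissions(prediction_params(model), model$arch, seq)
  colnames(em) <- model$vocab$tags
  em
}

#' Predict entity spans with a trained tagger
#'
#' Tokenizes each document, decodes every report line with Viterbi,
#' repairs any dangling `I-` tags and converts the BIO tags back to
#' character spans.  Prediction is pure: the same model and text always
#' give the same spans.
#'
#' @param object A `deid_tagger`.
#' @param newdata A corpus tibble or character vector of texts.
#' @param ... Unused.
#' @return A list of span tibbles, one per document.
#' @export
predict.deid_tagger <- function(object, newdata, ...) {
  texts <- if (is.character(newdata)) newdata else newdata$text
  params <- prediction_params(object)
  map(texts, function(text) {
    toks <- es_tokenize(text)
    if (nrow(toks) == 0) return(entity_spans())
    tags <- character(nrow(toks))
    for (idx in split(seq_len(nrow(toks)), toks$line)) {
      tk <- toks$token[idx]
      seq <- list(
        words = match(tolower(tk), object$vocab$words, nomatch = 1L) - 1L,
        chars = map(strsplit(tk, ""), function(ch) {
          match(ch, object$vocab$chars, nomatch = 1L) - 1L
        })
      )
      path <- cpp_predict_tags(params, object$arch, seq) + 1L
      tags[idx] <- object$vocab$tags[path]
    }
    bio_to_spans(mutate(toks, tag = tags), text)
  })
}

#' @export
print.deid_tagger <- function(x, ...) {
  cat(sprintf(
    "<deid_tagger> %s%s  |V|=%d  params=%d  best epoch %d (val F1 %.4f)\n",
    x$config$architecture, if (x$config$use_ema) " +EMA" else "",
    length(x$vocab$words), x$n_parameters, x$best_epoch,
    max(x$log$val_f1)
  ))
  invisible(x)
}

#' Training log and summary of a fitted tagger
#'
#' `tidy()` returns the per-epoch log (training NLL and validation
#' precision/recall/F1); `glance()` a one-row summary.
#'
#' @param x A `deid_tagger`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.deid_tagger <- function(x, ...) x$log

#' @rdname tidy.deid_tagger
#' @export
glance.deid_tagger <- function(x, ...) {
  tibble(
    architecture = x$config$architecture, use_ema = x$config$use_ema,
    epochs_trained = nrow(x$log), best_epoch = x$best_epoch,
    best_val_f1 = max(x$log$val_f1), n_parameters = x$n_parameters
  )
}

#' @rdname tidy.deid_tagger
#' @param object A `deid_tagger`.
#' @export
autoplot.deid_tagger <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

# --- persistence ------------------------------------------------------

#' Save or load a tagger checkpoint
#'
#' A checkpoint is a directory of plain text files: `config.dcf`
#' (key-value configuration), `words.txt` / `chars.txt` / `tags.txt`
#' (vocabularies) and one `param-*.txt` per parameter matrix (full
#' precision).  `load_tagger()` restores a model usable by
#' [predict.deid_tagger()].
#'
#' @param model A `deid_tagger`.
#' @param dir Checkpoint directory.
#' @return `save_tagger()` returns `dir` invisibly; `load_tagger()` the
#'   restored model.
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg$embeddings_path <- NULL
  write.dcf(
    cbind(as.data.frame(cfg[!vapply(cfg, is.null, TRUE)]),
          best_epoch = model$best_epoch),
    file.path(dir, "config.dcf")
  )
  writeLines(enc2utf8(model$vocab$words), file.path(dir, "words.txt"),
             useBytes = TRUE)
  writeLines(enc2utf8(model$vocab$chars), file.path(dir, "chars.txt"),
             useBytes = TRUE)
  writeLines(model$vocab$tags, file.path(dir, "tags.txt"))
  save_param_set <- function(set, prefix) {
    for (nm in names(set)) {
      con <- file(file.path(dir, sprintf("%s-%s.txt", prefix, nm)), "w")
      writeLines(sprintf("%d %d", nrow(set[[nm]]), ncol(set[[nm]])), con)
      writeLines(sprintf("%.17g", as.numeric(set[[nm]])), con)
      close(con)
    }
  }
  save_param_set(model$params, "param")
  if (!is.null(model$ema)) save_param_set(model$ema, "ema")
  utils::write.csv(model$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  cfgfile <- file.path(dir, "config.dcf")
  if (!file.exists(cfgfile)) {
    abort(sprintf("%s is not a tagger checkpoint (no config.dcf)", dir))
  }
  raw <- as.list(as.data.frame(read.dcf(cfgfile), stringsAsFactors = FALSE))
  num <- function(x) as.numeric(x)
  config <- tagger_config(
    architecture = raw$architecture, word_dim = num(raw$word_dim),
    char_dim = num(raw$char_dim), char_hidden = num(raw$char_hidden),
    word_hidden = num(raw$word_hidden), dropout = num(raw$dropout),
    use_ema = identical(raw$use_ema, "TRUE"),
    ema_decay = num(raw$ema_decay), epochs = num(raw$epochs),
    batch_size = num(raw$batch_size),
    learning_rate = num(raw$learning_rate),
    patience = num(raw$patience), seed = num(raw$seed)
  )
  vocab <- list(
    words = readLines(file.path(dir, "words.txt"), encoding = "UTF-8"),
    chars = readLines(file.path(dir, "chars.txt"), encoding = "UTF-8"),
    tags = readLines(file.path(dir, "tags.txt"))
  )
  if (!identical(vocab$tags, bio_tags())) {
    abort("checkpoint tag inventory does not match this package version")
  }
  read_param_set <- function(prefix) {
    files <- list.files(dir, pattern = sprintf("^%s-.*\\.txt$", prefix),
                        full.names = TRUE)
    if (length(files) == 0) return(NULL)
    set <- map(files, function(f) {
      lines <- readLines(f)
      dims <- as.integer(strsplit(lines[1], " ")[[1]])
      matrix(as.numeric(lines[-1]), dims[1], dims[2])
    })
    names(set) <- sub(sprintf("^%s-(.*)\\.txt$", prefix), "\\1",
                      basename(files))
    canon <- c("Ew", "Wf", "bf", "Wb", "bb", "P", "pb", "Tr",
               "Ec", "Cf", "cbf", "Cb", "cbb", "Fc", "fcb")
    set[intersect(canon, names(set))]
  }
  params <- read_param_set("param")
  if (nrow(params$Ew) != length(vocab$words)) {
    abort("checkpoint integrity error: embedding rows != vocabulary size")
  }
  structure(list(
    config = config, vocab = vocab,
    arch = arch_codes[[config$architecture]],
    params = params, ema = read_param_set("ema"),
    best_epoch = as.integer(raw$best_epoch),
    n_parameters = sum(map_int(params, length)),
    log = tibble::as_tibble(utils::read.csv(file.path(dir, "log.csv")))
  ), class = "deid_tagger")
}
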