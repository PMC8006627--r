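#' Department-aware train/validation/test split
#'
#' Reproduces the study-design split used for structurally heterogeneous
#' report collections: the test set is drawn exclusively from one held-out
#' department (whose reports have a distinct structural profile), the
#' validation set excludes that department entirely, and the training set
#' mixes the remaining documents with a fixed number of held-out-department
#' documents so the tagger sees some of the atypical structure during
#' training.
#'
#' With `sizes = c(train = 447, validation = 213, test = 32)` on a
#' 692-document corpus containing 97 held-out-department documents and
#' `n_heldout_in_train = 65`, the three subsets have exactly those sizes.
#'
#' @param corpus A corpus tibble.
#' @param heldout_department Department whose documents are reserved for
#'   test (default 7).
#' @param sizes Length-3 numeric, `c(train, validation, test)`.  Values
#'   that all lie in (0, 1] are interpreted as fractions of the corpus
#'   (test count rounded, train gets the remainder after validation).
#' @param n_heldout_in_train How many held-out-department documents go into
#'   training.  `NULL` (default) means all of them that are not in test;
#'   an explicit value that leaves held-out documents unplaced, or that
#'   exceeds the available count, is a sizing error.
#' @param seed Integer seed; the same corpus and seed give the same split.
#' @return An object of class `corpus_split`: a named list of corpus
#'   tibbles `train`, `validation`, `test`, pairwise disjoint by `doc_id`
#'   and jointly covering the input corpus.
#' @examples
#' corp <- deid_corpus(sprintf("r%02d", 1:20), rep("informe", 20),
#'                     department = rep(c(7, 1, 2, 3), 5))
#' split_corpus(corp, sizes = c(0.6, 0.3, 0.1), seed = 1)
#' @export
split_corpus <- function(corpus, heldout_department = 7,
                         sizes = c(train = 0.646, validation = 0.308,
                                   test = 0.046),
                         n_heldout_in_train = NULL, seed = 1) {
  n <- nrow(corpus)
  sizes <- unname(sizes)
  if (length(sizes) != 3) abort("sizes must have length 3")
  if (all(sizes >= 0 & sizes <= 1) && sum(sizes) <= 1 + 1e-9 && n > 0) {
    n_test <- round(sizes[3] * n)
    n_val <- round(sizes[2] * n)
    n_train <- n - n_val - n_test
  } else {
    n_train <- sizes[1]; n_val <- sizes[2]; n_test <- sizes[3]
    if (n_train + n_val + n_test != n) {
      abort(sprintf("sizes sum to %d but the corpus has %d documents",
                    n_train + n_val + n_test, n))
    }
  }
  held <- which(corpus$department %in% heldout_department)
  if (length(held) < n_test) {
    abort(sprintf(
      "test requires %d held-out-department documents but only %d exist",
      n_test, length(held)
    ))
  }
  with_seed(seed, {
    test_idx <- sort(sample(held, n_test))
    rest_held <- setdiff(held, test_idx)
    if (is.null(n_heldout_in_train)) n_heldout_in_train <- length(rest_held)
    if (n_heldout_in_train != length(rest_held)) {
      abort(sprintf(
        "n_heldout_in_train = %d but %d held-out documents remain after test",
        n_heldout_in_train, length(rest_held)
      ))
    }
    other <- setdiff(seq_len(n), held)
    n_other_train <- n_train - n_heldout_in_train
    if (n_other_train < 0 || n_other_train > length(other)) {
      abort("training size incompatible with department composition")
    }
    train_other <- sort(sample(other, n_other_train))
    train_idx <- sort(c(rest_held, train_other))
    val_idx <- setdiff(other, train_other)
  })
  structure(
    list(train = corpus[train_idx, ],
         validation = corpus[val_idx, ],
         test = corpus[test_idx, ]),
    class = "corpus_split"
  )
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split> train: %d  validation: %d  test: %d\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}
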