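#' Gazetteers: weighted entity dictionaries
#'
#' A gazetteer is a tibble of unique `surface` strings with positive
#' sampling `weight`s and a `category` attribute.  Weights carry the
#' sampling distribution used for surrogate generation: name lists are
#' weighted by frequency of the name in the population, municipality lists
#' by municipal population, so common surrogates appear with realistic
#' relative frequency.
#'
#' @param surface Character entries.
#' @param weight Positive numeric weights (recycled if length 1).
#' @param category Entity label the entries instantiate.
#' @return A `gazetteer` tibble.
#' @examples
#' gazetteer(c("Valencia", "Alacant"), c(789744, 334887), "LOC")
#' @export
gazetteer <- function(surface, weight = 1, category) {
  weight <- rep_len(as.numeric(weight), length(surface))
  if (any(!is.finite(weight) | weight <= 0)) {
    abort("gazetteer weights must be positive and finite")
  }
  if (anyDuplicated(surface)) {
    agg <- tapply(weight, factor(surface, levels = unique(surface)), sum)
    surface <- names(agg)
    weight <- unname(agg)
  }
  structure(tibble(surface = as.character(surface), weight = weight),
            category = category,
            class = c("gazetteer", class(tibble())))
}

#' Load a gazetteer from a delimited file
#'
#' Files are UTF-8, one `surface<TAB>weight` pair per line; `#` comment
#' lines are ignored.  Entries below `min_weight` are dropped (the name
#' source used in this domain, for instance, only lists names with
#' frequency of at least 20); duplicate surfaces are merged by summing
#' their weights.
#'
#' @param path File path.
#' @param category Entity label for the entries.
#' @param min_weight Minimum retained weight (default 0 keeps everything).
#' @return A `gazetteer` tibble.
#' @export
read_gazetteer <- function(path, category, min_weight = 0) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    warn(sprintf("%s: empty gazetteer", path))
    return(gazetteer(character(), numeric(), category))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("%s:%d: expected 'surface<TAB>weight'",
                  path, line_no[bad[1]]))
  }
  w <- suppressWarnings(as.numeric(map_chr(parts, 2)))
  if (anyNA(w)) {
    abort(sprintf("%s:%d: non-numeric weight", path,
                  line_no[which(is.na(w))[1]]))
  }
  surf <- map_chr(parts, 1)
  sel <- w >= min_weight
  if (!any(sel)) {
    warn(sprintf("%s: no entries at or above min_weight = %g",
                 path, min_weight))
    return(gazetteer(character(), numeric(), category))
  }
  gazetteer(surf[sel], w[sel], category)
}

#' Load a directory of gazetteers as a gazetteer set
#'
#' Looks for files named by category: `name.tsv` (NAME), `loc.tsv` (LOC),
#' `inst.tsv` (INST), `dir.tsv` (DIR).  `example_gazetteers()` loads the
#' miniature synthetic set bundled with the package (realistic Spanish
#' given names and surnames with plausible frequency weights, real
#' Valencian-region municipality names with approximate populations, and
#' invented hospital, clinic and street entries), sufficient for testing
#' and for fully self-contained corpus generation.
#'
#' @param dir Directory containing the category files.
#' @param min_weight Passed to [read_gazetteer()].
#' @return A named list of gazetteers (`NAME`, `LOC`, `INST`, `DIR`).
#' @examples
#' gz <- example_gazetteers()
#' names(gz)
#' @export
read_gazetteer_set <- function(dir, min_weight = 0) {
  files <- c(NAME = "name.tsv", LOC = "loc.tsv",
             INST = "inst.tsv", DIR = "dir.tsv")
  missing <- !file.exists(file.path(dir, files))
  if (any(missing)) {
    abort(sprintf("gazetteer set incomplete: missing %s",
                  paste(files[missing], collapse = ", ")))
  }
  out <- purrr::imap(files, function(f, cat) {
    read_gazetteer(file.path(dir, f), cat, min_weight = min_weight)
  })
  out[names(files)]
}

#' @rdname read_gazetteer_set
#' @export
example_gazetteers <- function() {
  read_gazetteer_set(system.file("extdata", "gazetteers", package = "deidr"))
}

#' Weighted sampling with exclusion
#'
#' Draws one surface from a gazetteer with probability proportional to its
#' weight, renormalized over the entries not in `exclude`.  An excluded
#' surface is never returned; this realizes the guarantee that a surrogate
#' is never the original string.  Sampling uses cumulative-weight
#' inversion, so it is exact and driven by the R random number generator
#' (set a seed for reproducibility).
#'
#' @param gaz A gazetteer.
#' @param exclude Character surfaces that must not be drawn.
#' @return A single surface string.
#' @examples
#' set.seed(1)
#' gz <- gazetteer(c("Garcia", "Pons"), c(9, 1), "NAME")
#' weighted_sample(gz)
#' @export
weighted_sample <- function(gaz, exclude = character()) {
  keep <- !(gaz$surface %in% exclude)
  if (!any(keep)) {
    abort(class = "deidr_gazetteer_exhausted",
          message = sprintf("all %d entries of the %s gazetteer excluded",
                            nrow(gaz), attr(gaz, "category") %||% "?"))
  }
  w <- gaz$weight[keep]
  cum <- cumsum(w)
  u <- runif(1) * cum[length(cum)]
  gaz$surface[keep][findInterval(u, cum) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dictionary matching against a gazetteer
#'
#' Finds longest, non-overlapping, word-boundary-anchored occurrences of
#' gazetteer surfaces in a text.  Matching is case-insensitive but
#' accent-sensitive (clinical text varies capitalization freely, while
#' accents distinguish lexical items); multi-word surfaces are matched as
#' token sequences, and on ties the scan is left-to-right greedy, so a full
#' name always outranks its components.  Matching is context-blind by
#' design: an anatomical word that is also a surname will be matched —
#' the corpus-construction filters, not the matcher, deal with ambiguity.
#'
#' @param text A string.
#' @param gaz A gazetteer.
#' @return A span tibble labeled with the gazetteer's category.
#' @examples
#' gz <- gazetteer(c("Maria", "Maria Garcia"), 1, "NAME")
#' match_entities("vista por Maria Garcia", gz)
#' @export
match_entities <- function(text, gaz) {
  toks <- es_tokenize(text)
  if (nrow(toks) == 0 || nrow(gaz) == 0) return(entity_spans())
  low <- tolower(toks$token)
  # index gazetteer surfaces as lowercase token sequences by first token
  seqs <- map(strsplit(gaz$surface, "\\s+"), tolower)
  by_first <- split(seq_along(seqs), map_chr(seqs, 1))
  starts <- integer(); ends <- integer()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    cand <- by_first[[low[i]]]
    best_len <- 0L
    if (!is.null(cand)) {
      for (k in cand) {
        sq <- seqs[[k]]
        L <- length(sq)
        if (L > best_len && i + L - 1L <= n &&
            all(low[i:(i + L - 1L)] == sq) &&
            # multi-token surfaces must stay on one report line
            toks$line[i + L - 1L] == toks$line[i]) {
          best_len <- L
        }
      }
    }
    if (best_len > 0L) {
      starts <- c(starts, toks$start[i])
      ends <- c(ends, toks$end[i + best_len - 1L])
      i <- i + best_len
    } else {
      i <- i + 1L
    }
  }
  if (length(starts) == 0) return(entity_spans())
  entity_spans(starts, ends, rep(attr(gaz, "category"), length(starts)),
               str_slice(text, starts, ends))
}
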