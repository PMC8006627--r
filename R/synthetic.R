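# Synthetic annotated radiology-style reports.
#
# Three structural profiles are emulated:
#   * "headered"  — Spanish metadata headers followed by free text, the
#                   majority profile of regional radiology reports;
#   * "dept7"     — Valencian-language headers with the metadata value
#                   detached onto the following line, plus identifying
#                   entities alone on independent lines (the held-out
#                   department's structure);
#   * "meddocan"  — clinical-record style where every sensitive value sits
#                   immediately after its metadata descriptor, the rigidly
#                   structured profile used to probe structure overfitting.

profile_headers <- list(
  headered = c("INFORME:", "TECNICA:", "HALLAZGOS:", "CONCLUSION:",
               "COMPARACION:", "MOTIVO DE CONSULTA:", "PROTOCOLO:",
               "IMPRESION DIAGNOSTICA:"),
  dept7 = c("INFORME", "TECNICA", "TROBALLES", "CONCLUSIO", "DATA",
            "PACIENT", "METGE", "N HISTORIA"),
  meddocan = c("Nombre:", "Apellidos:", "NHC:", "NASS:", "Domicilio:",
               "Localidad:", "Fecha de nacimiento:", "Medico:",
               "Centro de salud:", "Episodio:")
)

# descriptor used by the meddocan profile for each entity category
meddocan_desc <- c(NAME = "Nombre:", DIR = "Domicilio:", LOC = "Localidad:",
                   NUM = "NHC:", FECHA = "Fecha de nacimiento:",
                   INST = "Centro de salud:")

# neutral clinical filler phrases (tag O); {ENT} marks an entity slot
filler_plain <- c(
  "TAC craneal sin hallazgos patologicos significativos.",
  "No se observan alteraciones densitometricas parenquimatosas.",
  "Sistema ventricular de tamano y morfologia normales.",
  "Linea media centrada sin desplazamientos.",
  "No se identifican colecciones hemorragicas intra ni extraaxiales.",
  "Estructuras de fosa posterior sin alteraciones.",
  "No hay captaciones patologicas tras la administracion de contraste.",
  "Estudio realizado con cortes axiales de 5 mm.",
  "Discreta atrofia corticosubcortical acorde con la edad.",
  "Silla turca y penasco sin alteraciones valorables.",
  "Calcificaciones fisiologicas de plexos coroideos.",
  "No se aprecian lesiones oseas liticas ni blasticas.",
  "Hipodensidades periventriculares de aspecto cronico.",
  "Se recomienda control evolutivo segun clinica.",
  "Exploracion dentro de limites normales.",
  "Leve engrosamiento mucoso en senos maxilares.",
  "Surcos corticales de amplitud conservada.",
  "No signos de hipertension endocraneal.",
  "Cisternas basales libres y simetricas.",
  "Union craneocervical sin anomalias.",
  "Resto del estudio sin otros hallazgos relevantes.",
  "Impresion de normalidad radiologica.",
  "Se completa el estudio con reconstrucciones coronales.",
  "Hallazgos en probable relacion con microangiopatia cronica.",
  "No se evidencian lesiones ocupantes de espacio.",
  "Fracturas no visualizadas en el presente estudio.",
  "Parenquima cerebral con diferenciacion sustancia gris blanca conservada.",
  "Sin cambios significativos respecto a estudio previo.",
  "Quiste aracnoideo temporal izquierdo ya conocido.",
  "Megacisterna magna como variante anatomica."
)
filler_slot <- c(
  "Paciente {ENT} acude por cefalea de larga evolucion.",
  "Informe solicitado por {ENT} del servicio de neurologia.",
  "Estudio realizado el {ENT} en condiciones basales.",
  "Se remite copia al centro {ENT} para su valoracion.",
  "Exploracion previa del {ENT} disponible para comparacion.",
  "Peticion con registro {ENT} del servicio de urgencias.",
  "Paciente trasladado desde {ENT} para completar estudio.",
  "Revisado y firmado por {ENT} .",
  "Se cita para control en {ENT} .",
  "Domicilio de contacto en {ENT} segun historia.",
  "Residente en {ENT} segun filiacion.",
  "Episodio {ENT} cerrado tras valoracion.",
  "Control programado para el {ENT} en consultas externas.",
  "Valorado conjuntamente con {ENT} de guardia.",
  "Documentacion remitida a {ENT} a peticion del facultativo."
)
# anatomical use of an ambiguous surname-word, tag O on purpose
filler_ambiguous <- c(
  "TAC de cabeza sin alteraciones significativas.",
  "Dolor referido en cabeza y region cervical.",
  "Exploracion de cabeza dentro de la normalidad."
)

spanish_months <- c("enero", "febrero", "marzo", "abril", "mayo", "junio",
                    "julio", "agosto", "septiembre", "octubre", "noviembre",
                    "diciembre")

#' Structural profile of a synthetic report
#'
#' @param name One of `"headered"`, `"dept7"`, `"meddocan"`.
#' @param header_labels Section-header strings; defaults per profile
#'   (Spanish for `headered`, Valencian for `dept7`, metadata descriptors
#'   for `meddocan`).
#' @param orphan_entity_rate Probability that an identifying entity is
#'   emitted alone on an independent line with no surrounding text.
#'   Defaults: 0.1 (`headered`), 0.9 (`dept7`, whose hallmark is sensitive
#'   values out of context), 0 (`meddocan`, where values always follow
#'   their descriptor).
#' @param ambiguity_rate Probability that a document gains a filler line
#'   using an ambiguous word (an anatomical term that is also a common
#'   surname) in its non-identifying sense, tagged `O`.
#' @return A `structure_profile` list.
#' @examples
#' structure_profile("dept7")
#' @export
structure_profile <- function(name = c("headered", "dept7", "meddocan"),
                              header_labels = NULL,
                              orphan_entity_rate = NULL,
                              ambiguity_rate = 0.1) {
  name <- match.arg(name)
  if (is.null(header_labels)) header_labels <- profile_headers[[name]]
  if (is.null(orphan_entity_rate)) {
    orphan_entity_rate <- c(headered = 0.1, dept7 = 0.9, meddocan = 0)[[name]]
  }
  stopifnot(orphan_entity_rate >= 0, orphan_entity_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1)
  if (name == "dept7" && orphan_entity_rate <= 0) {
    abort("the dept7 profile requires orphan_entity_rate > 0")
  }
  structure(list(name = name, header_labels = header_labels,
                 orphan_entity_rate = orphan_entity_rate,
                 ambiguity_rate = ambiguity_rate),
            class = "structure_profile")
}

#' Entity-share targets for the generator
#'
#' Percent of annotated tokens per entity category that the generator
#' steers the corpus towards.  The built-in columns mirror the annotation
#' distribution of the reference radiology corpus (training, validation
#' and held-out-department test subsets); shares sum to 100.
#'
#' @param subset Which built-in column to return.
#' @return Named numeric vector of percentages over [deid_labels()].
#' @examples
#' entity_share_targets("training")
#' @export
entity_share_targets <- function(subset = c("training", "validation",
                                            "test")) {
  subset <- match.arg(subset)
  tab <- list(
    training   = c(CAB = 21.37, NAME = 35.34, DIR = 1.38, LOC = 0.85,
                   NUM = 12.47, FECHA = 17.79, INST = 10.80),
    validation = c(CAB = 20.87, NAME = 33.45, DIR = 2.23, LOC = 0.97,
                   NUM = 12.29, FECHA = 18.86, INST = 11.33),
    test       = c(CAB = 9.40, NAME = 30.25, DIR = 5.64, LOC = 2.04,
                   NUM = 11.21, FECHA = 23.51, INST = 17.95)
  )[[subset]]
  tab * (100 / sum(tab))
}

# --- entity surface generators ----------------------------------------

random_fecha <- function(format = NULL) {
  if (is.null(format)) format <- sample(c("slash", "dash", "written"), 1)
  y <- sample(1990:2024, 1)
  m <- sample(1:12, 1)
  dmax <- c(31, if (y %% 4 == 0 && (y %% 100 != 0 || y %% 400 == 0)) 29
            else 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  d <- sample(seq_len(dmax), 1)
  switch(format,
    slash = sprintf("%02d/%02d/%d", d, m, y),
    dash = sprintf("%02d-%02d-%d", d, m, y),
    written = sprintf("%d de %s de %d", d, spanish_months[m], y)
  )
}

# TRUE when the surface is a well-formed calendar date in one of the
# emitted format families
parse_fecha <- function(surface) {
  m <- regmatches(surface,
    regexec("^(\\d{1,2})[/-](\\d{1,2})[/-](\\d{4})$", surface))[[1]]
  if (length(m) == 0) {
    m <- regmatches(surface,
      regexec("^(\\d{1,2}) de (\\p{L}+) de (\\d{4})$", surface,
              perl = TRUE))[[1]]
    if (length(m) == 0) return(FALSE)
    mon <- match(tolower(m[3]), spanish_months)
    if (is.na(mon)) return(FALSE)
    m[3] <- as.character(mon)
  }
  d <- as.integer(m[2]); mo <- as.integer(m[3]); y <- as.integer(m[4])
  !is.na(as.Date(sprintf("%d-%02d-%02d", y, mo, d), format = "%Y-%m-%d"))
}

random_num <- function() {
  pat <- sample(c("digits", "grouped", "prefixed", "suffixed"), 1,
                prob = c(0.4, 0.25, 0.2, 0.15))
  digits <- function(k) paste(sample(0:9, k, replace = TRUE), collapse = "")
  letters_up <- function(k) paste(sample(LETTERS, k, replace = TRUE),
                                  collapse = "")
  switch(pat,
    digits = digits(sample(6:10, 1)),
    grouped = paste(digits(sample(3:4, 1)), digits(sample(3:4, 1)),
                    digits(2), sep = "-"),
    prefixed = paste0(letters_up(sample(1:2, 1)), digits(sample(6:8, 1))),
    suffixed = paste0(digits(sample(6:8, 1)), letters_up(1))
  )
}

random_name <- function(gaz, k = NULL, exclude = character()) {
  if (is.null(k)) k <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
  parts <- character(k)
  for (i in seq_len(k)) {
    parts[i] <- weighted_sample(gaz, exclude = exclude)
  }
  paste(parts, collapse = " ")
}

# Novel name not present in any gazetteer, emulating the long tail of
# real names that a frequency-truncated registry misses.
random_unlisted_name <- function(k = NULL) {
  if (is.null(k)) k <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
  paste(map_chr(seq_len(k), function(i) fallback_word("")), collapse = " ")
}

entity_surface <- function(label, gazetteers, unlisted_name_rate = 0) {
  if (label == "NAME" && runif(1) < unlisted_name_rate) {
    return(random_unlisted_name())
  }
  switch(label,
    NAME = random_name(gazetteers$NAME),
    LOC = weighted_sample(gazetteers$LOC),
    INST = weighted_sample(gazetteers$INST),
    DIR = weighted_sample(gazetteers$DIR),
    FECHA = random_fecha(),
    NUM = random_num(),
    abort(sprintf("no generator source for category %s", label))
  )
}

# --- corpus-level share balancing -------------------------------------

# environment tracking annotated-token counts per category; next_cat picks
# the allowed category with the largest share deficit, which makes corpus
# shares converge to the target as documents accumulate
share_counter <- function(target) {
  stopifnot(abs(sum(target) - 100) < 0.01, all(target > 0))
  env <- new.env(parent = emptyenv())
  env$cnt <- setNames(numeric(length(deid_labels())), deid_labels())
  env$target <- target[deid_labels()]
  env
}

counter_next <- function(env, allowed) {
  tot <- sum(env$cnt)
  share <- if (tot == 0) env$cnt else 100 * env$cnt / tot
  deficit <- (env$target - share)[allowed]
  allowed[which.max(deficit)]
}

counter_add <- function(env, label, n_tokens) {
  env$cnt[label] <- env$cnt[label] + n_tokens
}

n_tokens_of <- function(surface) nrow(es_tokenize(surface))

# --- document assembly ------------------------------------------------

#' Generate one synthetic annotated report
#'
#' Builds a report line by line: section-header lines (annotated `CAB`),
#' clinical filler sentences from a bundled phrase bank (tag `O`), and
#' identifying entities drawn from the gazetteers plus generated dates
#' (valid calendar dates in mixed numeric and written formats) and
#' record/license-style codes.  Entity categories are chosen by a
#' corpus-share balancer when a `counter` is supplied, otherwise by the
#' target shares alone.  Placement follows the profile: embedded in filler
#' text, alone on an independent line (orphan), or immediately after a
#' metadata descriptor.
#'
#' @param profile A [structure_profile()].
#' @param gazetteers A gazetteer set providing `NAME`, `LOC`, `INST`,
#'   `DIR` (see [read_gazetteer_set()]).
#' @param doc_id Document identifier.
#' @param target Percent shares steering category choice.
#' @param counter Internal share counter shared across a corpus.
#' @param annotated_tokens Approximate number of annotated tokens to place.
#' @param entity_density Fraction of all tokens that should be annotated;
#'   plain filler lines are appended until the density drops to this level.
#' @param unlisted_name_rate Probability that a NAME instance is a novel
#'   synthesized name absent from the gazetteer, emulating the long tail
#'   of real names that a frequency-truncated registry misses (reports
#'   contain such names; detecting them requires character-level cues
#'   rather than lexical memory).
#' @return A one-row corpus tibble.
#' @examples
#' set.seed(7)
#' generate_document(structure_profile("headered"), example_gazetteers())
#' @export
generate_document <- function(profile, gazetteers, doc_id = "synthetic-001",
                              target = entity_share_targets("training"),
                              counter = NULL,
                              annotated_tokens = NULL,
                              entity_density = 0.15,
                              unlisted_name_rate = 0.05) {
  for (cat in c("NAME", "LOC", "INST", "DIR")) {
    if (is.null(gazetteers[[cat]]) || nrow(gazetteers[[cat]]) == 0) {
      abort(sprintf("generation requires a non-empty %s gazetteer", cat))
    }
  }
  if (is.null(counter)) counter <- share_counter(target)
  if (is.null(annotated_tokens)) {
    annotated_tokens <- max(12L, round(rnorm(1, 32, 6)))
  }
  lines <- list()   # each: list(text, spans relative to the line)
  blocks <- integer()  # lines sharing a block stay adjacent when shuffled
  cur_block <- 0L
  push <- function(text, spans = entity_spans(), same_block = FALSE) {
    if (!same_block) cur_block <<- cur_block + 1L
    lines[[length(lines) + 1L]] <<- list(text = text, spans = spans)
    blocks[length(blocks) + 1L] <<- cur_block
  }
  headers_left <- sample(profile$header_labels)
  added <- 0L
  allow_cab <- profile$name != "meddocan"
  allowed <- c(if (allow_cab) "CAB", identifying_labels())
  pending_detached <- FALSE  # dept7: a header awaiting its detached value
  while (added < annotated_tokens) {
    cat <- counter_next(counter, allowed)
    if (cat == "CAB") {
      if (length(headers_left) == 0) headers_left <- sample(profile$header_labels)
      hdr <- headers_left[1]
      headers_left <- headers_left[-1]
      push(hdr, entity_spans(0, nchr(hdr), "CAB", hdr))
      nt <- n_tokens_of(hdr)
      counter_add(counter, "CAB", nt)
      added <- added + nt
      if (profile$name == "dept7") pending_detached <- TRUE
      next
    }
    surface <- entity_surface(cat, gazetteers, unlisted_name_rate)
    nt <- n_tokens_of(surface)
    if (profile$name == "meddocan") {
      desc <- meddocan_desc[[cat]]
      text <- paste(desc, surface)
      sp <- entity_spans(
        c(0, nchr(desc) + 1L), c(nchr(desc), nchr(text)),
        c("CAB", cat), c(desc, surface)
      )
      push(text, sp)
      ncab <- n_tokens_of(desc)
      counter_add(counter, "CAB", ncab)
      counter_add(counter, cat, nt)
      added <- added + nt + ncab
      next
    }
    detached <- pending_detached
    orphan <- detached || runif(1) < profile$orphan_entity_rate
    pending_detached <- FALSE
    if (orphan) {
      # a detached metadata value stays in its header's block
      push(surface, entity_spans(0, nchr(surface), cat, surface),
           same_block = detached)
    } else {
      tmpl <- sample(filler_slot, 1)
      pre <- sub("\\{ENT\\}.*$", "", tmpl)
      post <- sub("^.*\\{ENT\\}", "", tmpl)
      text <- paste0(pre, surface, post)
      push(text, entity_spans(nchr(pre), nchr(pre) + nchr(surface),
                              cat, surface))
    }
    counter_add(counter, cat, nt)
    added <- added + nt
  }
  if (runif(1) < profile$ambiguity_rate) {
    push(sample(filler_ambiguous, 1))
  }
  # pad with plain filler so annotated tokens make up ~entity_density of all
  total_tokens <- sum(map_int(lines, ~ n_tokens_of(.x$text)))
  while (entity_density > 0 && added / total_tokens > entity_density) {
    f <- sample(filler_plain, 1)
    push(f)
    total_tokens <- total_tokens + n_tokens_of(f)
  }
  # shuffle at block level (keeps detached metadata under its header and
  # the leading header block first)
  ids <- unique(blocks)
  if (length(ids) > 2) {
    ids <- c(ids[1], sample(ids[-1]))
  }
  lines <- lines[order(match(blocks, ids))]
  texts <- map_chr(lines, "text")
  offs <- c(0L, cumsum(nchr(texts) + 1L))[seq_along(texts)]
  spans <- bind_rows(map2(lines, offs, function(l, o) {
    if (nrow(l$spans) == 0) return(l$spans)
    mutate(l$spans, start = .data$start + o, end = .data$end + o)
  }))
  if (is.null(spans) || nrow(spans) == 0) spans <- entity_spans()
  spans <- arrange(spans, .data$start)
  dept <- if (profile$name == "dept7") 7L else
    sample(setdiff(1:17, 7), 1)
  deid_corpus(doc_id, paste(texts, collapse = "\n"), dept, list(spans))
}

#' Generate a synthetic annotated corpus
#'
#' Draws each document's structural profile from `profile_mix`, balances
#' entity categories across the whole corpus so annotated-token shares
#' converge to `target` as the corpus grows, and is byte-identical across
#' runs with the same seed.
#'
#' @param n Number of documents.
#' @param profile_mix Named fractions over profiles, summing to 1.  The
#'   default mixes the majority headered profile with the
#'   held-out-department profile in roughly the reference corpus
#'   proportion (97 of 692 documents).
#' @param target Percent shares per category, see [entity_share_targets()];
#'   applied to every profile except `dept7`.
#' @param dept7_target Percent shares for `dept7` documents, which in the
#'   reference corpus carry systematically more addresses, places and
#'   institutions and fewer headers than the rest; set to `target` to
#'   make the whole corpus homogeneous.
#' @param gazetteers Gazetteer set.
#' @param seed Integer seed driving all sampling.
#' @param entity_density,ambiguity_rate,unlisted_name_rate Passed to the
#'   document generator and profiles.
#' @return A corpus tibble with `n` rows.
#' @examples
#' corp <- generate_corpus(5, seed = 1)
#' corp$doc_id
#' @export
generate_corpus <- function(n,
                            profile_mix = c(headered = 0.86, dept7 = 0.14),
                            target = entity_share_targets("training"),
                            gazetteers = example_gazetteers(),
                            seed = 1,
                            dept7_target = entity_share_targets("test"),
                            entity_density = 0.15,
                            ambiguity_rate = 0.1,
                            unlisted_name_rate = 0.05) {
  stopifnot(n >= 0)
  if (abs(sum(profile_mix) - 1) > 1e-6) {
    abort("profile_mix fractions must sum to 1")
  }
  if (n == 0) return(deid_corpus(character(), character()))
  profs <- map(names(profile_mix), structure_profile,
               ambiguity_rate = ambiguity_rate)
  names(profs) <- names(profile_mix)
  with_seed(seed, {
    counter <- share_counter(target)
    counter7 <- share_counter(dept7_target)
    which_prof <- sample(names(profile_mix), n, replace = TRUE,
                         prob = profile_mix)
    rows <- map(seq_len(n), function(i) {
      is7 <- which_prof[i] == "dept7"
      generate_document(
        profs[[which_prof[i]]], gazetteers,
        doc_id = sprintf("syn-%s-%04d", which_prof[i], i),
        target = if (is7) dept7_target else target,
        counter = if (is7) counter7 else counter,
        entity_density = entity_density,
        unlisted_name_rate = unlisted_name_rate
      )
    })
  })
  bind_rows(rows)
}

#' Annotated-token shares of a corpus
#'
#' Percent of annotated tokens per entity category, the quantity the
#' generator steers towards its target.
#'
#' @param corpus A corpus tibble.
#' @return A tibble with `label`, `tokens`, `share` (percent).
#' @export
corpus_entity_shares <- function(corpus) {
  counts <- setNames(numeric(length(deid_labels())), deid_labels())
  for (i in seq_len(nrow(corpus))) {
    sp <- corpus$spans[[i]]
    for (k in seq_len(nrow(sp))) {
      counts[sp$label[k]] <- counts[sp$label[k]] + n_tokens_of(sp$surface[k])
    }
  }
  tibble(label = names(counts), tokens = as.integer(counts),
         share = if (sum(counts) > 0) 100 * counts / sum(counts) else
           counts * 0)
}
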