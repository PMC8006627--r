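---
title: "De-identifying Spanish clinical free text: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying Spanish clinical free text: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiology reports and other clinical free text contain protected health
information — names of patients and staff, dates, record numbers,
addresses, the hospitals involved — embedded in otherwise valuable
narrative.  Before such text can be reused for research it must be
de-identified, and in Spanish-language healthcare systems this has to be
done with Spanish-specific tooling: rule sets built for English do not
transfer.

`deidr` implements a two-stage strategy.  First, a neural sequence
tagger finds entity mentions in seven categories: section headers
(`CAB`), person names (`NAME`), full addresses (`DIR`), populated places
(`LOC`), identifying numbers and codes (`NUM`), dates (`FECHA`) and
healthcare institutions (`INST`).  Second, a randomizer replaces every
detected identifying mention with a synthetic surrogate of the same
category.  The substitution step is what makes the combination robust:
since substituted text is indistinguishable from real text of the same
category, any mention the tagger *missed* is hidden among surrogates
rather than being the only "real-looking" string left in an otherwise
scrubbed document.  Headers (`CAB`) are detected but deliberately kept,
because downstream information extraction relies on them.

## Sequence tagging model

Documents are tokenized with exact character offsets (whitespace
splitting, punctuation split off, date-like and code-like runs such as
`14/03/2018` or `1234-AB` kept whole so each entity surface stays one
token) and tagged in the BIO scheme: `B-X` opens a mention of category
`X`, `I-X` continues it, `O` is outside.  The tagging unit is the report
line, because in this document family entities are line-scoped and line
structure itself is signal — some departments emit a bare name or date
on its own line.

Three encoder architectures are provided, all ending in a linear-chain
conditional random field:

* **lstm-crf** — word embeddings into a bidirectional LSTM, linearly
  projected to per-tag scores;
* **lstm-lstm-crf** — adds a character-level BiLSTM per token; the final
  forward and backward states are concatenated to the word vector;
* **conv-lstm-crf** — adds instead a width-3 character CNN with
  max-over-time pooling.

Words are lowercased for the word channel; the character channel sees
the original casing, which is the dominant cue for `NAME`.  Digits are
not normalized — numeric shape is exactly the signal for `NUM` and
`FECHA`.

The CRF scores a tag path $y_{1:T}$ as

$$s(y) = \sum_{t} e_{t,y_t} + a_{\mathrm{START},y_1}
       + \sum_{t>1} a_{y_{t-1},y_t} + a_{y_T,\mathrm{STOP}}$$

with emissions $e$ from the encoder and transition scores $a$.  Training
minimizes the negative log-likelihood $\log Z - s(y^{\mathrm{gold}})$,
with the log-partition $\log Z$ computed by the forward algorithm in log
space; decoding is Viterbi.  No hard BIO constraints are imposed on the
transitions; instead, any dangling `I-X` in decoder output is repaired
to `B-X` before span conversion, so conversion is total on raw model
output.  Viterbi ties are broken toward the lowest tag index, making
decoding fully deterministic.

Optimization is minibatch Adam (default learning rate $10^{-3}$, batch
16) with inverted dropout (default 0.5) on the word representation,
early stopping on validation performance (patience 5), and optional
**exponential moving average** of all weights
($\,s' = \beta s + (1-\beta)\,w$, $\beta = 0.999$): with `use_ema` the
shadow copy, not the raw weights, is used for validation and
prediction.  The per-epoch validation quantity is the global
de-identification F1 described below.  Defaults (word dimension 100,
character dimension 25, hidden sizes 100/25) follow the conventions of
the BiLSTM-CRF named-entity literature this family of models descends
from.  Word embeddings are randomly initialized (uniform ±0.05);
pretrained vectors in the common text format can be loaded, but nothing
in the package requires a download.

With a fixed seed and single-threaded execution, training is
bit-reproducible: all parameter initialization and shuffling is driven
by the R RNG, and the only other randomness (dropout masks) is driven by
a per-batch seed drawn from the same stream.

## Gazetteers and surrogate generation

Surrogates are sampled from weighted gazetteers: name lists weighted by
frequency, municipality lists by population, so frequent surrogates
appear with realistic relative frequency.  Sampling uses
cumulative-weight inversion over the entries left after exclusion, and
*always excludes the original surface*: a surrogate never equals the
string it replaces.  If exclusion exhausts a gazetteer, a synthesized
fallback (syllable-built name or grammar-built code) is used instead,
still different from the original.

Category rules: `NAME` mentions are rebuilt token by token so a
two-token name gets a two-token surrogate; `FECHA` surfaces are
regenerated as random valid dates in the same format family as the
original (numeric with `/` or `-`, or written Spanish); `NUM` surfaces
are regenerated under the original's character-class mask (digit for
digit, letter for letter, separators untouched) so downstream parsers
keep working; `CAB` is returned unchanged.  Replacement proceeds right
to left so character offsets stay valid, all inter-span text is
preserved byte for byte, and the audit trail records only categories and
lengths — storing original surfaces would defeat the purpose.

The bundled gazetteers are deliberately miniature synthetic samples
(~190 names, 50 municipalities with approximate populations, 40
institutions, 50 addresses): the national registries they stand in for
are external resources, and the package must be fully self-contained.
Cross-document consistency (same patient, same pseudonym) and
constant-offset date shifting are out of scope.

## The synthetic corpus generator

Real corpora of this kind are access-restricted, so the package ships a
generator that emulates their *structure*, which is what the tagger is
sensitive to.  Three profiles are produced:

* `headered` — Spanish section headers followed by free-text findings,
  entities mostly embedded in sentences (the majority profile);
* `dept7` — Valencian-language headers with the metadata value detached
  onto the next line, and a high rate of *orphan* entities: a name or
  date alone on a line with no context (the held-out department);
* `meddocan` — every sensitive value directly after its metadata
  descriptor, a rigid structure useful for probing structure
  overfitting.

Clinical filler comes from a bundled bank of ~50 neutral radiology
phrases; content realism is not the target — structure and entity
placement are.  Entity categories are chosen by a corpus-level greedy
balancer that always fills the most-deficient category, so
annotated-token shares converge to a configurable target; the built-in
targets mirror the annotation distribution of the reference radiology
corpus, and `dept7` documents follow the held-out department's own
distribution (systematically more addresses, places and institutions,
far fewer headers).  Other defaults chosen once for realism: overall
entity density 15% of tokens (annotated-token density of the source
corpora is not published; 15% is typical of metadata-rich short
reports); ~32 annotated tokens per document; ambiguous anatomical words
that double as surnames ("cabeza") inserted in their harmless sense at
rate 0.1; and 5% of `NAME` instances are *unlisted* synthesized names
absent from every gazetteer, emulating the long tail that a
frequency-truncated name registry misses — it is precisely these names
that keep recall below 1 and make the character channel matter.

What passing tests on this generator do **not** show: performance on
real clinical prose (typos, abbreviations, genuine ambiguity), on
languages other than Spanish/Valencian, or at realistic vocabulary
sizes.  The generator validates the machinery, not the clinical
deployment.

## Evaluation

Evaluation is token-level, the convention in the de-identification
literature.  Per category, TP/FP/FN are counted over tokens with the B/I
prefix ignored.  The headline **global de-identification metric** is
computed on the binary distinction *identifying vs not*: a token is
identifying if its category is one of the six sensitive ones (`CAB` and
`O` are not), and a gold `NAME` token predicted `FECHA` is a binary true
positive — it still gets substituted — although it is a category FN plus
FP.  Counts are pooled over documents (micro-averaging); precision,
recall and F1 follow the standard formulas with the convention that a
zero denominator yields 0 and a `degenerate` flag.  A strict span-level
mode (exact boundaries and category) is available as a clearly-labelled
secondary option.  Recall is the metric that matters most here: a miss
is a leak.

## Numerical and design notes

* CRF computations are done in log space throughout; the CRF primitives
  are unit-tested against exhaustive path enumeration on small
  instances, and encoder gradients were verified against central finite
  differences for all three architectures.
* The transition matrix is `(K+2) x (K+2)` with START as origin-only row
  and STOP as destination-only column; the unused entries are never
  read.
* Empty lines produce no training sequences; empty documents predict
  empty span sets; prediction is pure.
* Checkpoints are plain text (config, vocabularies, full-precision
  parameter dumps), so models survive environments where binary
  serialization is unwelcome.
* Test-suite problem sizes were chosen to exercise every component at
  desk scale: CRF oracle instances up to length 6 with 5 tags,
  round-trip corpora of 500 random documents, 10,000-draw sampling
  checks, a 500-document generator-distribution check, and one reduced
  end-to-end run (250 documents, 86% `headered` / 14% `dept7`, a
  50-dimensional `lstm-lstm-crf` with EMA, at most 10 epochs) in which
  the tagger must reach at least 0.90 global de-identification recall
  on the validation split, with the `dept7`-only test split expected to
  score below validation — the structure-sensitivity effect.

## Known limitations

The generator's phrase bank is small and its Valencian is limited to
header labels.  The taggers are plain BiLSTM-CRFs: no transformer or
subword models, no GPU path.  Re-identification risk of the surrogate
strategy is not formally quantified here; a final human check of
de-identified text remains necessary before release, as any residual
miss — however well hidden among surrogates — is still a miss.
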