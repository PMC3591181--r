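---
title: "Recognizing nanotoxicology entities with a linear-chain CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing nanotoxicology entities with a linear-chain CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoner)
```

## The task

Nanotoxicology papers report which nanomaterials, administered by which
route, cause which toxic effects in which targets. `nanoner` treats this
as sentence-level named entity recognition over four categories:

* **NANO** — nanoparticles, nanomaterials, nanodevices ("zinc oxide
  nanoparticles", "C60");
* **EXPO** — routes of exposure ("inhalation", "intratracheal
  instillation");
* **TOXIC** — toxic effects ("apoptosis", "oxidative stress");
* **TARGET** — targets of those effects ("lung", "alveolar macrophages",
  "rats").

Annotated corpora for this domain are tiny (a few hundred sentences) and
typically not redistributable, which shaped two design commitments: a
model family known to work with small training sets (a linear-chain
conditional random field with sparse binary features and a Gaussian
prior), and a first-class synthetic corpus generator so that the entire
pipeline — format, features, training, decoding, metrics — is exercisable
and testable offline.

## Corpus format and tokenization

A corpus file is UTF-8 text, one sentence per line; each entity is
enclosed in inline tags:

```{r}
s <- parse_annotated(paste(
  "Intratracheal <EXPO>instillation</EXPO> of",
  "<NANO>titanium dioxide particles</NANO> and",
  "<NANO>carbon nanoparticles</NANO> caused <TOXIC>inflammation</TOXIC>",
  "in the <TARGET>lung</TARGET> of <TARGET>rats</TARGET> ."))
s$entities
```

Parsing rejects unbalanced, unknown, nested and token-splitting tags with
an error naming the line and character offset; `serialize_annotated()` is
its exact inverse. Offsets are 0-based and half-open throughout, for both
characters and tokens.

The tokenizer is a single regular-expression pass: maximal runs of word
characters, single-character punctuation tokens (hyphenated words split,
the hyphen kept), and — first in the alternation — chemical formulas,
defined as letter runs immediately followed by digits, possibly repeated
(`TiO2`, `C60`, `Fe3O4`), kept whole. Scientific text breaks naive
tokenizers precisely on these forms, and the formula pattern is also one
of the orthographic features below. Concatenating token texts with the
original gaps always reconstructs the input, which is what makes the
inline-tag round trip exact.

## BIO encoding

Entity spans are encoded per token as IOB2: the first token of each
entity gets `B-<category>`, the rest `I-<category>`, everything else `O`
— 9 labels in the fixed order `O`, then B/I pairs for NANO, EXPO, TOXIC,
TARGET. IOB2 (rather than IOB1) was chosen because its inversion is
unambiguous. The decoder's output may be ill-formed; `bio_to_spans()`
repairs an orphan `I-X` by treating it as `B-X` (the most common
convention), so every non-`O` token ends up in exactly one span. The
repair is covered by tests, which lets training leave illegal transitions
such as `O → I-X` soft rather than hard-masked — a simpler, strictly
convex objective.

## Features

Each position receives a set of binary features, a closed inventory fixed
by the package for reproducibility:

* word identity, lowercased (`W=tio2`);
* word shape: uppercase → `X`, lowercase → `x`, digit → `0`, other kept,
  adjacent duplicates collapsed (`TiO2` → `XxX0`);
* character prefixes/suffixes of lengths 1–3 (configurable);
* orthographic predicates: `INITCAPS`, `ALLCAPS`, `CAPSMIX`, `HASDIGIT`,
  `ALLDIGITS`, `ALPHANUMERIC`, `HASDASH`, `PUNCTUATION`, `GREEKLETTER`
  (spelled-out names), `ROMANNUMERAL`, `CHEMFORMULA` (the tokenizer's
  formula pattern);
* the word/shape features of neighbors at offsets ±1…±window, prefixed
  with the signed offset (`W@-1=…`); window defaults to 1;
* a constant bias.

```{r}
extract_features(tokenize("TiO2 induced apoptosis ."), 1)
```

Defaults (window 1, affixes 1–3) are small, standard and fast; all
features are presence indicators, no real-valued features. Extraction is
deterministic and local: features at position *i* depend only on tokens
within the window, which tests verify directly.

## The CRF

With feature sets $x_1 \dots x_T$ and tags $y_1 \dots y_T$,

$$\mathrm{score}(y \mid x) = \sum_t \sum_{f \in x_t} w_{f,y_t}
  \;+\; \sum_{t>1} A_{y_{t-1},y_t}, \qquad
  P(y \mid x) = \frac{e^{\mathrm{score}(y|x)}}{Z(x)}$$

where $A$ is a 9×9 transition matrix (label pairs only, not
feature-conjoined — the classic linear-chain formulation, which keeps the
parameter count desk-scale) and $Z(x)$ sums over all $9^T$ taggings.
Training minimizes

$$\mathcal{L}(w) = -\sum_s \left[\mathrm{score}(y^{(s)} \mid x^{(s)})
  - \log Z(x^{(s)})\right] + \frac{\lVert w\rVert^2}{2\sigma^2}$$

whose gradient is (expected − observed) feature counts plus $w/\sigma^2$,
with expectations from forward–backward marginals.

Numerical and algorithmic choices:

* all dynamic programs (forward, backward, Viterbi) run in log space with
  a guarded log-sum-exp — long sentences underflow otherwise — in
  compiled code (`src/crf_dp.cpp`), with the sparse feature algebra done
  through `Matrix`;
* the optimizer is `stats::optim` L-BFGS-B with the analytic gradient;
  defaults $\sigma = 10$, relative-objective tolerance $10^{-6}$, at most
  200 iterations, zero-weight start. The objective is smooth and convex,
  so the start point affects only the path, not the optimum — a property
  the test suite checks by random restarts agreeing to $10^{-4}$;
* Viterbi ties break toward the lowest label index at every backtrace
  step, so the all-zero model deterministically decodes `O` everywhere;
* a non-finite objective aborts training with an error reporting the
  evaluation count;
* models persist as a single self-describing JSON container (format
  `nanoner-crf`, version 1: labels, feature index, weights, prior,
  feature configuration); the feature index is stable across save/load.

Correctness is established against independent oracles rather than
against a reference implementation: exhaustive enumeration of all $9^T$
taggings ($T \le 4$) must reproduce the partition function and marginals
to $10^{-8}$ and the Viterbi score to floating-point accuracy, and the
analytic gradient must match central finite differences to $10^{-5}$
relative error.

## Evaluation

Per category, with `correct`/`returned`/`in_gold` counts:

* **entity level** — an entity is correct only if category *and* token
  boundaries match exactly; EP = correct/returned, ER = correct/gold,
  EF = harmonic mean;
* **token level** — tokens inside category entities are compared
  individually, crediting partial matches. Predicting "nickel
  nanoparticles" for the gold entity "metallic nickel nanoparticles"
  scores 0 at entity level but 2-of-3 token recall at perfect token
  precision. Tokens outside predicted entities are never counted as
  returned.

0/0 ratios are taken as 0 with a warning. `cross_validate()` shuffles
sentences with a seed, makes `k` folds whose sizes differ by at most one
(no stratification), trains on each complement, predicts the held-out
fold, and **pools the counts across folds before computing metrics**
(micro-averaging). Whether to micro- or macro-average over folds is a
genuinely open choice for this design; micro-averaging was chosen because
it weighs every entity equally and is stable for the rare EXPO category
in small folds, and it is stated here prominently because the two can
differ noticeably at this corpus scale.

## The dictionary + TF/IDF baseline

The baseline emulates what a practitioner would do with term lists alone.
Candidate terms are all tokens (minus a fixed, bundled English stop-word
list) plus n-grams of sizes 2–6. Each candidate is scored tf·ln(N/df),
where a "document" is one corpus sentence — the corpus unit here is the
sentence, so this is the natural reading — tf is the count in the
document with the most occurrences, and no smoothing is applied.
Candidates scoring below 0.1 are discarded; survivors are matched
*exactly* (lowercased, surrounding punctuation stripped, whitespace
collapsed; no stemming, case-insensitive) against a NANO lexicon and a
TARGET lexicon, longest match first, then leftmost; a term in both
lexicons counts as NANO. The baseline never emits EXPO or TOXIC: no
controlled vocabulary covers those categories.

The bundled lexicons (`npo_synthetic_lexicon.txt`,
`fma_synthetic_lexicon.txt`) are *synthetic stand-ins* — ~50 nanoparticle
names and ~50 anatomy/organism terms written for this package — not
excerpts of any released ontology. Because they largely cover the
synthetic generator's vocabulary, the baseline's recall on generated
corpora is near 1; on real literature, ontology coverage is far poorer
and recall is the baseline's known weakness. The synthetic run
demonstrates the machinery (scoring, thresholding, matching, overlap
resolution), not realistic baseline performance.

## The synthetic corpus generator

The generator is the package's study-conditions module: it emits corpora
with the statistical shape of a 300-sentence nanotoxicology gold
standard —

* 300 sentences by default, ~10% of them entity-free distractors (fixed;
  forces the model to learn `O`);
* entity categories drawn with weights proportional to 426 : 144 : 485 :
  385 (NANO : EXPO : TOXIC : TARGET), i.e. ≈ (0.296, 0.100, 0.337,
  0.267), about 4.8 entities per annotated sentence;
* entity lengths drawn as 1 + Poisson(mean − 1), truncated to the lengths
  available in the lexicon, with per-category means (717/426, 186/144,
  637/485, 705/385) ≈ (1.68, 1.29, 1.31, 1.83) tokens — fractional means
  realized with integer lengths;
* surfaces filled from bundled per-category term lists of realistic
  nanotoxicology vocabulary (40–80 terms each, including chemical
  formulas and multiword names, so the tokenizer and orthographic
  features are genuinely exercised), **disjoint across categories by
  construction**;
* ten sentence frames with category-agnostic entity slots and six
  distractor frames; everything deterministic given the seed;
* `label_noise` optionally drops a fraction of annotations (text kept) to
  simulate imperfect gold annotation; `perturb_annotations()` separately
  fabricates "system output" at analytically known precision/recall for
  metric calibration (drop-only at rate *q*: EP = 1 exactly, E[ER] =
  1 − *q*).

What passing tests on this corpus show — and what they do not. Category
lexicons are disjoint and context frames are regular, so a correct CRF
implementation should recover entities almost perfectly at the default
scale (the acceptance band is entity F ≥ 0.85 per category under 10-fold
cross-validation; observed values exceed 0.98). This validates the
pipeline end to end: features must fire, training must optimize the right
objective, decoding and span reconstruction must be exact, metrics must
pool correctly. It does **not** estimate real-literature performance:
real text has ambiguous category membership, unseen surface forms,
nonlocal cues and annotation disagreement, none of which the template
grammar emulates.

## Problem sizes and runtime

Defaults were chosen so a full check runs on a laptop core: the test
suite uses corpora of 10–80 sentences for properties, 200 enumeration
oracles at $T \le 4$, 20 finite-difference instances, and one full
300-sentence 10-fold cross-validation (~1.5 min); `scripts/acceptance.R`
repeats the 300-sentence CV and the baseline run from a single `--seed`.

## Known limitations

* Transitions are not feature-conjoined; rich contextual interactions
  must come through the window features.
* The feature inventory is a fixed approximation to the classic
  biomedical-NER defaults; exact replication of any particular historical
  tool's feature space is not claimed.
* The baseline's TF/IDF "document" is the sentence; with abstract-level
  documents the idf scale, and hence the 0.1 threshold's bite, would
  differ.
* The generator's linguistic realism stops at templates by design;
  distributional shape, not fluency, is what it controls.
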