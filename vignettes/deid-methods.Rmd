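---
title: "De-identifying bilingual clinical notes: rules, pseudo-labels, and a reference tagger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying bilingual clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical notes written in Korean hospitals mix Korean and English freely and
carry protected health information (PHI): dates of imaging and procedures,
names of medical staff and patients, referring hospitals, regions, telephone
and patient numbers, and demographic fragments such as age, sex and
nationality. Before such notes can be shared for research the PHI must be
found and replaced. `deidr` implements a two-stage strategy for this setting:

1. a **rule engine** of 51 regular expressions over six PHI categories
   (`DAT`, `PER`, `ORG`, `LOC`, `NUM`, `ETC`), built for radiology-style
   bilingual notes; and
2. a **semi-supervised stage** that uses the rules as a weak labeler to
   pseudo-label a large corpus in BIO form, optionally corrects the labels
   at the corpus level, and trains a sequence tagger on them, so that the
   learned model can recall PHI variants the rules never covered.

Because real hospital notes cannot be shipped, the package also contains a
seeded **synthetic note generator** that emulates the structural properties
of the source setting; every empirical claim the test suite makes is
computed on that generator's output at desk scale.

## Text model and coordinates

All text is NFC-normalized at ingestion (`normalize_text()`), so decomposed
Hangul jamo sequences and composed syllables have one canonical form before
any pattern runs. Spans are 0-based, half-open, and counted in Unicode code
points of the normalized text. Code points (rather than bytes or grapheme
clusters) give stable slicing for mixed Hangul/Latin text; adjacent
half-open spans never overlap by construction.

## The rule engine

Rules live in a versioned YAML file (`default_rules_path()`), one record per
rule: an ICU regular expression, the category, the index of the capture
group that is the PHI portion, and a priority. Family sizes are a structural
invariant checked at compile time: 18 DAT, 8 PER-staff, 3 PER-patient,
13 ORG, 1 LOC, 4 NUM, 4 ETC — 51 in total. The printed per-category
decomposition of the source rule set does not sum consistently with its
printed total, so the DATE family here carries the balance (18) to preserve
the total of 51, which is the externally checkable number.

Design points that matter in practice:

* **Identifier words are context, not PHI.** 환자이름, 판독의, `Tel.`,
  전화번호 and similar anchors are matched but never masked; only the
  capture group becomes the annotation. Masked output therefore reads
  `환자이름: [PER]`.
* **Dates require a plausible year.** Numeric dash/dot patterns insist on a
  4-digit `19xx/20xx` component, so a measurement range like `1.2-1.7`
  is never a date. The cost is that genuinely abbreviated dates without a
  year marker are missed; that trade-off is deliberate and documented.
* **Numbers require an anchor.** A bare 4-digit number cannot be told apart
  from a year, so NUM fires only next to 전화번호/`Tel.`/`T.`/환자번호/내선
  or on members of a site-supplied extension vocabulary. That vocabulary
  ships empty: the real extension list is institution-private, and an empty
  vocabulary compiles to a never-matching pattern so the rule count is
  stable across sites.
* **Known failure modes are reproduced, not patched.** The 확인함 rule
  over-triggers on 상기확인함 (tagging 상기 as a name); the 고려대/중앙대
  alias families false-positive on 고려 ("considering") and 중앙값
  ("median"); `CMC` is tagged ORG regardless of whether it means a hospital
  or a joint. These are properties of the rule-based approach the
  downstream correction workflow exists to fix; unit tests assert they
  fire exactly.

**Overlap resolution** is a total order, so the result is unique: longer
span wins; at equal length ORG > LOC (a city adjoined to a known hospital
is an organization), then DAT > PER > NUM > ETC; then leftmost span, lower
rule priority, rule id. `apply_rules()` is tested against an independent
run-every-rule-then-resolve oracle with a naive quadratic resolver.

## Tokenization and BIO projection

Tokens are maximal runs split at whitespace and then at boundaries between
three script classes — Hangul, Latin/digit, and everything else — so
`2019-02-04 촬영` tokenizes as `2019 - 02 - 04 촬영`. The convention is a
package choice (the source conventions are unstated); anyone comparing
token counts against other tools should account for it. Concatenating
tokens with the inter-token text reconstructs the note exactly, a tested
round-trip invariant.

`project_to_bio()` maps non-overlapping character spans to BIO2 tags: a
token inherits category X if any of its characters overlaps an X span
(partial overlap inherits, so masking can never leak a fragment of a name
or date), the first covered token takes `B-X`, the rest `I-X`, and staff
and patient subcategories both collapse to `PER`. `build_corpus()` keeps
only notes with at least one rule match (tiers count PHI-bearing notes),
samples uniformly without replacement under a seed, and tallies PHI words
as `B-` runs.

The correction workflow (`derive_corrections()` / `apply_corrections()`)
models the manually corrected tier: flagged false-positive spans revert
their tokens to `O`, a note whose last annotation disappears is dropped,
and gold-annotated notes from other departments may be appended.

## The reference tagger

The learned stage is a feature-based **averaged perceptron** with greedy
left-to-right decoding and a previous-tag transition weight, implemented in
C++ for speed. Features at each position are deterministic and local:
lowercased surfaces and shapes (digits→`9`, Hangul→`H`, Latin→`a`) of the
token and its ±2 neighbors, the script class, identifier-word flags in the
±1 window, and sentence-boundary flags. Decoding is followed by a BIO
repair step (`enforce_bio_validity()`, orphan `I-X` → `B-X`), so predictions
are always BIO-valid.

This architecture was chosen because the mechanism under study is
*pseudo-label-driven learning* — how the data volume and label corrections
change a learned tagger — and a desk-scale discriminative tagger exhibits
that mechanism without pretrained weights or downloads. It does not stand
in for a transformer's pretrained knowledge. External pretrained taggers
can be plugged in through `tagger_adapter()`, which fixes the contract
(`train(corpus, epochs, seed)`, `predict(model, tokens)`) while leaving
hyperparameters to the adapter.

Defaults: 5 epochs, seeded shuffle order, ties in decoding break toward
`O`. Training is bit-reproducible given the corpus and seed. Models
serialize to a flat JSON weight table with zero rows pruned.

## Evaluation conventions

Scoring is **token-level with B/I collapsed to the category**, matching the
source convention of annotating and scoring at the token level; span-exact
scoring would deflate the numbers. Precision is TP/(TP+FP) and recall
TP/(TP+FN) with 0/0 defined as 0; F1 is the harmonic mean. When gold and
prediction disagree on two non-O categories, the token counts as an FP for
the predicted category *and* an FN for the gold category — the source
convention is unstated, and this double-count choice keeps per-category
marginals consistent. Internal values are full precision; printed tables
round half-up to two decimals (`round_half_up()`), which is how a gold
date row of 537 tokens with 6 misses and 1 spurious mask renders as
recall 0.99.

## The synthetic generator

`generate_corpus()` assembles notes from rule-inert clinical filler
sentences (radiology and "other department" flavors) and injects PHI
snippets with exact gold spans. The generator, not the rule engine, is the
ground-truth authority; tests then ask how well the rules and the tagger
recover that truth. Key defaults, chosen once to mirror the source data's
structure:

* `phi_note_fraction = 0.10` — about a tenth of notes carry PHI; training
  pools are generated with the fraction at 1 because training tiers count
  PHI-bearing notes only.
* `category_mix` proportional to the observed PHI counts of the source
  rule-development corpus (DAT 1045, PER-staff 56, PER-patient 50, ORG 47,
  LOC 7, NUM 3, ETC 5) — dates dominate at ~86% of instances.
* `out_of_scope_fraction` — fraction of PHI instances rendered in notation
  families no rule covers (day-month-year dashes, space-separated dates,
  unanchored staff names such as 담당의 NAME, unlisted clinic names,
  unanchored numbers). With the fraction at 0 the rule engine is provably
  perfect on the generator's output (precision = recall = 1.00), which is
  a generator invariant, not an empirical achievement; with it above 0 the
  rules have a recall ceiling the tagger can beat.
* `homonym_trap_rate = 0.05` in the benchmark — non-PHI homonym sentences
  (고려해 볼 때, 중앙값, CMC joint, 상기확인함) that the rules are known
  to false-positive on, at a rate giving a few-percent false-positive
  share, comparable to the source workflow's correction volume. The
  correction experiment raises the rate to 0.2 so the precision effect is
  measured under a clearly noisy labeler.
* All names and institutions are fictitious (240 combinatorial Korean
  names, invented hospital names) plus the alias families needed to
  exercise the documented homonyms.

What the generator does **not** emulate: real physician prose, typos
(the rules are typo-intolerant by design and that limitation is out of
scope), sub-note structure, and the long tail of institution-specific
notation. Passing tests therefore demonstrate the mechanics of the
pipeline and the directional claims, not clinical-grade performance on
real notes.

## Experiment design and problem sizes

The benchmark experiments are scaled to a tenth of the source tiers so the
whole suite runs on a laptop: training pools of 4,000 PHI-bearing notes,
tiers of 800/1,600/3,200, held-out sets of 400 notes, 5 seeds per
condition. Tier samples are **nested** per seed (one pool permutation,
tiers are its prefixes): each tier is still a uniform draw without
replacement, and the tier comparison becomes paired, which removes
sampling noise from the data-size trend.

`run_tier_experiment()` reproduces the two directional claims of the
semi-supervised design on this benchmark:

* the 3,200-note tagger's total recall exceeds the rule engine's on the
  same held-out gold (the generalization gap; driven mostly by
  out-of-scope date notations, which the tagger recovers from digit shapes
  and recurring year surfaces);
* `run_correction_experiment()` shows that deleting flagged false
  positives from the training corpus strictly raises held-out precision
  (≈0.974 → ≈0.9996 in the shipped configuration).

One directional claim does **not** reproduce under this architecture: mean
held-out micro-F1 is not monotone over 800 → 1,600 → 3,200 (it drifts down
by ~0.004). The averaged perceptron already saturates the in-scope
patterns at 800 notes, so additional pseudo-labeled data mainly entrenches
the labeler's out-of-scope misses as `O`, shrinking the generalization
that smaller, less-converged models display. This is a real property of
pseudo-label training — a learner converging to its weak labeler — and it
is reported rather than tuned away; a pretrained transformer, which starts
far from convergence and brings external lexical knowledge, is the setting
in which the data-size trend is expected to hold. For the same reason the
tagger does not recall staff names in unanchored contexts (the anchor
features absorb the PER evidence), while it does recall novel date
notations.

## Numerical and degenerate-input choices

* Decoding ties break to the lowest tag index, which is `O`; an untrained
  weight table therefore predicts all `O` rather than arbitrary tags.
* 0/0 metrics are 0, never NaN; empty corpora evaluate to all-zero reports.
* `build_corpus()` fails loudly when asked for more PHI-bearing notes than
  exist, reporting the available count.
* Masking validates non-overlap and bounds before editing; overlapping
  input spans are a contract violation, not silently merged.
* Seeds: every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state; derived stage seeds stay well below
  2^31.

## Known limitations

* The rule set is a faithful radiology-flavored reconstruction seeded from
  published examples; the full source vocabulary (hospitals, the exact
  REGION pattern, the private extension list) is not recoverable, so
  site-specific deployment requires extending the YAML config.
* Token-level scoring credits partial masks of multi-token entities;
  span-exact scoring would be stricter and is deliberately out of scope.
* The reference tagger's contextual generalization is bounded by its
  features; it demonstrates the pipeline's mechanics, not
  state-of-the-art NER.
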