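# deidr — de-identification of bilingual clinical notes

`deidr` detects and masks protected health information (PHI) in clinical
notes that mix Korean and English, the writing style typical of Korean
hospital radiology reports. It is aimed at clinical NLP engineers and
health-data stewards who need to share narrative notes for research and
cannot: dates, names of medical staff and patients, hospitals, regions,
phone/patient numbers, and age/sex/nationality fragments must first be
found and replaced.

The package implements a two-stage design:

1. **Rule engine.** 51 regular-expression rules over six PHI categories
   — `DAT`, `PER` (staff/patient), `ORG`, `LOC`, `NUM`, `ETC` — with
   Unicode-aware matching on NFC-normalized text, identifier words
   (환자이름, 판독의, `Tel.`, …) used as unmasked context anchors, and a
   deterministic overlap-resolution order (longest span, then
   ORG > LOC > DAT > PER > NUM > ETC). Matched spans are replaced by
   category placeholders (`[DAT]`, `[PER]`, …).
2. **Semi-supervised stage.** The rules pseudo-label a large corpus into
   token-level BIO tags (`B-X`/`I-X`/`O`); a corpus-level correction
   workflow removes flagged false positives and can add gold notes from
   other departments; a feature-based averaged-perceptron sequence tagger
   is trained on the result and evaluated token-by-token (B/I collapsed to
   category) with per-category and micro precision P = TP/(TP+FP), recall
   R = TP/(TP+FN), and F1 = 2PR/(P+R).

A seeded synthetic note generator with exact gold annotations makes the
entire pipeline testable without access to any restricted hospital data —
all names and institutions in generated text are fictitious.

## Worked example

```r
library(deidr)

ruleset <- compile_ruleset()          # the shipped 51-rule set
note <- clinical_note(
  "rad-0001",
  "Brain MRI. 2019-02-04 시행한 외부 영상과 비교. 고려대병원 에서 전원됨. 특이 소견 없음. 판독의 홍길동")

matches <- apply_rules(note, ruleset)
matches
#>            rule_id category subcategory start end priority    surface
#> 1     dat_ymd_dash      DAT        <NA>    11  21        1 2019-02-04
#> 2        org_vocab      ORG        <NA>    37  42        1 고려대병원
#> 3 per_staff_pandok      PER       staff    65  68        6     홍길동

mask_text(note, matches)
#> [1] "Brain MRI. [DAT] 시행한 외부 영상과 비교. [ORG] 에서 전원됨. 특이 소견 없음. 판독의 [PER]"
```

Each row is one resolved PHI span: the exam date, a hospital alias from
the vocabulary, and the radiologist's name captured after the identifier
word 판독의 (which itself survives masking, as identifiers are context,
not PHI). Offsets are 0-based half-open code-point positions.

Scoring the rule engine against gold annotations on a fully in-scope
synthetic corpus (1,000 notes, seed 1) reproduces the generator invariant
that everything the rules were built for is found exactly:

```r
notes  <- generate_corpus(synth_config(seed = 1, n_notes = 1000))
report <- evaluate_corpus(gold_tag_notes(notes), rule_tag_notes(notes, ruleset))
report
#>  category  tp fp fn precision recall   f1
#>       DAT 711  0  0      1.00   1.00 1.00
#>       PER  14  0  0      1.00   1.00 1.00
#>       ORG   8  0  0      1.00   1.00 1.00
#>       LOC   0  0  0      0.00   0.00 0.00
#>       NUM   0  0  0      0.00   0.00 0.00
#>       ETC   2  0  0      1.00   1.00 1.00
#>     Total 735  0  0      1.00   1.00 1.00
```

(735 gold PHI tokens, dominated by dates as in the source distribution;
LOC and NUM are too rare to appear in this draw, and 0/0 metrics render
as 0 by convention.)

The semi-supervised experiments are one call each:
`run_tier_experiment()` trains the tagger on nested 800/1,600/3,200-note
pseudo-labeled tiers over 5 seeds and compares it with the rule engine on
held-out gold; `run_correction_experiment()` measures the precision gain
from deleting flagged false positives before training. The end-to-end
pipeline, including masking and reports, is `run_pipeline()`; a thin
command-line front end with `synth`/`mask`/`pseudo-label`/`train`/
`predict`/`eval`/`run` subcommands ships in `inst/cli/deid.R`.

See the methods vignette (`vignettes/deid-methods.Rmd`) for the model,
conventions, generator design, and known limitations.

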