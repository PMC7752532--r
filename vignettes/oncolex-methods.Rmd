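---
title: "Methods: consumer-term cancer ontology and post-level frequency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consumer-term cancer ontology and post-level frequency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolex)
```

## The problem

Health consumers discuss cancer on blogs and online communities in lay
vocabulary. Estimating information needs and emotions from such text needs
three things: a terminology that covers consumer expressions, an annotator
that does not fire on false-positive contexts, and a counting scheme whose
unit is the post, not the token. This vignette describes the model behind
each stage, the parameters that matter, and the design decisions we made
where more than one reasonable choice existed.

## Ontology model

Concepts form a single-parent forest. Roots are the nine superclasses
(*cancer type, prevention, diagnosis, treatment, prognosis, risk factor,
symptom, dealing with cancer, emotion*); depth is limited to 4 parent hops
(the hierarchy in practice uses 3–4 levels). We chose a tree rather than a
DAG deliberately: the frequency analysis rolls every concept up to a
*unique* superclass, which multiple parentage would break.

The terminology maps surface forms to concepts with a term type
(preferred/synonym/abbreviation/heteronym). The normalization key is
Unicode NFC + lowercase + whitespace collapse; case folding is a no-op for
Hangul and romanized-Korean forms, but consumer posts mix scripts, so the
Latin part matters. A normalized form mapping to two concepts is reported
by `validate_ontology()` as the warning `AMBIGUOUS_TERM` rather than an
error — the ontology is still usable for everything except matching — but
`match_terms()` refuses to match such a form, because the only
disambiguation mechanism in this design is the stop-phrase list, which
offers no tie-break between two genuine concepts.

The packaged skeleton (`skeleton_ontology()`) encodes only publicly
documented structure: the 9 superclasses, the risk-factor subclass families
(health condition, demographic, lifestyle, environmental, hereditary, with
end nodes such as gender, age, dietary, obesity, tobacco, chemical,
infectious agent), the symptom families (digestive, psychological,
neurological, metabolic, sexual and reproductive), dealing-with-cancer
(daily life with diet and exercise; leisure with sex life, travel,
driving; support group), treatment (unspecified treatment, surgery,
chemotherapy), prognosis (recurrence, cure), eleven cancer types, and the
nine emotion classes. The original 213-class, 4061-synonym terminology was
never published; where tests need a bigger vocabulary,
`generate_ontology_fixture()` extends the skeleton with synthetic classes
and synonyms. One open point: published results report the superclass
*prognosis* while some figure-level analyses treat *recurrence* and *cure*
separately; we model recurrence and cure as subclasses of prognosis, so
superclass tables show prognosis and class-level tables show both
subclasses — both readings are available.

## Annotation pipeline

The stage order is fixed and matters:

normalize → de-identify → ad check → stop-phrase masking → term matching.

* **De-identification** is pattern-based (phones, e-mails, URLs with
  embedded account names, @handles → fixed placeholders). Personal names
  would need NER and are a documented limitation. The operation is
  idempotent, so the pipeline may safely re-apply it.
* **Advertising keywords remove the whole post**, before any matching: an
  ad mentioning genuine cancer terms still contributes nothing. This
  asymmetry with stop phrases is intentional — an ad is not consumer
  discourse at all, while a stop phrase merely neutralizes one keyword
  occurrence.
* **Stop phrases mask occurrences in place** (same-length runs of a mask
  character), rather than discarding the post: "agseong virus" (computer
  virus) contains "agseong" (malignant), and the post around it may be a
  perfectly good non-cancer post. In-place masking preserves all offsets.
* **Matching is normalized substring search**, not token-boundary search.
  Korean is agglutinative — "jaegeomsa" contains the abbreviation
  "jaegeom" — and consumer abbreviations imply subword hits. The cost is
  overmatching on very short forms (e.g. "am" inside unrelated words); the
  stop-phrase list is the instrument for suppressing the frequent
  false-positive contexts.

Both masking and matching resolve overlapping candidate spans with one
shared rule: **longest first, then leftmost**, greedily accepting
non-overlapping spans. The rule is deterministic and is enforced
identically in both stages so that masking can never free a partial match
the matcher would treat differently. Two candidates can never tie exactly
(equal start and length implies equal string), so no further tie-break is
needed. A subtle consequence we verified by brute force: all occurrences of
a form, including self-overlapping ones ("aba" twice in "ababa"), must
enter candidate selection — a plain left-to-right fixed search that resumes
after each hit finds too few.

## Frequency analysis

Counting is binary per post: however many times a concept's terms occur,
the post contributes at most 1 to that concept. A post counts toward
superclass *S* iff any of its concepts lies in *S*'s subtree — including a
direct mention of *S*'s own surface forms (the "unspecified treatment"
pattern shows such superclass-level vocabulary exists). Percentages are
`100 * n / N`, rounded **half-up** to one decimal to match the convention
of the published tables (base R's banker's rounding would turn 42.47 into
42.5 here too, but disagrees on exact ties); raw fractions are retained in
every output table. Where a published text reports the same ratio as both
42.5% and 42.47%, both are recoverable from our `pct` and `pct_raw`
columns.

Strata are per-cancer-type sub-corpora; the denominator is the stratum's
own post count, and a post mentioning two cancer types enters both strata
(nothing in the counting model forces single-type assignment, and
within-type relative frequencies are the quantity of interest). The
stratum list is explicit configuration — published figure sets are
ambiguous about, e.g., whether thyroid cancer is included — defaulting to
the top 10 types by post count. Ranking ties are broken lexicographically
by concept id (C-locale radix order): ties are unlikely at corpus scale but
the rule must be deterministic. The date window is a closed interval on
both ends, matching the usual reading of "between January 1, 2014 and
June 30, 2017".

The registry comparison table shipped in
`extdata/registry_stats_synthetic.csv` is a synthetic stand-in: it encodes
every publicly stated constraint of the Korean national cancer statistics
(stomach, colon, thyroid, lung as the top 4; seven types shared with the
social top 10; cervical cancer, leukemia and brain tumors absent), but it
is not the registry's own publication and the file name says so.

## Synthetic corpus generator

`generate_corpus()` emulates the *lexical* structure the annotator sees;
matching is lexical, so lexical structure is the only structure that
matters for testing. Per post, an independent random stream (seeded from
the corpus seed and the post index, so generation is reproducible and
order-independent) draws:

* platform and source type — defaults `naver` 0.550, `daum` 0.427,
  `tistory` 0.015, `egloos` 0.008 (the two major platforms carry 97.7%)
  and blog 0.587 / community 0.413, matching the reported corpus;
* a date uniform in 2014-01-01..2017-06-30;
* cancer types by independent Bernoulli draws — defaults head at colon
  0.064, breast 0.063, stomach 0.050, then plausibly decreasing values for
  the remaining seven types (only the top three rates are published; the
  rest are our fixed choices and only their order matters downstream);
* for each drawn type and superclass, whether to plant a concept of that
  superclass — default rates are the published corpus-wide superclass
  frequencies (risk factor 0.425 … prognosis 0.094) used as per-type
  conditional rates, the only published calibration available. For posts
  mentioning several types the union of draws slightly inflates the
  marginal rate; type probabilities are small, so the effect is under a
  percentage point;
* 5% advertising posts (an ad keyword is planted; type draws still
  happen, so ads can contain genuine cancer terms) and, among posts with
  no cancer mention, 5% stop-phrase confusables.

Planted concepts appear as their preferred labels; filler words are token
soup built from a character set disjoint from every terminology character
pattern (each filler word starts and ends with `q` and uses only
`q z v x w i u o`), with at least one filler word between planted phrases.
These two constraints make accidental matches impossible, which is what
lets the ground truth be *exact*: on any generated corpus the annotator
must achieve precision = recall = 1.0, and any deviation is a bug in the
pipeline, not noise in the fixture. What the generator deliberately does
not emulate: fluent Korean, morphology, discourse, emotion co-occurrence
beyond the rate table, or near-miss spellings. Passing tests therefore
demonstrate the pipeline's mechanics, not matcher robustness on real
Korean text.

## Numerical and degenerate-input choices

* `relative_frequency(n, 0)` is an error, not `NaN`; empty strata are
  reported via the `totals` attribute with no concept rows.
* Duplicate post ids abort corpus ingestion (the post is the unit of
  analysis; silent deduplication would corrupt every downstream count).
* An empty ontology file is a parse error; cycles and dangling parents are
  structural errors on load but merely *reported* by
  `validate_ontology()`, which must be able to describe broken inputs.
* Validation warnings (ambiguity, duplicate term rows) do not block
  loading; matching fails fast only when an ambiguous form actually occurs
  in a text.

## Problem sizes

The test suite works at small scale (trees ≤ 50 nodes against exhaustive
oracles, ≥ 1000 randomized 60-character texts against brute-force
scanners, corpora of 150–8000 posts for distributional checks) and one
50,000-post corpus for end-to-end rate recovery, where the planted colon
rate 0.064 must be recovered within `3·sqrt(q(1-q)/n)` ≈ 0.0033. These
sizes give binomial standard errors a few times smaller than the planted
effects while keeping the whole suite in minutes on one core.

## Limitations

* Substring matching overmatches very short consumer forms on real text;
  the stop-phrase inventory, not morphology, is the only guard.
* De-identification does not detect personal names.
* The skeleton terminology is a small, structurally faithful subset; all
  absolute counts on synthetic corpora are illustrative only.
* Frequencies are descriptive; the package deliberately offers no
  statistical testing of between-type differences and no time-series
  modeling.
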