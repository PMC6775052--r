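---
title: "Detecting obsessive-compulsive symptom mentions in clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting obsessive-compulsive symptom mentions in clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocsnlp)
library(dplyr)
```

## The problem

Obsessive-compulsive symptoms (OCS) — persistent intrusive, distressing
thoughts (obsessions) and repetitive goal-directed rituals (compulsions) —
are clinically important comorbidities in psychosis and bipolar disorder,
but they are recorded almost exclusively in free-text notes and letters,
and the words used to record them are not specific. "Obsessed" often means
a keen interest; "a compulsion to gamble" is about risk-taking; "his
mother has OCD" is about somebody else; "possible OCD" is not a definite
mention; and "Obsessive Compulsive Index (OCI): 12" is a questionnaire
header, not a clinical observation. A keyword count therefore badly
over-counts, and a useful detector has to reason about the local context
of every keyword occurrence.

`ocsnlp` implements a fully rules-based pipeline for this task. Rules, not
a learned model, are the point: each verdict carries an audit trail (which
inclusion rule fired, which exclusion triggers were found, in which
sentence), every step is deterministic and bit-reproducible, and the rule
pack is plain data that a clinician can read and edit.

## The pipeline

For each document:

1. **Pre-filter.** A document enters the pipeline only if it contains at
   least one term from three keyword sets: the five core OCS families
   (`obses*`, `compul*` — explicitly excluding the token "compulsory" —
   `ocd`/`o.c.d`, `hoard*`, `ritual*`), the Y-BOCS item vocabulary
   (cleaning, washing, checking, repeating, counting, ordering,
   rearranging), and patient-insight markers (distress, unwanted,
   repugnant, repulsive, egodystonic, intrusive, "unable to stop"). The
   pre-filter uses the same matcher as detection, so it is provably a
   superset of detection reach.
2. **Sentence split and windows.** Text is split on terminal punctuation
   with a protected-abbreviation list (a deterministic rule engine, not a
   statistical model, so runs are bit-identical everywhere). Every core
   keyword hit anchors an *instance*: the keyword sentence plus up to two
   sentences either side (at most five sentences, clipped at document
   edges). The instance is the unit of classification and evaluation.
3. **Inclusion routes.** An instance is a candidate positive if one of
   five routes holds in its window: the anchor is the OCD family (stated
   OCD features or a clinician diagnosis); the anchor is hoarding (counted
   regardless of further examples); at least two distinct keyword
   *families* co-occur (repeated tokens of one family do not
   self-corroborate); or a single family is corroborated by a Y-BOCS
   example or by an insight marker anywhere in the window.
4. **Exclusion engine.** Seven veto categories are evaluated exhaustively
   and any hit forces a negative verdict regardless of inclusion evidence:
   form/questionnaire fragments, negation, non-patient experiencers,
   hedges, self-diagnosis, romantic/weight modifiers and
   risk/self-harm modifiers.
5. **Roll-up.** A document is positive if any instance is; `n_positive`
   counts distinct (sentence-range, component) mentions so that several
   keyword tokens inside one mention are not double-counted.

## Scope decisions that were genuinely open

Several scoping choices had to be made where the coding rules are silent
or ambiguous; they are recorded here as the package's design position.

**Exclusion scopes.** Negation and experiencer terms must occur in the
*anchor sentence*: these are sentence-level grammatical phenomena, and
letting "denies" two sentences away veto a mention would over-exclude.
Form and self-diagnosis patterns apply to the *whole window*: both
describe the discourse around the mention (a questionnaire block, a
reported self-description) rather than the keyword's own clause. Hedges
are treated as sentence-scoped with one extension: a hedge elsewhere in
the window still vetoes if it falls within 5 tokens before the anchor
keyword, which reconciles "uncertainty about the instance" with "hedges
specifically refer to the keyword" while bounding over-exclusion.

**Modifier categories.** Romantic/weight and risk/self-harm words veto
only within 3 tokens of the anchor keyword. These rules are about words
that *modify* the keyword ("obsessed with his girlfriend", "compulsive
gambling"); mere co-occurrence in a five-sentence window ("gambling debts
discussed … later, compulsive checking") is not evidence against the
mention. No canonical term list exists for these two categories, so the
package ships small, documented seed lists that users should extend
(`excl_romantic_weight`, `excl_risk_selfharm` in the lexicon config).

**Standalone "none"/"nil".** Bare "none" anywhere in a sentence would
over-trigger ("none of the strategies helped"). The default requires
sentence-initial position or adjacency (at most 2 intervening tokens) to a
keyword; both token sets and the gap are configurable in
[detection_config()].

**Adjacency negations.** "no/not/than" negate only when they precede a
keyword with at most 2 intervening tokens ("no current obsessions",
"rather than an obsession"). These are collocational patterns, not
free-floating terms; an unbounded scope would make "not" a universal veto.

**Y-BOCS anchoring.** Y-BOCS vocabulary (checking, cleaning, order…) is
ubiquitous in clinical prose — "bloods checked", "in order to" would
anchor spurious instances. By default Y-BOCS terms therefore corroborate
a core keyword rather than anchoring instances of their own;
`detection_config(ybocs_anchors = TRUE)` restores the more liberal
behaviour for users who want the full reach implied by the coding rules.
Similarly, the literal token "ocs" is accepted as a variant of the OCD
family by default; remove it from the lexicon config to disable.

**Offsets.** All character offsets are 1-based and inclusive, computed on
the raw, un-normalised document text (the R convention, e.g. `substring`
and stringr). No normalisation ever happens before matching, so every
stored span can be checked against the source note.

## The synthetic corpus: what it does and does not show

The original development corpus is access-restricted health-record text,
so the package ships a seeded generator of labelled pseudo-clinical notes
instead. Each document mixes keyword-free, clinical-flavoured filler
sentences with template sentences instantiating every inclusion route and
every exclusion situation; template slots (subject, kin term, hedge,
Y-BOCS example) are filled from the same lexicon stock the detector uses,
so the gold labels are correct *by construction* under the coding rules.
Default mixing rates give roughly half positive and half negative
instances spread across all twelve situations, with 3–8 fillers per
document and a 25% chance of a second, well-separated template sentence
(multi-instance documents). Seeding is counter-based per document, so a
corpus regenerates byte-identically and earlier documents are unchanged
when more are added.

This design makes "closed-loop soundness" well-defined: on a corpus built
only from the shared templates, the detector must score precision =
recall = 1.0, and any failure is a rule-engine bug, not noise. The suite
asserts exactly that on 500 documents. Two things the generator
deliberately does **not** emulate: real note length/style variation, and
vocabulary outside the rule pack. Perfect closed-loop scores are
therefore a correctness statement about the engine, *not* a clinical
performance claim — on real notes, performance is bounded by the rule
pack's coverage, which is why the separate `adversarial_suite()` exists:
hand-labelled fixtures (lay usages, "compulsory", questionnaire
fragments, kin experiencers, hedges, self-diagnosis, romantic/weight and
risk modification, mixed documents) that do not reuse the templates.

A `perturb_corpus()` operation rewrites every gold-positive template
sentence to insert a negation, hedge or experiencer trigger (or swap in a
lay usage) and re-labels it negative, which turns the veto-precedence
contract — exclusions always beat inclusion evidence — into a testable
monotonicity property.

## Evaluation layer

Instance- and document-level confusion counts align predictions and gold
labels on shared keys (with a greedy, leftmost-first span-overlap aligner
for standoff gold without shared ids). Precision (positive predictive
value) and recall (sensitivity) carry exact binomial (Clopper–Pearson)
95% confidence intervals computed from the beta-quantile closed form;
metrics with zero denominators are reported as `NA`, never coerced to 0.
Inter-annotator agreement uses observed agreement and Cohen's κ =
(p~o~ − p~e~)/(1 − p~e~), with κ undefined when p~e~ = 1. The test suite
checks the interval against an independent binomial tail-sum root-finding
oracle for every k ≤ n ≤ 30 (agreement to 1e−6) and κ against direct
formula evaluation on random tables.

## Worked example

```{r example}
corpus <- tibble::tibble(
  doc_id = c("n1", "n2", "n3"),
  text = c(
    "He reports compulsive checking causing marked distress.",
    "His mother has obsessions and compulsions.",
    "Attendance at the day centre is compulsory."
  )
)
kept <- prefilter_corpus(corpus)
kept$doc_id

ann <- detect_ocs(kept)
ann$documents
tidy(ann) %>%
  select(instance_id, anchor_text, fired_rule, excl_categories, final)
```

The first note is positive (a compulsion corroborated by a Y-BOCS example
and an insight marker); the second fires the same inclusion route but is
vetoed by the experiencer rule; the third never enters the pipeline
because "compulsory" is an explicit exception of the `compul*` stem.

```{r eval-example}
synth <- generate_corpus(generator_config(n_docs = 100, seed = 7))
ann <- detect_ocs(synth$corpus)
ev <- evaluate_detection(
  select(tidy(ann), doc_id, instance_id, label = final),
  select(synth$gold_instances, doc_id, instance_id, label),
  level = "instance")
glance(ev)
```

## Numerical and degenerate-input choices

* Empty text: zero sentences, zero instances, document negative.
* A window at a document edge simply has fewer sentences; nothing is
  padded.
* Matching is case-insensitive; offsets always refer to the original
  text. Ties in hit ordering are broken by (start, end, lexicon, stem).
* The sentence splitter protects listed abbreviations ("Dr.", "e.g.") and
  single dotted letters (which covers "o.c.d"), and treats text without
  terminal punctuation as one sentence.
* Exclusion checks are pure functions of (window text, anchor position,
  lexicons, configuration); the detection path contains no randomness at
  all. All randomness in the package lives in the generator, governed by
  one integer seed.
* Problem sizes in the shipped checks — 500 documents for the closed
  loop, 1000 sentences/documents for the matcher and window fuzzers,
  exhaustive k ≤ n ≤ 30 for the interval oracle — were chosen as the
  smallest sizes that exercise every template, route and boundary many
  times over.

## Known limitations

* Temporality is out of scope: "had severe OCD in 2005" counts as a
  mention. Distinguishing current from historical symptoms would need a
  dedicated component.
* Severity is not scored; Y-BOCS totals in text are not parsed.
* The rule pack is lexical and positional; there is no syntactic parsing,
  so unusual constructions ("obsessions were denied by the patient") can
  escape the negation scope.
* Distinguishing OCS from psychotic phenomena relies on the same lexical
  evidence the rules encode; the package inherits that limit.
* The romantic/weight and risk/self-harm term lists are non-canonical
  seed lists and should be reviewed before use on real data.
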