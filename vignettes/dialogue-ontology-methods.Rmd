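---
title: "Ontology-driven counseling dialogue: model, engine and quality metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven counseling dialogue: model, engine and quality metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phido)
```

## The model

phido treats a patient-counseling conversation as a walk over an RDF graph.
The schema (T-Box) is organised in four levels: a **Discussion** (the whole
encounter) *hasGoal* one or more **Communication Goals**; each goal
*hasSpeechTask* an ordered set of **Speech Tasks** (greeting, disclaimer,
topic transition, interviewing, discussing one health fact, question
answering, farewell); each task *hasUtterance* a small graph of
**Utterances**. Utterances are split into system utterances (spoken by the
agent, carrying `hasUtteranceString`) and participant utterances (expected
from the user, carrying `hasUtteranceExamples` for similarity matching).
Every utterance class is annotated with its Searle speech act (assertive,
representative, directive, commissive, expressive, declaration); the two
classes that model uncaptured speech (Unintelligible, Prattle), and abstract
grouping classes, carry no act. Both *assertive* and *representative* are
kept as distinct annotation values because the source inventory prints both;
a note annotation records that Searle's taxonomy treats them as one
category.

Five data properties drive execution: `hasUtteranceString` (what to say),
`hasUtteranceExamples` (what to listen for), `hasUtterancePriority`
(candidate ordering; lower integer = higher priority, assigned in template
listing order), `hasBeenSaid` (minimal dialogue context), and `hasFocus`
(the single marker of where the conversation stands). Utterances are wired
by `precedes`/`follows` — declared mutual inverses, so only `precedes` is
stored and `follows` is answered by inverse closure — and by `speechSegue`,
which links the last utterance of a task to the entry of the next. All
three are sub-properties of the symmetric `utteranceLink`.

The communication goals follow the Health Belief Model: four goals convey
perceived benefits, effectiveness, harms and uncertainty; Acclimate opens
the encounter, Conclude closes it, and Pursuit Before Exit holds the
nudge offered to a hesitant user before giving up.

### What is reconstructed, and what is not

The published ontology reports 86 classes and 9 object properties but names
fewer; `build_schema()` constructs exactly the named inventory — 72 classes
(18 participant utterance classes, 29 system utterance classes including
Health Information, plus the structural hierarchy), 8 object properties and
the 5 data properties. Totals are deliberately not padded to the published
counts: the identities of the unnamed classes and of the ninth object
property are not recoverable. Negative Personal Status is printed twice
with two different speech acts; it is kept once, under both Negative
Utterance and Personal Status, annotated expressive like its sibling, with
the dual printing recorded in a note.

## Task templates

The per-task utterance flows are reconstructed from their published
descriptions and frozen as golden fixtures in the test suite. All templates
share one convention: every point where the user speaks offers an
Unintelligible fallback wired to a Request Repeat loop. The salutation, for
example, is

    System Greet -> {Reciprocal Greet, Unintelligible};
    Unintelligible -> Request Repeat -> {Reciprocal Greet, Unintelligible};
    Reciprocal Greet -> System Introduction -> [segue out]

Discuss Health Topic chains one block per health item: the agent speaks the
fact (Health Information), asks for uptake (Confirm Health Information),
and handles Confirmation (next item), Request System Repeat (replay the
fact), Question (detour to question answering), Disconfirmation (detour to
the pursuit goal) and Unintelligible. Question answering offers one Answer
instance per entry of the task's answers map — each carrying the question
phrasing it answers in its examples — plus a No Answer default, then loops
on "any more questions?" until the user declines.

Where the published account was open, these choices were made once:

* **Goal ordering.** The goal inventory is listed without an order;
  the bundled script and the generator use Acclimate first, the four
  Health-Belief goals in benefit/effectiveness/harms/uncertainty order, and
  Conclude last, because Acclimate is described as introductory and
  Conclude as the ending goal.
* **Off-path tasks.** Tasks inside a Pursuit Before Exit goal and
  question-answering tasks are excluded from the linear happy-path chain:
  they are reachable only through Disconfirmation and Question segues,
  which is the only reading under which a cooperative user never meets
  them. Each detour records a resume address (where the declined
  Confirmation would have led) on a single-depth return stack; the detour's
  exit pops it, with the farewell entry as fallback.
* **Refusal handling.** A Disconfirmation in an ordinary task segues to the
  pursuit goal's first task; a second refusal inside the pursuit task leads
  to a Capitulate utterance and then the valediction — pursue once, never
  twice.
* **Topic options** are listed in a single Topic Options utterance rather
  than sibling utterances, since nothing in the flows selects among
  siblings at that point.
* **Retry budget.** Repeated misunderstanding ends the session; the number
  of tolerated repeats per Request Repeat site is not published. The
  default budget is 2, counted per site, after which the engine emits a
  segue to session end.

## The engine

The transition mechanism is a query loop: ask which utterances `follow` the
focus (ordered by priority, ties by instance id; when none, the
`speechSegue` targets), act, move the focus. A system focus is spoken
(`system_say`), marked `hasBeenSaid`, and the focus advances — pausing with
`await_input` when the followers are participant slots. A participant slot
classifies the supplied input: each candidate is scored by the maximum
token-set Jaccard similarity between the lower-cased, punctuation-stripped
input and the candidate's examples; the best candidate is matched when its
score reaches the threshold τ, otherwise the input is Unintelligible.
τ defaults to 0.5 — the midpoint at which an input sharing half its token
union with an example still matches — and is configurable; Jaccard was
chosen because it is deterministic, dependency-free and auditable, where
the source specifies only "similarity matching". A matched participant
utterance is marked heard and the focus passes *through* it to its follower
in the same step (pausing on the participant node would deadlock the
query loop). Exactly one instance holds `hasFocus` after every step, none
after `session_end`; both invariants are property-tested across randomized
personas, together with the monotonicity of `hasBeenSaid` and a termination
bound of nodes × (retry budget + 1) × (question budget + 1) turns.

## The simulator

`generate_script()` emulates the shape of a vaccine-counseling encounter: a
salutation, a disclaimer-led discussion opening, a short interview, one
transition + discussion (+ question-answering) block per Health-Belief
goal with `items_per_topic` facts assembled from a fixed vocabulary, an
off-path pursuit goal, and a valediction. Defaults (4 goals, 2 items per
topic) keep a cooperative run around 30 engine turns — the scale of a short
counseling session. `participant_policy()` supplies five personas:
cooperative (always the first example of the highest-priority compliant
reply), repeater, confused, questioner and refuser, each perturbing the
cooperative baseline at its trigger sites with stated probabilities. Each
session draws from one private RNG stream seeded by the caller, so
transcripts are reproducible bit-for-bit. Gibberish is emitted from a
consonant-cluster alphabet disjoint from every example vocabulary, making
the Unintelligible classification certain rather than probabilistic.

What the simulator does **not** model: real patient language (paraphrase,
hesitation, mixed intents), speech recognition noise, or mixed-initiative
topic jumps. Passing tests therefore demonstrate the control-flow contracts
of the ontology and engine, not natural-language robustness.

## The metric suite

Six sub-scores on three semiotic branches, each in [0, 1]:

* **lawfulness** = 1 − violating statements / total statements, where
  violations are breaches of the supported OWL2 profile (undeclared
  predicates, class axioms over literals or undeclared classes, punning
  between declaration kinds, literal/IRI mismatches on property values);
* **richness** = share of a recognised axiom-type inventory in use; the
  inventory is configuration (15 types by default) because the original
  feature list behind the published richness of 0.38 is not specified;
* **interpretability** = fraction of distinct label words with at least one
  sense in a word-sense provider;
* **clarity** = mean of 1 / max(1, senses) over label words;
* **consistency** = fraction of satisfiable classes under structural
  reasoning (subclass closure against asserted disjointness) — a full DL
  reasoner is deliberately not involved, which is sufficient for schemas
  without complex class expressions;
* **comprehensiveness** = class count / reference library size, capped at
  1; the reference size is configuration (default 10,000) because the
  benchmark library's average is not published.

Composites: syntactic = mean(lawfulness, richness); semantic =
mean(interpretability, consistency, clarity); pragmatic =
comprehensiveness; overall = Σ weight × branch with default weights 1/3 —
read as exactly one third so a perfect ontology scores 1.00. On the
published branch values (0.69, 0.94, 0.00) this yields 0.54, matching the
published overall. Note that the unweighted mean of the published semantic
sub-scores (0.94, 1.00, 0.92) is 0.95, not the published 0.94; the original
weighting is unrecoverable, so no result here is pinned to it. The
pragmatic sub-scores relevance and accuracy require human domain experts
and are out of scope, as are benchmark z-scores beyond the configurable
`benchmark` input of `metric_zscores()`.

The word-sense provider is a contract (`function(word) -> senses`); the
bundled `toy_lexicon()` is a deterministic table covering the schema
vocabulary, suitable for offline tests. Scores computed with it are
comparable across runs of this package but not directly against scores
computed with a full lexical database.

```{r metrics}
report <- semiotic_report(build_schema())
report
```

## Numerical and degenerate-input conventions

Empty ontology: lawfulness 1, interpretability/clarity 1 (no words),
consistency 1 (no classes), comprehensiveness 0. Unknown words clamp to one
sense in clarity. Candidate ties in the engine break by instance id after
priority; classification ties break toward the higher-priority candidate.
Scripts must start with the salutation (if present) and end with the
valediction (if present); a discussion task requires at least one health
item.

## Problem sizes

The test suite exercises the full bundled counseling script (about 100
utterance instances), randomized persona runs accumulating over 1,000
engine turns, exhaustive inverse-closure checks on graphs up to 200 nodes,
and a dozen randomized sub-schema serialization round-trips per dialect —
sizes chosen to cover every template and engine branch while keeping the
default suite under a minute.

## Known limitations

* The RDF layer supports the OWL2 subset the package emits (named classes,
  property declarations and annotations; no blank nodes, collections or
  class expressions); documents outside it are rejected at parse time.
* Structural consistency misses unsatisfiability that requires full DL
  reasoning.
* The classifier is lexical; paraphrases outside the example vocabulary
  classify as Unintelligible by design.
* The published class/property totals and z-score benchmarks are not
  reproducible from the published record; see the sections above.
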