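---
title: "Building and updating clinical knowledge graphs with clinkg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and updating clinical knowledge graphs with clinkg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`clinkg` maintains a clinical knowledge graph (KG): a property graph in
which nodes are clinical concepts — drugs, diseases, symptoms, side
effects, outcomes, trials, labs, procedures — and edges are typed
assertions between them (`TREATS`, `CAUSES`, `RESULTS_IN`,
`ASSOCIATED_WITH`, `CONTRAINDICATED_IN`, `USED_IN_TRIAL`, `REPORTED`,
`INDICATES`). Every edge carries a confidence in $[0,1]$, the full list
of sources asserting it, and a half-open validity interval
$[\mathrm{valid\_from}, \mathrm{valid\_to})$; an absent `valid_to` means
the assertion is currently active. Every source is tagged with an
authority tier, ordered

$$\text{regulatory guideline} \;>\; \text{structured EMR} =
\text{textbook} \;>\; \text{trial report} \;>\;
\text{unstructured note},$$

which drives both confidence scoring and conflict resolution.

The central assumption is that most clinical concepts are stable: a
one-time *topology discovery* pass over curated, authoritative documents
establishes the bulk of the graph's nodes, and the ongoing stream of
clinical documents and EMR encounters then mostly *enriches* that
topology — new edges and attributes on existing nodes — with genuinely
novel concepts (a breakthrough drug, a new trial) being the exception.
Updates are two-phase:

1. **Extraction** turns each incoming item into candidate facts. For
   text this is entity recognition plus relation patterns; terms are
   normalized to standard vocabularies (SNOMED CT, ICD-10-CM, RxNorm,
   LOINC) through a three-stage cascade — exact lexical match after
   canonicalization, synonym expansion, then adjudicated ranking under a
   semantic-type filter — with a separate crosswalk branch for terms that
   arrive already carrying a code. For structured records it is schema
   alignment (exact, similarity, terminology-code), timestamp-based
   temporal precedence, and attribution of labs/medications to one of the
   encounter's active comorbidities.
2. **Application** validates each candidate syntactically (types, dates,
   confidence bounds) and semantically (predicate domain/range rules,
   e.g. `TREATS`: drug $\to$ disease), detects contradictions against an
   exclusion table (by default a drug cannot both treat and be
   contraindicated in the same condition), resolves them by authority
   then recency, scores confidence, and merges atomically and
   idempotently.

Conflict resolution implements *temporal supersedence*: when the
challenger outranks the incumbent (higher tier, or equal tier and
strictly newer source date), the incumbent's validity interval is closed
at the winner's source date and the challenger inserted; when the
incumbent outranks the challenger nothing changes; a full tie is flagged
for review and the graph's assertions stay as they were. The incumbent's
standing is judged by its *creation* source (first provenance entry). A
pluggable adjudicator may instead return a qualified reconciliation
("treats in general, but contraindicated in this patient"), in which
case both edges are kept and the challenger annotated with the
qualifier. Because a winner must be strictly greater in the
(tier, date) order, supersedence cannot cycle.

Edge confidence is `tier_base × method_factor`, clipped to $[0,1]$:

| | ontology / crosswalk / direct KG | rule | adjudicator | similarity |
|---|---|---|---|---|
| regulatory guideline (0.95) | 0.95 | 0.855 | 0.8075 | 0.76 |
| textbook / structured EMR (0.90) | 0.90 | 0.81 | 0.765 | 0.72 |
| trial report (0.80) | 0.80 | 0.72 | 0.68 | 0.64 |
| unstructured note (0.60) | 0.60 | 0.54 | 0.51 | 0.48 |

The formula is a package convention: the inputs (authority ordering,
method of inference) are principled, the numeric bases and factors are
chosen to keep high-authority rule-extracted edges above the direct-link
threshold (below) and note-derived similarity mappings well under it.

## Pluggable contracts

Four seams accept external components, each with a deterministic
reference implementation so the whole pipeline runs and tests without
any model inference:

* **recognizer** — text to mentions; reference: case-insensitive,
  word-boundary, longest-match dictionary scan over the terminology's
  surface forms, emitting 0-based half-open offsets.
* **relation backend** — sentence to triples; reference: the surface
  pattern grammar (`X treats Y`, `T reported S`, ..., with `, which`
  relative-clause expansion).
* **embedder** — two strings to a similarity in $[0,1]$; reference:
  token-set cosine over canonical tokens,
  $|A \cap B| / \sqrt{|A||B|}$.
* **adjudicator** — a structured request (question kind, options,
  context, history) to `(choice, confidence, rationale)` or a decline.
  The scripted adjudicator answers from a JSON map keyed by a
  deterministic request key; the default stub declines, so ambiguous
  cases degrade to *unresolved/unattributed* rather than being guessed.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `schema_accept` | 0.80 | minimum similarity for a stage-2 schema mapping to be accepted |
| `schema_review` | 0.60 | mappings scoring below this are flagged for review |
| `direct_link` | 0.80 | minimum edge confidence for a KG association to count as a "strong, specific" link during attribution |
| `exclusions` | `{TREATS, CONTRAINDICATED_IN}` | mutually exclusive predicate pairs (symmetric, extensible) |
| `target_namespace` | SNOMEDCT | namespace diagnosis codes are crosswalked into |

All three thresholds are dimensionless scores in $[0,1]$. No published
quantitative definition exists for "strong and specific", so 0.80 is a
package decision: it admits guideline- and textbook-derived assertions
(0.81–0.95) and excludes trial-report and note-derived ones. The review
band mirrors common practice of a two-threshold triage (auto-accept /
propose-with-review / reject).

Canonicalization (lower-case, punctuation to spaces, collapse
whitespace, sort tokens) replaces lexical-variant tooling; it is pure,
idempotent and case-insensitive, which the suite checks
property-style. Stage-2 synonym matching is *exact* over canonicalized
synonyms — no fuzzy distance — so the cascade is deterministic; fuzzy
scoring lives only behind the embedder contract. A stage-3 score is the
adjudicator's reported confidence clipped to $[0,1]$.

## What the generator emulates

`generate_corpus()` fabricates the full study input at desk scale: a
terminology fixture (always containing the worked rows
ICD-10-CM E11.9 → SNOMED CT 44054006 and RxNorm 860975 with its
"Metformin 500 mg extended-release" synonym, plus LOINC→SNOMED lab
rows); 50 initialization documents (guidelines/textbooks) whose
sentences come from the same grammar the reference relation backend
parses; 500 update documents (trial reports and notes carrying new
edges, trial attributes, authority-backed attribute revisions, novel
concepts, and injected contradictions); and 200 EMR encounters with
concurrent comorbidities, ICD-coded diagnoses, timestamped medication
orders and lab results, including the named creatinine /
acute-kidney-injury / pneumonia attribution scenario and scripted
answers for the injected ambiguous labs.

The defaults are the study conditions: 85% of final-graph nodes
created at initialization (the generator sizes its novel-concept
injection from `target_init_node_fraction`), at least 80% of update
operations enriching existing elements, a conflict-injection rate of
0.02 over update documents and an ambiguity rate of 0.02 over
encounters (both rates are package choices — ten contradictions and
four scripted ambiguities at the default scale keep every scenario
exercised without exhausting the drug pool the EMR generator draws
from). The injected conflicts deliberately cover all three outcomes:
a 2023 guideline superseding a 2010–2012 textbook assertion, a 2022
note losing to an initialization guideline, and a same-tier same-date
tie that is flagged.

While emitting items the generator *mirrors* the updater's counting
rules, so its manifest predicts the pipeline's ChangeSet exactly and
records the intended final node/edge sets; the acceptance suite checks
both to equality. Everything is a deterministic function of the seed —
two runs with the same config are byte-identical.

What the generator does **not** emulate: real clinical language
(sentences are grammar-clean, so recognizer precision/recall of 1.0 on
generated corpora says nothing about free text), negation/hedging,
abbreviation ambiguity beyond the scripted cases, imaging or other
non-text modalities, statistical realism of prevalence or co-occurrence,
and adversarial terminology (overlapping synonyms across concepts).
Passing tests therefore demonstrate the correctness of the graph
machinery — merge semantics, conflict policy, accounting, queries — not
the linguistic robustness of extraction on real notes.

## Numerical and bookkeeping conventions

* **ChangeSet semantics.** `attributes_modified` counts property
  assignments that actually change state — a new key, or an overwrite
  that wins under the authority rule — plus validity closures from
  supersedence. Provenance unions and confidence-max merges are applied
  but audit-only. This makes replay exactly zero: re-applying an applied
  batch changes nothing and counts nothing.
* **Single-valued property conflicts.** Equal incoming value: no-op.
  Different value: overwrite iff the incoming (tier, date) is strictly
  greater lexicographically; full tie keeps the incumbent and logs.
* **Flagged conflicts.** A flagged tie records the challenger as a
  review marker on the incumbent edge; the graph's assertion content is
  unchanged, and the identical challenger seen again (e.g. on replay) is
  not re-counted.
* **Determinism.** Node ids are deterministic functions of the identity
  key (first sorted concept code, else canonical name + semantic type),
  so merges are replay-stable. Serialization writes JSON-Lines with
  sorted keys and sorted record ids; two serializations of the same
  store are byte-identical. Paths order by length then lexicographic
  node sequence; entity results sort by node id.
* **Degenerate inputs.** Empty text yields empty mention/triple lists;
  a blank term, an out-of-range confidence, an impossible date
  (`2023-13-40`) or a dangling endpoint raise classed errors
  (`kg_syntax_error`, `kg_entity_error`, `kg_timestamp_error`,
  `kg_code_conflict`); an unparseable timestamp rejects the whole EMR
  record; item-level pipeline failures are logged and skipped without
  touching the graph (per-item atomicity under value semantics).
* **Text metrics.** BLEU is BLEU-4 with clipped precisions, add-one
  smoothing on orders ≥ 2, orders above the candidate length skipped,
  zero unigram precision short-circuiting to 0, and brevity penalty
  $\exp(1 - r/c)$ against the closest (ties: shorter) reference length.
  ROUGE is ROUGE-L F1. Both are conventions fixed here so scores are
  comparable across runs; rating aggregation counts ratings ≥ 3 as
  clinically acceptable and ≥ 4 as very good or excellent.

## Open design points, decided

* Crosswalk resolution is a separate normalization branch keyed on an
  attached code and tried before the lexical stages; synonym expansion
  never triggers a crosswalk hop on its own.
* Paths are simple (no repeated nodes) — traversal terminates and a
  clinical chain that revisits a concept has no obvious reading.
* Batch and real-time ingestion share one code path; the mode only
  changes commit-granularity bookkeeping in the log, since per-call
  atomicity is the actual contract.
* "Cross-verification against structured data" is realized through the
  tier order: a note-derived assertion contradicted by a structured-EMR
  assertion loses automatically.
* Update-delay bookkeeping counts items and stages, not wall-clock
  time; latency is a property of hardware, not of this implementation.
* Triple-level extraction confidence is audit-only; edge confidence is
  always recomputed by `score_confidence()` from source tier and
  inference method.

## Problem sizes

The packaged study conditions are deliberately desk-scale: 50 + 500
documents, 200 encounters, ~115 final nodes, ~280 edges — the full
init + update pipeline runs in a few seconds, and the complete test
suite (including oracle-equivalence sweeps on random graphs up to 200
edges and exhaustive path enumeration up to 50 nodes) in well under a
minute. Corpus sizes are configuration, not code: the same generator
scales up by raising the counts in `synth_config()`.

## Known limitations

* Node identity never merges two existing nodes; if two nodes are later
  discovered to be the same concept (one code-keyed, one name-keyed),
  they stay distinct unless re-ingested through a payload carrying both
  identities.
* Only one exclusion pair ships by default; richer medical-logic rules
  (dose ranges, age contraindications) are out of scope.
* The store is in-memory with value semantics — ideal for correctness
  and testing, not for multi-process writers or graphs that do not fit
  in memory (the Cypher export exists for handing the graph to a real
  graph database).
* The reference extraction grammar is closed over the generator; real
  corpora need real recognizer/relation backends plugged into the same
  contracts.
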