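---
title: "Severity annotation of phenotype ontologies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity annotation of phenotype ontologies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosev)
```

# The problem

Phenotype ontologies organise tens of thousands of phenotypic abnormalities
into an `is_a` DAG but say almost nothing about how severe each phenotype is.
Manual curation of severity at ontology scale is infeasible, which motivates
annotating every term automatically — with a large language model or any
other oracle — and then asking two separate questions: *what severity does
each annotation imply* and *how much should the annotations be trusted*.
`phenosev` implements both halves against a pluggable annotator, so the whole
pipeline is testable offline with simulated annotators of known behaviour.

# The annotation model

Each phenotype is annotated with how frequently it **directly causes** each
of ten clinical characteristics: intellectual disability, death, impaired
mobility, physical malformations, blindness, sensory impairments,
immunodeficiency, cancer, reduced fertility, and congenital onset. The
response vocabulary is deliberately restricted to four ordered frequency
words — never, rarely, often, always — and every response must carry a free
text justification. Constraining the vocabulary makes responses
machine-parseable and comparable across phenotypes; the justification gives
an audit trail (and, as it turns out, a way to detect a failure mode: see
the indirect-causation audit below).

Prompts carry at most two phenotypes each. Longer phenotype lists degrade
LLM formatting discipline and output quality, so the batch driver enforces
the limit structurally: `build_prompt()` refuses more than two names.

Responses use a line-oriented grammar,

```
<phenotype name> | <characteristic>: <frequency> - <justification>
```

one line per (phenotype, characteristic). The grammar was chosen over free
text because it is trivially renderable by an LLM, parseable with one
regular expression, and validates strongly: `parse_response()` rejects
unknown characteristic tokens, unknown frequency words, missing phenotype
blocks and missing or duplicated characteristics, reporting the offending
line. The batch driver retries a failed query (`max_retries`, default 2) and
records permanent failures rather than dropping terms silently — on a real
run some fraction of terms always fails, and that fraction should be
visible, not hidden.

Three bundled annotators implement the contract without any network:
`mock_annotator()` (deterministic hash of name x characteristic, with
keyword override rules), `random_annotator()` (independent uniform draws —
the chance baseline), and `planted_annotator()` (truth-set members answered
often/always with probability 1 − ε).

# The severity score

Frequencies are encoded never = 0, rarely = 1, often = 2, always = 3. Each
characteristic carries an integer weight on a 1–6 scale reflecting
clinician-elicited importance for disease severity: death 6, intellectual
disability 5, impaired mobility 4, blindness 4, physical malformations 3,
sensory impairments 3, immunodeficiency 3, cancer 3, reduced fertility 1,
congenital onset 1. The weighted values (weight x code) for all forty
(characteristic, frequency) pairs are exposed by `weighted_value()`.

The composite severity score of a phenotype is the sum of its weighted
values normalised by the theoretical maximum — the score of a phenotype that
"always" causes everything:

$$\mathrm{NSS}_p = 100 \cdot \frac{\sum_j W_j F_{pj}}{\sum_j W_j F_{\max}}$$

With default weights the denominator is 99, so NSS lies on a fixed 0–100
scale whose meaning does not depend on which other phenotypes are in the
analysis. The normalisation choice (sum over **all ten** characteristics,
including congenital onset) is the one that makes the all-always phenotype
score exactly 100; it follows that NSS is (100/99) x an integer in 0..99,
and that raising any single frequency can never lower the score — both
properties are asserted in the test suite.

## Severity classes

For use cases that need a categorical label, a tier-based decision tree maps
each annotation to Profound/Severe/Moderate/Mild. Characteristics are
assigned tiers (1 = most severe): death 1, intellectual disability 1,
impaired mobility 2, physical malformations 2, blindness 3, sensory
impairments 3, immunodeficiency 3, cancer 3, reduced fertility 4. Congenital
onset carries no tier and is ignored by classification — an intentional
asymmetry: onset contributes to *how much* severity (the score) but is not
itself a harm. Writing H for the characteristics a phenotype often/always
causes:

- |H ∩ Tier 1| > 1 → **Profound**
- |H ∩ Tier 1| = 1, or |H ∩ (Tier 2 ∪ Tier 3)| ≥ 3 → **Severe**
- |H ∩ Tier 2| ≥ 1 → **Moderate**
- otherwise → **Mild**

When several rules fire the most severe class wins; the rules are evaluated
most-severe-first so the tie-break is structural. Note that blindness keeps
weight 4 in the score (where it is grouped with impaired mobility) while
sitting in tier 3 for classification; both maps are explicit arguments
(`default_severity_weights()`, `default_tier_map()`) so the asymmetry is
visible and overridable.

Replicates are always scored independently. An optional consensus mode
(`consensus_annotations()`: modal frequency per characteristic, ties
resolved towards the more severe word) exists for single-annotation
downstream uses but is off by default.

# Evaluating annotation quality

**Replicate consistency.** Over phenotypes annotated more than once, the
*lenient* metric collapses the vocabulary into {always, often} vs
{never, rarely} and requires all replicates in one group; the *stringent*
metric requires identical words. With more than two replicates "all agree"
is used — the strictest reading. The chance levels under independent uniform
draws are exact: `2 · (1/2)^k` lenient and `4 · (1/4)^k` stringent, i.e. 1/2
and 1/4 for duplicate annotation. `chance_consistency()` returns these;
the acceptance suite verifies by Monte Carlo (10,010 duplicated phenotypes,
two replicates each, uniform marginals) that measured rates fall within
three standard errors of both.

**Recall against ontology truth sets.** Some ontology branches reliably
indicate a characteristic: descendants of an "Intellectual disability" term
should often/always cause intellectual disability. `default_benchmark_spec()`
encodes one such query set per benchmarked characteristic (death and
congenital onset have none). Queries mix exact term names and lower-case
substrings; each carries an explicit match mode rather than a guessed one.
Blindness carries exclusion substrings ("color", "colour", "night
blindness") because colour and night blindness are not causes of complete
blindness. The denominator of `true_positive_rate()` is the truth-set
members actually present in the annotation set — first replicate by default,
mirroring a single-pass annotation run — and a hit is an often/always
annotation. Empty denominators are reported as missing, never coerced to 0.

**Indirect-causation audit.** A known LLM failure mode is describing an
indirect effect in the justification while scoring it as a direct cause.
`flag_indirect()` scans justifications case-insensitively for the patterns
"indirectly" and "does not directly" (extensible); `reassign_indirect()`
sets flagged frequencies to never. Because weights are positive,
reassignment can only lower scores and classes — asserted as a property.

**Association statistics.** `depth_consistency_association()` tests whether
consistency improves with term specificity. The unit of analysis is the
(phenotype, characteristic) pair: each duplicated phenotype contributes ten
0/1 consistency indicators paired with its depth. A per-phenotype
all-ten-characteristics indicator was considered and rejected: under
realistic marginals it is nearly always zero, which degenerates the
contingency table; the pair-level rate is exactly the consistency rate whose
depth trend is of interest. Reported: Spearman's rho (depth vs indicator),
Pearson chi-square on the depth x consistent table (no continuity
correction, so the statistic matches the textbook formula used as the test
oracle) and Cramér's V. `class_score_concordance()` reports one-way
between-groups omega squared, `(SSb − dfb·MSw)/(SSt + MSw)`, of NSS across
severity classes with the F-test p-value; for a one-way design this equals
the partial form. Raw p-values are reported throughout; no multiplicity
correction is applied.

**Correlations.** `metric_correlations()` returns the 11 x 11 Pearson matrix
over the ten frequency codes plus NSS. Zero-variance columns yield missing
entries, never 0 — a constant column carries no correlation information.

# Ontology handling: definitions and numerical choices

- **Branches** are the direct children of the resolved root term. For the
  HPO one passes `root_name = "Phenotypic abnormality"`, recovering the
  familiar top-level abnormality categories. A term under several branches
  (multi-parent DAG) belongs to each, and per-branch summaries count it once
  per branch.
- **Depth** is the length of the *shortest* parent-path to the root
  (root = 0) — deterministic, cheap, and well-defined in a DAG where
  "the level" is otherwise ambiguous.
- **Obsolete terms** are parsed and retained with a flag but excluded from
  traversal results, name queries and truth sets: they cannot be annotated.
- Only `is_a` edges are used; a cycle is a hard load error. Terms that do
  not reach the root (possible in ontology subsets) load with depth `NA` and
  an empty branch set rather than failing the file.
- OBO and obographs-JSON loaders are required to agree exactly on a shared
  fixture; writers for both formats make that a testable round-trip.
- Name matching is case-insensitive in both modes (exact, substring).
- Ranking ties on NSS break by term id, making output order reproducible.

# The synthetic generator

`make_toy_ontology()` and `simulate_annotations()` generate the fixtures all
evaluation code is tested on. The generator emulates the *statistical*
structure the evaluation assumes, not the content of a real ontology:

- Branch names are chosen to match the default benchmark queries, so truth
  sets are non-empty on toys; term names are otherwise stubs.
- Per-characteristic frequency marginals default to a never-heavy profile
  (0.55/0.25/0.13/0.07) for nine characteristics — in large annotation runs
  most phenotypes never cause most severe outcomes — and a congenital-onset
  profile with 21.7% never (0.217/0.18/0.25/0.353), since rare-disease
  phenotypes are predominantly early-onset.
- A Gaussian copula couples characteristics through a per-phenotype latent
  severity: with `latent_rho > 0` all of a phenotype's characteristics shift
  together, inducing positive inter-metric correlation and a realistic
  spread of severity classes *while preserving the marginals exactly*
  (thresholds are the marginal quantiles). Replicates share the latent but
  draw independent noise. The default is `latent_rho = 0` (independence);
  evaluation-oriented runs use 0.5–0.6.
- A `dup_fraction` (default 0.05, roughly the duplicated share of a real
  annotation run) of phenotypes receives `n_replicates` draws; truth-set
  members are overridden to often/always with probability 1 − ε
  (default ε = 0.03, consistent with a high-recall annotator); justification
  text is templated, with indirect-causation phrasing injected at
  `indirect_rate` (default 0.03).

What the generator does **not** emulate: real term-name semantics, annotator
biases that correlate with meaning rather than structure, depth-dependent
consistency, or systematic LLM formatting drift. Passing tests on synthetic
data therefore demonstrate that the *measurement machinery* is correct and
that planted signals are recovered at the planted magnitude — they say
nothing about the quality of any particular LLM's annotations.

# Problem sizes and budgets

The test and acceptance workloads were sized to be decisive yet quick: the
Monte-Carlo chance-consistency check uses 10,010 duplicated phenotypes (two
replicates; standard error ~0.005 on the lenient rate), planted-recall
recovery uses ~200 truth members per characteristic at ε ∈ {0, 0.1, 0.25}
(three standard errors ≈ 0.06–0.09), scoring properties use ~1,000 simulated
phenotypes, and the indirect-injection check uses ~10,000 annotation cells at
a 30% injection rate. The full pipeline on a 17,500-term toy ontology
(matching the scale of the real HPO) simulates, scores, classifies and
evaluates in well under a minute on one CPU.

# Known limitations

- Severity is reduced to ten characteristics and a frequency scale; pain,
  treatment availability, disease course, within-phenotype heterogeneity and
  psychosocial burden are outside the model, so NSS is a prioritisation aid,
  not a clinical judgement.
- Weights and tiers are configuration derived from a published clinician
  survey, not fitted quantities; alternative elicitations plug in through
  the same arguments.
- The indirect-causation audit is a substring scan — no stemming, no
  negation handling; its two default patterns are the empirically useful
  ones but recall of the audit itself is unknown.
- Truth sets depend on the ontology release and on the query match modes;
  counts will differ across releases, which is why the benchmark spec is an
  explicit, serialisable document rather than a constant.
- The external-LLM adapter is intentionally out of scope: the annotator
  contract (prompt string in, grammar string out) is the integration point.
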