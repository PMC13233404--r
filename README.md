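# phenosev

Severity annotation and scoring of phenotype ontology terms.

Ontologies such as the Human Phenotype Ontology (HPO) catalogue >17,500
phenotypic abnormalities, but almost none of them carry machine-readable
metadata about how *severe* they are. `phenosev` is a toolkit for building
that metadata at scale with a large language model (or any other annotator),
and for quantifying how trustworthy the result is. It is aimed at rare-disease
researchers and clinical-informatics groups who need per-phenotype severity
estimates for prioritisation — of gene-therapy targets, of treatment order in
complex presentations, of curation effort.

The package covers the whole pipeline:

- **Ontology handling** — load OBO or obographs JSON, query descendants,
  branches and depth of the `is_a` DAG, and build per-characteristic truth
  sets from name queries (`load_ontology()`, `descendants()`, `branch_of()`,
  `term_depth()`, `build_truth_sets()`).
- **Annotation** — prompt construction (two phenotypes per query), a strict
  line-oriented response grammar with parsing and validation, and a batch
  driver over a pluggable annotator contract (`annotate_terms()`). Bundled
  annotators: a deterministic mock, a uniform-random annotator, and a
  planted-truth simulator, so everything runs offline.
- **Severity scoring** — each phenotype is annotated with how frequently it
  *directly causes* each of ten clinical characteristics (intellectual
  disability, death, impaired mobility, physical malformations, blindness,
  sensory impairments, immunodeficiency, cancer, reduced fertility,
  congenital onset), on the scale never/rarely/often/always.
- **Evaluation** — replicate consistency, truth-set recall, indirect-causation
  auditing, metric correlations, depth/consistency association, and
  class/score concordance.
- **Synthetic fixtures and a CLI** — seeded toy ontologies and annotation
  sets with planted structure; a `phenosev` command-line entry point.

## The severity model

Frequencies are encoded numerically, `never` = 0, `rarely` = 1, `often` = 2,
`always` = 3, and each characteristic *j* carries a clinician-derived weight
*W<sub>j</sub>* on a 1–6 scale (death 6; intellectual disability 5; impaired
mobility and blindness 4; physical malformations, sensory impairments,
immunodeficiency and cancer 3; reduced fertility and congenital onset 1).
For phenotype *p* with encoded frequencies *F<sub>pj</sub>*, the composite
severity score is the weighted sum normalised by its theoretical maximum
(every characteristic "always"):

    NSS_p = 100 * sum_j(W_j * F_pj) / sum_j(W_j * F_max)

With the default weights `sum_j(W_j * F_max)` = 99, so NSS lies on a 0–100
scale where 100 is the most severe phenotype possible.

A categorical **severity class** is assigned by a tier-based decision tree
over the characteristics a phenotype often/always causes (tiers: death and
intellectual disability 1; impaired mobility and physical malformations 2;
blindness, sensory impairments, immunodeficiency and cancer 3; reduced
fertility 4; congenital onset untiered and ignored here): more than one
Tier-1 → **Profound**; exactly one Tier-1, or three or more Tier-2/3 →
**Severe**; at least one Tier-2 → **Moderate**; otherwise **Mild**. The most
severe class that fires wins.

## Worked example

```r
library(phenosev)

spec <- fixture_spec(n_branches = 5, terms_per_branch = 40, seed = 42,
                     latent_rho = 0.5, dup_fraction = 0.2)
ont <- make_toy_ontology(spec)
ont
#> <phenotype_ontology> 206 terms (0 obsolete), root TOY:0000001 (Phenotypic abnormality), 5 branches

set <- simulate_annotations(ont, spec)
scored <- score_annotations(set)
rank_phenotypes(scored)[1:3, c("hpo_id", "hpo_name", "raw_sum", "nss", "severity_class")]
#>   hpo_id      hpo_name                    raw_sum   nss severity_class
#> 1 TOY:0000003 Gait disturbance                 83  83.8 Profound
#> 2 TOY:0000070 Gait disturbance subtype 24      77  77.8 Profound
#> 3 TOY:0000086 Gait disturbance subtype 40      76  76.8 Profound
```

`nss` is the 0–100 composite score (83 of the maximal raw sum 99 → 83.8) and
`severity_class` the decision-tree label; replicates are scored
independently. A single annotation scores the same way:

```r
freqs <- setNames(rep("never", 10), characteristics())
freqs[c("death", "congenital_onset")] <- "always"
composite_score(freqs)$nss      # 21.21  (= 100 * (18 + 3) / 99)
classify_severity(freqs)        # "Severe" (exactly one Tier-1 characteristic)
```

Annotation quality on the duplicated subset and against the ontology-derived
truth sets:

```r
consistency_rates(set)[1:2, ]
#>   characteristic          n_duplicated lenient_rate stringent_rate
#> 1 intellectual_disability           41        0.756          0.463
#> 2 death                             41        0.707          0.537

true_positive_rate(set, build_truth_sets(ont))[1:3, ]
#>   characteristic          n_truth n_hit recall
#> 1 intellectual_disability      61    59  0.967
#> 2 impaired_mobility            46    46  1
#> 3 physical_malformations       43    41  0.953
```

The lenient metric collapses {always, often} and {never, rarely}; by chance
alone two replicates agree at 1/2 (lenient) and 1/4 (stringent) —
`chance_consistency(2, "lenient")`. Recall counts truth-set members annotated
often/always; here the generator planted them with a 3% miss rate, so rates
sit near 0.97. Characteristics whose queries match nothing in this small toy
ontology are reported as missing, never as zero.

The same pipeline is available from a shell:

```sh
phenosev simulate --out-dir demo --seed 42
phenosev score --annotations demo/annotations.csv --out demo/scored.csv
phenosev benchmark --annotations demo/annotations.csv \
    --ontology demo/ontology.obo --spec demo/benchmark_spec.json \
    --out demo/recall.csv
```

To annotate a real ontology with a real LLM, implement the annotator
contract — any function mapping a prompt string to a response string in the
grammar `<phenotype name> | <characteristic>: <frequency> - <justification>`
— and pass it to `annotate_terms()`.

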