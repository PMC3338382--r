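---
title: "The bdokit knowledge model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bdokit knowledge model and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdokit)
```

## The knowledge model

`bdokit` models the skeletal dysplasia domain around three knowledge
pillars: the diseases themselves, their genotype (genes, gene mutations,
proteins) and their phenotype (entity–quality composites and references to
external phenotype vocabularies). Each class definition carries a pillar, a
label and synonyms, parents in a subclass DAG, restriction axioms, and
annotation-property values (cross-references such as `omim_no` or
`uniprot_id`; gene mutations also carry the datatype properties `encoding`,
`offset`, `count`, `original_content`, `mutated_content`).

The disease hierarchy is deliberately shallow: the root, a layer of
nosology groups (operationally: direct subclasses of `Bone_Dysplasia`), a
layer of leaf diseases, and occasionally a third level where a historically
distinct disease is kept as a subclass of the disorder that subsumed it.
`depth()` therefore reports 2 for typical leaves and 3 for the historical
ones, and the generator reproduces exactly this shape.

Relations are a closed registry with fixed domains and ranges: a
`characterized_by` axiom may only appear on a dysplasia and its filler atoms
must be gene mutations, phenotypic composites, or external terms descending
from the radiographic-abnormality or phenotypic-abnormality roots;
`has_locus` links gene mutations to genes; `mutation_type` to the external
mutation-type taxonomy; and so on. External terms are held as minimal
MIREOT-style records — id, source, label, and a `parent_hint` naming the
term's parent in its source ontology — which is all the subtree-membership
checks need.

### Axiom representation

Restriction axioms are stored as `(relation, kind, filler)` with kinds
`only`, `some`, and `only_and_some` for the pervasive
universal+existential pair (`has_locus only Gene and has_locus some Gene`).
One construct does not fit this shape: the phenotypic-composite root is
defined by a *disjunction of restriction conjunctions* ("either it has
parts that are phenotypic composites, or it describes an anatomical
entity, or it describes an anatomical composite"). We added a fourth axiom
kind, `disjunct`, holding branches of plain restriction axioms, so that
definition is representable verbatim rather than approximated. The parser
accepts it ("(R and R) or (R and R)"), the serializer reproduces it, and
both validators know that an individual must satisfy at least one branch.

A note on identifier padding: published renderings of the incremental
identifiers vary between `GM000001` and `GM0000001`. The canonical form is
seven digits; the parser accepts five to eight and normalizes, so both
renderings refer to the same class.

## Closed-world validation instead of DL reasoning

The original ontology was checked with open-world tableau reasoners. For a
desk-scale library whose instance data are patient records, we deliberately
use **closed-world constraint semantics** over asserted links: a `some`
restriction demands at least one asserted link of that relation to a
suitably typed individual; an `only` restriction demands that every
asserted link of that relation is suitably typed. This is a divergence, not
an approximation error: open-world semantics can never falsify an
existential from a finite record, which is useless for checking whether a
patient record is complete. The TBox side (`check_tbox()`) is purely
structural: relation domains against pillars, filler atoms against ranges,
reference resolution, and DAG acyclicity.

Typing is subsumption-aware in both directions: an internal class matches a
filler atom through the subclass DAG, an external term through its
`parent_hint` chain. A chain that runs into an unresolvable reference
degrades to a *warning*, never a violation — a missing external parent hint
is a curation gap, not evidence of inconsistency. Restriction axioms are
inherited: an individual asserted to be a specific gene mutation is also
checked against the gene-mutation root's axioms.

`classify_membership()` applies the same machinery to diagnosis: a disorder
is *compatible* with a patient when the disorder's `characterized_by`
universal filler covers every linked finding. Two vacuous cases follow
directly from the semantics of the universal quantifier and we kept both: a
patient with no findings is compatible with every disorder, and a disorder
with no `characterized_by` axiom (no established gene or phenotype links)
constrains nothing and is compatible with every patient. The universal
restriction is read as "allowed features", not "required features";
required features would need existential axioms that the disease
definitions do not carry.

Violations are reported as data (subject, relation, kind, message), ordered
lexicographically so that reports diff reproducibly.

## Analytics

The phenotype profile of a disorder is the set of phenotype-kind atoms
(external HP/REAMS terms and phenotypic composites) in its
`characterized_by` fillers; gene-mutation atoms are excluded. Overlap
analytics are plain set intersections over these profiles.

Disorder ranking must turn "probabilistic correlations" into something
concrete; the design was genuinely open and we chose **Jaccard similarity**
between the patient's phenotype set and each profile as the default scorer
because it is deterministic, parameter-free and exactly reproducible. A
second scorer sums the confidences of fired association rules per
consequent, normalized over all fired rules; it is exposed
(`rank_disorders(..., method = "rules")`) but not the default, since its
output depends on the mined rule set. Ties always break by term id.
Patient mutations are accepted in case records but ignored by both scorers;
conditioning on mutation evidence is listed as future work rather than
silently mixed into a phenotype score.

Association rules `{phenotype subset} → diagnosis` are mined Apriori-style
with an antecedent size cap (default 3, desk-scale tractability); support
counts rule-satisfying cases over all cases, confidence over
antecedent-carrying cases. `refine_rules()` then drops any rule whose
antecedent is incompatible with the consequent's universal filler — the
axiom-aware filtering step — and is idempotent by construction. No
statistical significance testing is attempted.

Text annotation is dictionary matching only: case-insensitive,
left-to-right, longest-match, non-overlapping, on word boundaries, with
offsets reported 0-based half-open on whitespace-normalized text.
Entity–quality decomposition of phenotype labels uses the same matcher with
a typed lexicon; morphological variation ("prolapsed" vs "prolapse") is
handled by lexicon alternates rather than a lemmatizer, keeping the
operation deterministic.

## The synthetic nosology generator

Real disease labels, HP content and OMIM numbers are not shipped; the
generator emulates the *structural statistics* of the real ontology so that
every module is testable offline:

| parameter | default | rationale |
|---|---|---|
| `n_groups` | 40 | the nosology's group count |
| `dysplasias_per_group` | 3 | 120 leaves: desk-scale stand-in for 475 |
| `depth3_fraction` | 0.10 | a minority of leaves are historical depth-3 diseases |
| `n_genes`, `n_mutations`, `n_proteins` | 60 / 90 / 50 | preserves the released counts' proportions |
| `phenotype_pool_size` | 100 | pool for profile sampling |
| `profile_size` | 8 | phenotypes per linked disease |
| `frac_with_mutation` | 0.70 | fraction of leaves with mutation links |
| `frac_with_phenotype` | 0.80 | fraction of leaves with phenotype links |

The linkage fractions are applied as exact subset sizes
(`ceiling(frac * n_leaves)`), not Bernoulli draws, because ">70%
mutation-linked" is a property of the artifact being emulated, not a
sampling distribution. `paper_scale_config()` switches to the released
pillar counts (515 dysplasia classes = 40 groups + 475 leaves, 254 genes,
361 gene mutations, 224 proteins). Synthetic phenotypes form a random
parent forest under the phenotypic-abnormality root so subsumption-aware
matching is exercised; mutation encodings are drawn from the nomenclature
grammar so every generated knowledge base also exercises the parser.
Generation is a pure function of the configuration (seed included) and the
canonical serialization is byte-identical across runs.

Cohort simulation (`generate_cases()`) samples a true disorder uniformly
among phenotype-linked leaves, keeps each profile phenotype with
probability `1 - dropout`, and adds `n_spurious` off-profile phenotypes.
The reference study conditions used throughout the tests are 200 cases,
dropout 0.2, 2 spurious phenotypes.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: real phenotype profiles are correlated within
disease groups (synthetic profiles are drawn independently, which makes
ranking *easier* than reality); synthetic labels carry no clinical
vocabulary, so annotation tests say nothing about real clinical-text
recall; and external hierarchies are shallow random forests, not HP's deep
lattice.

## Numerical and degenerate-input choices

* Support/confidence thresholds are compared with a `1e-9` slack so that
  counts like 8/10 pass a 0.8 threshold despite floating-point division.
* An empty knowledge base reports zero counts and `NA` linkage fractions
  (no leaves to take a fraction of).
* `overlap_distribution()` of an empty-profile focus is empty; ranking
  returns only positive scores.
* Serialization is deterministic everywhere (classes sorted by id,
  annotations by key, violations lexicographically); two writes of the same
  knowledge base are byte-identical.
* Cycle errors abort a load; Table-level domain violations in a loaded file
  are collected as warnings and the load continues, matching how a curated
  file with one bad axiom should behave.

## Problem sizes in the test suite

The suite builds its fixtures in code: the bundled reference definitions
(8 own classes, 18 external terms) for the worked examples; generated
nosologies of 3–10 groups for property tests; 100 perturbed knowledge bases
plus 100 random ABoxes (and a second 200 in the acceptance tests) for
validator/oracle agreement; 1000-instance round-trip batches for the
grammar and the mutation encoding; cohorts of up to 15 cases for exhaustive
rule-miner comparison; and one full-scale (515/254/361/224) generation in
the acceptance script. These sizes were chosen as the smallest at which the
properties are non-trivial.

## Known limitations

* The OWL readers cover the constructs this knowledge model uses (named
  classes, subclass axioms, only/some restrictions, union fillers, labels
  and annotations). They are not general RDF parsers; in particular the
  disjunction-of-restrictions axiom is supported only in the canonical
  dialect, and OWL output is not produced.
* Cardinality restrictions beyond only/some are out of grammar; the model's
  definitions use none.
* The mutation dialect covers substitutions (`count = length(orig)`);
  insertions and deletions are out of scope, and the offset's coordinate
  system (cDNA vs genomic) is recorded opaquely, never converted.
* No tableau reasoning, no inferred hierarchy, no equivalence or
  disjointness axioms.
* Whether multiple qualities in one quality composite are conjunctive or
  alternative is underdetermined by the printed definitions; `has_part` is
  treated as conjunction, and the choice is flagged here rather than hidden.
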