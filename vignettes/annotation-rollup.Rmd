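---
title: "Deriving gene-level annotations from mouse genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving gene-level annotations from mouse genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generollup)
```

## The model

Curated mouse phenotype (Mammalian Phenotype ontology, `MP:`) and disease
(`OMIM:`) annotations attach to **genotypes**: one or more allele pairs on
a strain background. A gene-level annotation is a stronger claim — that a
mutation in *this marker* causes the phenotype — and deriving it means
deciding, per genotype, which marker (if any) can carry that claim.

The unit of evidence is the **locus set** of a genotype: every genetic
locus its alleles touch, each tagged with how it is touched.

| evidence tag     | meaning                                                    |
|------------------|------------------------------------------------------------|
| `mutated`        | endogenous locus disrupted by the allele                   |
| `transgene_self` | the transgene marker of a transgenic allele                |
| `region_gene`    | endogenous gene inside a multi-genic mutation region       |
| `expressed`      | inserted expressed-gene cargo (mouse gene or ortholog)     |

Three modelling conventions matter throughout:

* A multi-genic region marker (an engineered deletion) contributes **both
  itself and its member genes**: a deletion spanning 39 genes counts as 40
  loci. This is what routes deletion genotypes into the multi-genic branch
  rather than the single-locus branch.
* The tool product of a recombinase or transactivator allele (cre, Flp,
  tTA) is **never** recorded as an expressed gene, and neither are
  expression-modifying motifs (ERT, ERT2). `expressed_genes` holds only
  genuine cargo. Consequently "the allele expresses nothing but its tool"
  is testable as `length(expressed_genes) == 0` — and an allele with even
  one recorded cargo gene is retained by the filter, because that cargo
  may cause phenotypes.
* Cargo without a mouse ortholog is usually absent from the record
  entirely; when a curator does record non-mouse cargo (species
  `non_mouse`), it counts as a locus and later forces exclusion of the
  genotype, but it can never be an annotation subject.

## The filter

Non-causative ("tool") allele classes, with the evidence for each verdict:

1. **wild-type** alleles — always tools;
2. **transgenic transactivator** alleles with no cargo;
3. **transgenic reporter** alleles: attribute `reporter` without
   `inserted_expressed_sequence` (attribute-based, since a reporter-only
   transgene has no recordable cargo anyway);
4. **recombinase** alleles with no cargo, of *any* generation method, but
   only in **conditional** genotypes — in a non-conditional genotype the
   same allele may be causative and is retained.

Knock-in (targeted) reporters and transactivators are never excluded: many
are simultaneously knock-outs of their host gene. This is a documented
source of false negatives (a knock-in tTA cannot be filtered even when it
is acting purely as a tool), accepted to avoid false positives.

Rules are evaluated in the fixed order above purely so reason codes are
reproducible; each rule keys on different evidence, so the outcome is
order-independent. Classification of one allele never consults the others,
making the filter idempotent and permutation-invariant.

## The resolution flow

After counting loci (box 1) and filtering (box 2), the engine resolves:

* **one locus before filtering** → annotate it (`B1_SINGLE`);
* **nothing retained** → excluded, `all_alleles_excluded`;
* **one locus after filtering** → annotate it (`B3_SINGLE_AFTER_FILTER`),
  or `B11_SELF_EXPRESSED` when the sole gene is also its own inserted
  expressed gene (a knock-in expressing a variant of its host gene);
* **one region marker ± its member genes** → annotate the region marker
  only (`B4_MULTIGENIC_MARKER`); two region markers, or a region marker
  plus an outside locus → excluded;
* **no expressed gene among several loci** → excluded
  (`multi_marker_no_expressed`) — the Apoe;Fasl-style digenic case;
* **several expressed genes** → annotate the single transgene if no
  endogenous mutated gene remains (`B6_TRANSGENE_ONLY`; the transgene as a
  whole is causative, not its individual cargo), else excluded;
* **one expressed non-mouse gene** → excluded (`non_mouse_expressed`); no
  assumption is made that the mouse ortholog would behave the same;
* **one transgene + its expressed mouse gene** → annotate both (`B8`, or
  `B9` when the same gene is additionally mutated endogenously — the two
  boxes differ only in the trace);
* **docking site + one expressed mouse gene** → annotate the expressed
  gene only (`B10_DOCKING_SITE`);
* anything else → excluded, `unresolved_multi`.

On every path, markers in `never_self_annotate_ids` (by default
*Gt(ROSA)26Sor*, for which no mutant phenotypes are known) are stripped
from the result; a result emptied this way reports `rosa_suppressed`.

### Tunable parameters

`derivation_config()` has two knobs, both marker-id sets:

* `docking_site_ids` — default: the catalog markers whose symbols are
  `Gt(ROSA)26Sor`, `Col1a1`, `Hprt`. Docking behaviour comes **only** from
  membership here, never from inference; this deliberately preserves the
  documented false negative where an insertion at another intergenic site
  (the *Igs1*/Edn2 case) stays unannotated. Promoting such a site via a
  config file flips that genotype to `B10` without touching the engine.
* `never_self_annotate_ids ⊆ docking_site_ids` — default Rosa26 only;
  *Col1a1* and *Hprt* may self-annotate when a cargo-less insertion is the
  sole remaining locus, Rosa26 may not.

Strain background is carried in every trace but never consulted — which
preserves the documented false positive where a knock-out on a
diabetes-prone NOD background inherits the strain's disease annotation.

## Design decisions at genuinely open points

* **Tool-cargo threshold.** "Excluded only if it expresses nothing but its
  tool product" is implemented as zero recorded expressed genes. An
  alternative reading (at most one) would wrongly exclude a recombinase
  that carries exactly one cargo gene, contradicting the retention of
  cargo-bearing tools; zero is the only reading consistent with the cargo
  conventions above.
* **Reachability of `B11`.** The self-expressed pattern is a single-member
  locus set, so it is recognized inside the single-remaining-locus branch
  (both tags `mutated` and `expressed` on the sole gene) rather than as a
  separate late stage; the annotation outcome is identical to `B3`, the
  split exists for trace fidelity.
* **Strict docking geometry.** `B10` requires the post-filter set to be
  exactly {docking site, one expressed mouse gene}; any extra locus falls
  through to exclusion. Looser readings would trade false negatives for
  false positives, against the stated priority.
* **Box-6 endogenous test.** "No additional endogenous genes" is read as:
  no retained locus tagged `mutated` other than the transgene itself.
* **Conditional without recombinase.** A genotype flagged conditional that
  contains no recombinase allele gets no special handling; the flag only
  arms filter rule 4.
* **Exclusion label for digenic genotypes.** A multi-gene genotype with no
  cargo reports `multi_marker_no_expressed` (the stage that eliminates
  it), not the catch-all `unresolved_multi`.

## The synthetic-data generator

`simulate_catalog()` draws genotypes from a mixture of sixteen archetypes
(simple knock-outs, conditional cre models, transgenic over-expression
models, docking-site knock-ins, engineered deletions, digenic crosses,
all-tool genotypes, ...). The default weights were chosen once to echo the
reported structure of the curated corpus — a majority of single-marker
genotypes (weight 0.45), conditional cre models as the largest multi-marker
class (0.12), digenic models next (0.08), and small but non-zero weights
(0.01–0.06) for every remaining archetype so that each terminal box and
each exclusion reason is reachable in a 1000-genotype sample. They were
not tuned against test outcomes.

What a green property suite on synthetic data establishes: the engine's
set-level behaviour (conservation of fan-out, Rosa26 suppression,
tool-exclusion soundness, permutation invariance, agreement with an
independently written brute-force decision table) on catalogs that are
*structurally* like the curated corpus. What it does not establish:
behaviour on real curation irregularities (inconsistent attribute usage,
shared alleles across hundreds of genotypes, ontology structure, real
strain genetics, corpus-scale marker frequencies). The curated
worked-example fixtures cover the documented real cases, including the
published false positives and false negatives, which the suite asserts
*as documented behaviour*, not as biological truth.

A property worth stating precisely: adding a fresh homozygous mutant pair
to a genotype never causes any *pre-existing* marker to gain annotation.
The fresh gene itself may legitimately become the subject when every
original allele was a tool — the new mutation is then the genotype's only
causative one — so the monotonicity claim is about the restriction to the
original marker universe.

## Numerical and degenerate-input choices

* All outputs are deterministically sorted (derived annotations by marker,
  term, ontology; traces by genotype id; locus sets and marker sets
  lexicographically), so reruns are byte-identical and diffs meaningful.
* Validation returns violations as data rather than raising; a catalog
  that validates cleanly is guaranteed not to raise cross-reference errors
  in the engine.
* An all-excluded genotype resolves to "no annotation", never an error.
* Homozygous pairs contribute their allele once; pair order and
  allele1/allele2 order are meaningless and tested as such.
* The simulator restores the caller's RNG state; identical parameters and
  seed give byte-identical catalogs.

## Known limitations

* Causality is single-marker by construction: digenic phenotypes are never
  attributed, even partially, to either gene.
* Knock-in transactivators/reporters and mouse-gene reporters (the *Tyr*
  coat-colour idiom) cannot be filtered, losing otherwise derivable
  annotations.
* Strain-background effects are not modelled; background-driven
  annotations are inherited by the mutated gene.
* Expressed orthologs of mouse genes (humanized models) yield no
  annotation for the mouse ortholog.
* Region membership is curated input; no genomic-coordinate computation is
  attempted.
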