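# generollup

Roll genotype-level mouse phenotype and disease annotations up to the gene
whose mutation actually causes them.

## The problem

Mouse model-organism databases (MGI-style) curate Mammalian Phenotype (MP)
ontology terms and OMIM disease associations against *genotypes*: sets of
allele pairs on a strain background. A modern mouse model rarely carries
just one mutation — alongside the causative allele there are experimental
tools: *cre* recombinase drivers, tTA/tetO transactivator systems,
fluorescent reporter transgenes, wild-type partner alleles. A user asking
"what phenotypes does a mutation in gene *X* cause?" should not be told
that *cre* causes diabetes because a *cre* driver happened to be present in
a diabetic model.

`generollup` implements the rule engine that answers that question. For
each annotated genotype it:

1. counts the genetic loci touched by all alleles — mutated endogenous
   genes, genes inside engineered deletion regions, transgene markers, and
   inserted expressed "cargo" genes;
2. filters out non-causative tool alleles using curated allele attributes
   (generation method × {reporter, recombinase, transactivator,
   inserted expressed sequence, ...}): transgenic reporter-only and
   transactivator-only alleles, recombinase alleles in conditional
   genotypes, and wild-type alleles. A tool allele that also expresses
   another gene is retained;
3. resolves the remaining locus set through a decision flow: a single
   remaining locus is annotated directly; a deletion spanning many genes is
   attributed to the region marker, not its member genes; a transgene plus
   its single expressed mouse gene annotates both; docking-site knock-ins
   (*Gt(ROSA)26Sor*, *Col1a1*, *Hprt*) are attributed to the inserted
   expressed gene, never to *Gt(ROSA)26Sor* itself; everything genuinely
   multi-genic is conservatively left unannotated (false negatives are
   preferred to false positives).

Every genotype gets a full decision trace: per-allele verdicts, locus sets
before and after filtering, the terminal flow-chart box, and the exclusion
reason when no annotation is derived.

## Worked example

The package ships the published worked examples as a runnable corpus:

```r
library(generollup)

fx  <- mgi_fixture_catalog()
out <- derive_annotations(fx$annotations, fx$catalog)

# A conditional genotype: Kcnj11* knocked into the Rosa26 docking site,
# driven by an Ins2-cre transgene. The cre tool is excluded, Rosa26 is
# suppressed, and the annotations land on Kcnj11 alone:
print(out$traces[["MGI:4430413"]])
#> <trace> genotype MGI:4430413
#>   excluded alleles:
#>     syn:al-tgins2cre (conditional_recombinase)
#>   loci: 3 before, 2 after filtering
#> <resolution> MGI:4430413: B10_DOCKING_SITE -> {syn:Kcnj11}

subset(out$derived, marker_id == "syn:Kcnj11")
#>    marker_id marker_symbol     term_id  ontology source_genotype_ids   terminal_boxes
#> 4 syn:Kcnj11        Kcnj11  MP:0003059 phenotype         MGI:4430413 B10_DOCKING_SITE
#> 5 syn:Kcnj11        Kcnj11 OMIM:606176   disease         MGI:4430413 B10_DOCKING_SITE

print(summarize_run(out$traces))
#> Derivation run breakdown
#>   genotypes processed:          19
#>   with derived annotations:     11 (57.9%)
#>     one-marker genotypes:       2 (10.5%)
#>     resolved multi-marker:      9 (47.4%)
#>     novel markers via multi:    11
#>   exclusions by reason:
#>     multi_marker_no_expressed            2
#>     non_mouse_expressed                  1
#>     rosa_suppressed                      1
#>     unresolved_multi                     4
#>   tool-allele removals (genotypes / distinct alleles):
#>     recombinase              5 / 3
#>     reporter_transgene       1 / 1
#>     transactivator_transgene 1 / 1
#>     wild_type                5 / 5
```

The 11 genotypes with derived annotations include the deletion genotype
(attributed to the region marker, not its 39 member genes) and the
transgene/endogenous-gene pairs; the exclusions include the Apoe;Fasl-style
digenic models, a knock-in expressing a non-mouse gene, and the documented
false negatives the rules accept by design.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "generollup", package = "generollup"))')
Rscript $CLI fixtures --out fix/
Rscript $CLI derive --catalog fix/catalog.json \
                    --annotations fix/annotations.tsv --out results/
Rscript $CLI validate --catalog fix/catalog.json
Rscript $CLI simulate --out sim/ --seed 7 --n-genotypes 500
Rscript $CLI report --traces results/traces.json
```

Catalogs are JSON (`markers` / `alleles` / `genotypes`); annotations and
derived outputs are TSV; outputs are deterministically sorted so reruns
are byte-identical. A `--config` JSON file can override the docking-site
list without touching the engine.

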