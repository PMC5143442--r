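Package: generollup
Title: Derive Gene-Level Phenotype and Disease Annotations from Mouse Genotypes
Version: 0.1.0
Authors@R:
    person("Open", "Curation", email = "curation@example.org", role = c("aut", "cre"))
Description: A rule engine that rolls genotype-level Mammalian Phenotype (MP)
    and OMIM disease annotations of mouse models up to the genetic marker
    (gene, transgene, or multi-genic region) whose mutation is causative.
    Transgenic tool alleles (reporters, transactivators, conditional
    recombinases) and wild-type alleles are filtered out, docking-site
    knock-ins (Gt(ROSA)26Sor, Col1a1, Hprt) are resolved to their inserted
    expressed gene, and multi-genic deletions are attributed to the region
    marker.  Every decision is recorded in a per-genotype trace.  Includes a
    curated fixture catalog of published worked examples, a seeded synthetic
    catalog generator, a breakdown reporter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
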