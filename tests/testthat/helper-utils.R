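# Shared helpers: a minimal hand-built catalog and permutation utilities
# for order-invariance properties.

tiny_catalog <- function() {
  catalog(
    markers = list(
      marker("m:g1", "Gene1"), marker("m:g2", "Gene2"),
      marker("m:tg1", "Tg(One)1", "transgene")
    ),
    alleles = list(
      allele("a:n1", "Gene1<tm1>", "targeted", "null_knockout", "m:g1"),
      allele("a:n2", "Gene2<tm1>", "targeted", "null_knockout", "m:g2"),
      allele("a:w1", "Gene1<+>", "other", mutated_markers = "m:g1",
             is_wild_type = TRUE),
      allele("a:tgc", "Tg(One-cargo)1", "transgenic",
             "inserted_expressed_sequence", "m:tg1",
             list(expressed_gene("m:g2")))
    ),
    genotypes = list(
      genotype("g:hom1", list(allele_pair("a:n1", "a:n1"))),
      genotype("g:hom1b", list(allele_pair("a:n1", "a:w1"))),
      genotype("g:tg", list(allele_pair("a:tgc")))
    )
  )
}

shuffle <- function(x) x[sample.int(length(x))]

permute_genotype <- function(g) {
  pairs <- lapply(g$allele_pairs, function(p) {
    if (!is.na(p$allele2) && stats::runif(1) < 0.5) {
      allele_pair(p$allele2, p$allele1)
    } else p
  })
  genotype(g$id, shuffle(pairs), is_conditional = g$is_conditional,
           strain_background = g$strain_background)
}

permute_catalog <- function(cat) {
  catalog(
    markers = shuffle(unname(cat$markers)),
    alleles = shuffle(unname(cat$alleles)),
    genotypes = lapply(shuffle(unname(cat$genotypes)), permute_genotype)
  )
}

expect_trace_matches <- function(tr, expected_row) {
  expect_identical(tr$resolution$terminal_box, expected_row$terminal_box,
                   label = sprintf("terminal box of %s", tr$genotype_id))
  expect_identical(paste(tr$resolution$annotate_markers, collapse = ";"),
                   expected_row$annotate_markers,
                   label = sprintf("annotated markers of %s", tr$genotype_id))
  expect_identical(tr$resolution$exclusion_reason,
                   expected_row$exclusion_reason,
                   label = sprintf("exclusion reason of %s", tr$genotype_id))
}
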