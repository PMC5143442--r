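# Tool-allele classification, driven by a parameterised case table built
# from the published tool-allele examples.

mk <- function(generation, attrs = character(), cargo = 0L, wt = FALSE,
               cargo_species = "mouse") {
  allele("a:x", "X<al>", generation, attributes = attrs,
         mutated_markers = "m:x",
         expressed_genes = if (cargo > 0L) {
           lapply(seq_len(cargo), function(i)
             expressed_gene(sprintf("m:c%d", i), cargo_species))
         } else list(),
         is_wild_type = wt)
}

test_that("allele causality classification follows the published rules", {
  cases <- list(
    # Tg(Tyr-cre/ERT2)-style: recombinase-only transgene, conditional
    list(mk("transgenic", "recombinase"), TRUE, "exclude",
         "conditional_recombinase"),
    # same allele in a non-conditional genotype: may be causative
    list(mk("transgenic", "recombinase"), FALSE, "retain", "not_applicable"),
    # knock-in recombinases are also removable in conditional genotypes
    list(mk("targeted", c("recombinase", "null_knockout")), TRUE, "exclude",
         "conditional_recombinase"),
    # Tg(Tyr-cre/ERT,-Hras1*,-Trap1a)-style: cre plus two cargo genes
    list(mk("transgenic", c("recombinase", "inserted_expressed_sequence"),
            cargo = 2L), TRUE, "retain", "not_applicable"),
    # a recombinase expressing any other gene is retained
    list(mk("transgenic", c("recombinase", "inserted_expressed_sequence"),
            cargo = 1L), TRUE, "retain", "not_applicable"),
    # Tg(Tek-tTA)-style transactivator transgene
    list(mk("transgenic", "transactivator"), FALSE, "exclude",
         "transgenic_transactivator"),
    # knock-in transactivators (Foxg1-tTA-style) cannot be excluded
    list(mk("targeted", c("transactivator", "null_knockout")), FALSE,
         "retain", "not_applicable"),
    # Tg(Cspg4-DsRed.T1)-style reporter-only transgene
    list(mk("transgenic", "reporter"), FALSE, "exclude",
         "transgenic_reporter"),
    # Tg(CAG-Bmpr1a*,-lacZ)-style: reporter plus inserted expressed sequence
    list(mk("transgenic", c("reporter", "inserted_expressed_sequence"),
            cargo = 1L), FALSE, "retain", "not_applicable"),
    # knock-in reporters are retained (may be knock-outs)
    list(mk("targeted", c("reporter", "null_knockout")), FALSE, "retain",
         "not_applicable"),
    # wild types are always tools
    list(mk("other", wt = TRUE), FALSE, "exclude", "wild_type"),
    # ordinary causative mutation
    list(mk("targeted", "null_knockout"), TRUE, "retain", "not_applicable")
  )
  for (i in seq_along(cases)) {
    c_ <- cases[[i]]
    v <- classify_allele_causality(c_[[1]], c_[[2]])
    expect_identical(v$verdict, c_[[3]], label = sprintf("case %d verdict", i))
    expect_identical(v$reason, c_[[4]], label = sprintf("case %d reason", i))
    # invariant: retain <=> not_applicable
    expect_identical(v$verdict == "retain", v$reason == "not_applicable")
  }
})

test_that("conditionality only ever changes recombinase verdicts", {
  fx <- mgi_fixture_catalog()
  for (a in fx$catalog$alleles) {
    flip <- !identical(classify_allele_causality(a, TRUE)$verdict,
                       classify_allele_causality(a, FALSE)$verdict)
    if (flip) expect_true("recombinase" %in% a$attributes)
  }
})

test_that("genotype filtering reports all verdicts and retains causatives", {
  fx <- mgi_fixture_catalog()

  fig2d <- filter_noncausative(fx$catalog$genotypes[["MGI:4429149"]],
                               fx$catalog)
  expect_identical(fig2d$retained, "syn:al-ewsr1-tm")
  ex <- fig2d$verdicts[fig2d$verdicts$verdict == "exclude", ]
  expect_setequal(ex$allele_id, c("syn:al-ewsr1-wt", "syn:al-tgcagcre"))
  expect_setequal(ex$reason, c("wild_type", "conditional_recombinase"))

  fig2b <- filter_noncausative(fx$catalog$genotypes[["MGI:3836994"]],
                               fx$catalog)
  expect_setequal(fig2b$retained, c("syn:al-prnp-tm", "syn:al-tgprnp"))
  expect_true(all(fig2b$verdicts$verdict == "retain"))
})

test_that("an all-wild-type genotype retains nothing but does not error", {
  cat <- tiny_catalog()
  wt2 <- allele("a:w2", "Gene2<+>", "other", mutated_markers = "m:g2",
                is_wild_type = TRUE)
  cat2 <- catalog(unname(cat$markers), c(unname(cat$alleles), list(wt2)),
                  list(genotype("g:wt", list(allele_pair("a:w1", "a:w1"),
                                             allele_pair("a:w2", "a:w2")))))
  fl <- filter_noncausative(cat2$genotypes[["g:wt"]], cat2)
  expect_length(fl$retained, 0L)
  tr <- resolve_genotype(cat2$genotypes[["g:wt"]], cat2)
  expect_identical(tr$resolution$exclusion_reason, "all_alleles_excluded")
})

test_that("filtering is order-invariant and idempotent", {
  fx <- mgi_fixture_catalog()
  set.seed(33)
  for (gid in c("MGI:4429149", "MGI:3689403", "MGI:4412090")) {
    g <- fx$catalog$genotypes[[gid]]
    base <- filter_noncausative(g, fx$catalog)
    perm <- filter_noncausative(permute_genotype(g), fx$catalog)
    expect_setequal(perm$retained, base$retained)
    # idempotent: re-filtering a genotype reduced to its retained alleles
    keep <- base$retained
    g2 <- genotype(g$id, lapply(keep, allele_pair),
                   is_conditional = g$is_conditional)
    again <- filter_noncausative(g2, fx$catalog)
    expect_setequal(again$retained, keep)
  }
})
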