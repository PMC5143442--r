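# The resolution engine, checked against the stored expectations of every
# curated worked example, plus fan-out/dedup behaviour and trace
# invariants.

test_that("every curated example genotype resolves to its documented outcome", {
  fx <- mgi_fixture_catalog()
  cfg <- derivation_config(fx$catalog)
  expect_gte(nrow(fx$expected), 14L)
  for (i in seq_len(nrow(fx$expected))) {
    e <- fx$expected[i, ]
    tr <- resolve_genotype(fx$catalog$genotypes[[e$genotype_id]],
                           fx$catalog, cfg)
    expect_trace_matches(tr, e)
  }
})

test_that("traces satisfy their structural invariants", {
  fx <- mgi_fixture_catalog()
  for (g in fx$catalog$genotypes) {
    tr <- resolve_genotype(g, fx$catalog)
    expect_true(all(tr$loci_after$members %in% tr$loci_before$members))
    res <- tr$resolution
    # annotated markers come from the post-filter locus set
    expect_true(all(res$annotate_markers %in% tr$loci_after$members))
    # annotate empty iff excluded; reason only when excluded
    expect_identical(length(res$annotate_markers) == 0L,
                     res$terminal_box == "EXCLUDED")
    expect_identical(is.na(res$exclusion_reason),
                     res$terminal_box != "EXCLUDED")
  }
})

test_that("fan-out produces one derived annotation per causative marker", {
  fx <- mgi_fixture_catalog()
  ann <- fx$annotations[fx$annotations$genotype_id == "MGI:3836994", ]
  out <- derive_annotations(ann, fx$catalog)
  expect_identical(nrow(out$derived), 2L)
  expect_setequal(out$derived$marker_id, c("syn:Prnp", "syn:TgPrnp"))
  expect_identical(unique(out$derived$term_id), ann$term_id)
})

test_that("identical derivations from different genotypes are deduplicated", {
  cat <- tiny_catalog()
  ann <- data.frame(
    genotype_id = c("g:hom1", "g:hom1b"),
    term_id = "MP:9711111", ontology = "phenotype",
    stringsAsFactors = FALSE
  )
  out <- derive_annotations(ann, cat)
  expect_identical(nrow(out$derived), 1L)
  expect_identical(out$derived$source_genotype_ids, "g:hom1;g:hom1b")
})

test_that("empty annotation tables derive nothing and resolve nothing", {
  fx <- mgi_fixture_catalog()
  out <- derive_annotations(fx$annotations[0, ], fx$catalog)
  expect_identical(nrow(out$derived), 0L)
  expect_length(out$traces, 0L)
})

test_that("annotations to unknown genotypes fail naming the id", {
  fx <- mgi_fixture_catalog()
  ann <- data.frame(genotype_id = "MGI:0000000", term_id = "MP:9700001",
                    ontology = "phenotype", stringsAsFactors = FALSE)
  expect_error(derive_annotations(ann, fx$catalog), "MGI:0000000")
})

test_that("conservation holds: contributions = annotations x markers", {
  fx <- mgi_fixture_catalog()
  out <- derive_annotations(fx$annotations, fx$catalog)
  total <- 0L
  for (gid in names(out$traces)) {
    k <- sum(fx$annotations$genotype_id == gid)
    total <- total + k * length(out$traces[[gid]]$resolution$annotate_markers)
  }
  # fixture terms are unique per genotype, so dedup merges nothing here
  expanded <- sum(lengths(strsplit(out$derived$source_genotype_ids, ";")))
  expect_identical(expanded, total)
})

test_that("Gt(ROSA)26Sor never appears as a derived-annotation subject", {
  fx <- mgi_fixture_catalog()
  out <- derive_annotations(fx$annotations, fx$catalog)
  expect_false("MGI:104735" %in% out$derived$marker_id)
  # even a Rosa26-only genotype with its own annotation derives nothing
  tr <- out$traces[["syn:gt-rosa-viral"]]
  expect_identical(tr$resolution$exclusion_reason, "rosa_suppressed")
})

test_that("markers seen only through excluded alleles are never annotated", {
  fx <- mgi_fixture_catalog()
  for (g in fx$catalog$genotypes) {
    tr <- resolve_genotype(g, fx$catalog)
    ex <- tr$verdicts$allele_id[tr$verdicts$verdict == "exclude"]
    if (length(ex) == 0L) next
    kept <- setdiff(genotype_allele_ids(g), ex)
    tool_only <- setdiff(
      genotype_loci(g, fx$catalog, allele_ids = ex)$members,
      genotype_loci(g, fx$catalog, allele_ids = kept)$members
    )
    expect_length(intersect(tr$resolution$annotate_markers, tool_only), 0L)
  }
})

test_that("resolution is invariant under allele, pair and record order", {
  fx <- mgi_fixture_catalog()
  cfg <- derivation_config(fx$catalog)
  set.seed(99)
  base <- derive_annotations(fx$annotations, fx$catalog, cfg)
  for (rep in 1:3) {
    cat2 <- permute_catalog(fx$catalog)
    ann2 <- fx$annotations[sample.int(nrow(fx$annotations)), ]
    out2 <- derive_annotations(ann2, cat2, cfg)
    expect_identical(out2$derived, base$derived)
  }
})

test_that("docking-site geometry is strict: extra loci fall through", {
  fx <- mgi_fixture_catalog()
  # Hprt cargo genotype resolves B10 ...
  tr <- resolve_genotype(fx$catalog$genotypes[["syn:gt-hprt-cargo"]],
                         fx$catalog)
  expect_identical(tr$resolution$terminal_box, "B10_DOCKING_SITE")
  # ... but adding an unrelated mutated gene spoils the pattern
  extra <- genotype("g:dock-extra",
                    list(allele_pair("syn:al-hprt-cargo"),
                         allele_pair("syn:al-sell", "syn:al-sell")))
  cat2 <- catalog(unname(fx$catalog$markers), unname(fx$catalog$alleles),
                  c(unname(fx$catalog$genotypes), list(extra)))
  tr2 <- resolve_genotype(cat2$genotypes[["g:dock-extra"]], cat2,
                          derivation_config(cat2))
  expect_identical(tr2$resolution$terminal_box, "EXCLUDED")
  expect_identical(tr2$resolution$exclusion_reason, "unresolved_multi")
})
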