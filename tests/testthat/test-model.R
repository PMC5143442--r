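test_that("constructors reject malformed fields with named errors", {
  expect_error(marker(1, "x"), "'id'")
  expect_error(allele("a", "s", c("targeted", "transgenic"),
                      mutated_markers = "m"), "generation_method")
  expect_error(genotype("g", list()), "at least one allele pair")
  expect_error(allele_pair("a1", c("x", "y")), "allele2")
})

test_that("referential and invariant violations are reported as data", {
  cat <- catalog(
    markers = list(marker("m:g1", "Gene1"),
                   marker("m:bad", "Bad", "multi_genic_region")),
    alleles = list(
      allele("a:dangle", "Dangle<tm1>", "targeted",
             mutated_markers = "m:missing"),
      allele("a:wt", "Gene1<+>", "other", attributes = "reporter",
             mutated_markers = "m:g1", is_wild_type = TRUE),
      allele("a:typo", "Gene1<tm2>", "targeted", attributes = "reproter",
             mutated_markers = "m:g1"),
      allele("a:tg", "Tg(X)1", "transgenic", mutated_markers = "m:g1")
    ),
    genotypes = list(genotype("g:x", list(allele_pair("a:gone"))))
  )
  v <- validate_catalog(cat)
  pick <- function(rule) v[v$rule == rule, ]

  dangling <- pick("mutated_marker_ref")
  expect_identical(dangling$id, "a:dangle")
  expect_match(dangling$message, "m:missing")
  expect_identical(pick("wild_type_plain")$id, "a:wt")
  expect_identical(pick("attribute_vocabulary")$id, "a:typo")
  expect_identical(pick("region_genes_required")$id, "m:bad")
  expect_identical(pick("transgenic_marker")$id, "a:tg")
  expect_identical(pick("allele_ref")$id, "g:x")
})

test_that("duplicate ids are flagged", {
  cat <- catalog(markers = list(marker("m:g1", "Gene1"),
                                marker("m:g1", "Gene1Again")))
  v <- validate_catalog(cat)
  expect_true(any(v$rule == "unique_id" & v$id == "m:g1"))
})

test_that("validation is order-independent", {
  cat <- catalog(
    markers = list(marker("m:g1", "Gene1")),
    alleles = list(
      allele("a:1", "A<tm1>", "targeted", mutated_markers = "m:gone"),
      allele("a:2", "B<+>", "other", attributes = "reporter",
             mutated_markers = "m:g1", is_wild_type = TRUE)
    )
  )
  set.seed(11)
  for (i in 1:5) {
    expect_identical(validate_catalog(permute_catalog(cat)),
                     validate_catalog(cat))
  }
})

test_that("the curated fixture catalog validates cleanly", {
  fx <- mgi_fixture_catalog()
  expect_identical(nrow(validate_catalog(fx$catalog)), 0L)
  # and a clean catalog never raises cross-reference errors downstream
  for (g in fx$catalog$genotypes) {
    expect_no_error(resolve_genotype(g, fx$catalog))
  }
})

test_that("derivation_config enforces the subset invariant and symbol lookup", {
  fx <- mgi_fixture_catalog()
  cfg <- derivation_config(fx$catalog)
  expect_setequal(cfg$docking_site_ids,
                  c("MGI:104735", "MGI:88467", "MGI:96217"))
  expect_identical(cfg$never_self_annotate_ids, "MGI:104735")
  expect_error(
    derivation_config(docking_site_ids = "m:a",
                      never_self_annotate_ids = "m:b"),
    "subset"
  )
})
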