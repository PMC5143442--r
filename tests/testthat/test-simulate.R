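# Synthetic catalog generator and the breakdown reporter.

test_that("identical params and seed give identical catalogs", {
  p <- simulation_params(n_genotypes = 40, seed = 17)
  s1 <- simulate_catalog(p)
  s2 <- simulate_catalog(p)
  expect_identical(s1, s2)
  s3 <- simulate_catalog(simulation_params(n_genotypes = 40, seed = 18))
  expect_false(identical(s1$catalog, s3$catalog))
})

test_that("generated catalogs validate cleanly", {
  sim <- simulate_catalog(simulation_params(n_genotypes = 120, seed = 5))
  expect_identical(nrow(validate_catalog(sim$catalog)), 0L)
})

test_that("a degenerate single-gene mixture yields only B1 resolutions", {
  sim <- simulate_catalog(simulation_params(
    n_genotypes = 30, mixture = c(single_gene = 1), seed = 2))
  for (g in sim$catalog$genotypes) {
    tr <- resolve_genotype(g, sim$catalog)
    expect_identical(tr$resolution$terminal_box, "B1_SINGLE")
  }
})

test_that("infeasible parameters are rejected", {
  expect_error(simulation_params(n_genes = 0), "n_genes")
  expect_error(simulation_params(mixture = c(nonsense = 1)), "nonsense")
  expect_error(simulation_params(mixture = c(single_gene = -1)),
               "non-negative")
  expect_error(simulation_params(n_regions = 0,
                                 mixture = c(multigenic = 1)), "region")
})

test_that("the simulator keeps the generating archetype of each genotype", {
  sim <- simulate_catalog(simulation_params(n_genotypes = 50, seed = 9))
  expect_identical(sort(names(sim$archetypes)),
                   sort(names(sim$catalog$genotypes)))
  expect_true(all(sim$archetypes %in% names(generollup:::SIM_TEMPLATES)))
})

test_that("excluded fraction grows with the digenic mixture weight", {
  frac_excluded <- function(p_digenic, seed = 31) {
    w <- generollup:::SIM_TEMPLATES
    w <- w / sum(w) * (1 - p_digenic)
    w["digenic"] <- w["digenic"] + p_digenic
    sim <- simulate_catalog(simulation_params(
      n_genotypes = 400, mixture = w, seed = seed))
    cfg <- derivation_config(sim$catalog)
    mean(vapply(sim$catalog$genotypes, function(g)
      resolve_genotype(g, sim$catalog, cfg)$resolution$terminal_box ==
        "EXCLUDED", NA))
  }
  fr <- vapply(c(0.05, 0.40, 0.80), frac_excluded, 0)
  expect_true(all(diff(fr) > 0))
})

test_that("empty trace lists give an all-zero breakdown", {
  b <- summarize_run(list())
  expect_identical(b$total_genotypes, 0L)
  expect_identical(b$with_derived, 0L)
  expect_identical(b$novel_markers_from_multi, 0L)
  expect_true(all(b$removals_by_allele_class$genotypes == 0L))
})

test_that("the breakdown of the curated fixtures matches a hand enumeration", {
  fx <- mgi_fixture_catalog()
  out <- derive_annotations(fx$annotations, fx$catalog)
  b <- summarize_run(out$traces)

  # Hand enumeration over the 19 stored expectations:
  # derived: fig2a, fig2b, fig2c, Kcnj11, Smo, Col1a1, Hprt, Sell,
  #          Hras/Trap transgene, self-expressed knock-in, App = 11,
  # of which B1 (single marker before filtering): Sell, App.
  expect_identical(b$total_genotypes, 19L)
  expect_identical(b$with_derived, 11L)
  expect_identical(b$one_marker, 2L)
  expect_identical(b$resolved_multi, 9L)
  expect_identical(b$with_derived, b$one_marker + b$resolved_multi)
  # multi-resolved markers are all absent from the B1 set here
  expect_identical(b$novel_markers_from_multi, 11L)
  expect_identical(
    b$exclusions_by_reason[c("multi_marker_no_expressed",
                             "non_mouse_expressed", "rosa_suppressed",
                             "unresolved_multi")],
    c(multi_marker_no_expressed = 2L, non_mouse_expressed = 1L,
      rosa_suppressed = 1L, unresolved_multi = 4L)
  )
  rm_ <- b$removals_by_allele_class
  expect_identical(rm_$genotypes[rm_$class == "recombinase"], 5L)
  expect_identical(rm_$alleles[rm_$class == "recombinase"], 3L)
  expect_identical(rm_$genotypes[rm_$class == "reporter_transgene"], 1L)
  expect_identical(rm_$genotypes[rm_$class == "transactivator_transgene"], 1L)
  expect_identical(rm_$genotypes[rm_$class == "wild_type"], 5L)
  expect_identical(rm_$alleles[rm_$class == "wild_type"], 5L)
})

test_that("with_derived equals the number of traces with annotate markers", {
  sim <- simulate_catalog(simulation_params(n_genotypes = 150, seed = 12))
  out <- derive_annotations(sim$annotations, sim$catalog)
  b <- summarize_run(out$traces)
  expect_identical(b$with_derived, sum(vapply(out$traces, function(t)
    length(t$resolution$annotate_markers) > 0L, NA)))
  expect_identical(b$with_derived, b$one_marker + b$resolved_multi)
})
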