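# Independent brute-force oracle for genotype resolution.
#
# Re-derives the outcome from the written rules directly, as a single flat
# decision table over a long-format locus/evidence table, sharing no code
# with the staged engine.  Used to cross-check resolve_genotype on
# thousands of generated genotypes.

oracle_env <- function(cat) {
  list(markers = list2env(as.list(cat$markers), parent = emptyenv()),
       alleles = list2env(as.list(cat$alleles), parent = emptyenv()))
}

oracle_resolve <- function(gt, env, config) {
  ids <- unlist(lapply(gt$allele_pairs, function(p) c(p$allele1, p$allele2)))
  ids <- unique(ids[!is.na(ids)])

  # Long-format evidence table: one row per (allele, locus, evidence kind).
  al <- character(); lo <- character(); kd <- character(); nm <- logical()
  emit <- function(a, l, k, n = FALSE) {
    al[length(al) + 1L] <<- a; lo[length(lo) + 1L] <<- l
    kd[length(kd) + 1L] <<- k; nm[length(nm) + 1L] <<- n
  }
  for (aid in ids) {
    a <- get(aid, env$alleles)
    for (mm in a$mutated_markers) {
      m <- get(mm, env$markers)
      if (m$marker_class == "transgene") {
        emit(aid, mm, "transgene_self")
      } else {
        emit(aid, mm, "mutated")
      }
      if (m$marker_class == "multi_genic_region") {
        for (rg in m$region_genes) emit(aid, rg, "region_gene")
      }
    }
    for (e in a$expressed_genes) {
      emit(aid, e$gene_id, "expressed", e$species == "non_mouse")
    }
  }

  done <- function(box, annotate, reason = NA_character_) {
    annotate <- setdiff(annotate, config$never_self_annotate_ids)
    if (box != "EXCLUDED" && length(annotate) == 0L) {
      return(list(terminal_box = "EXCLUDED", annotate = character(),
                  reason = "rosa_suppressed"))
    }
    list(terminal_box = box, annotate = sort(unique(annotate)),
         reason = reason)
  }

  # "the number of genetic loci associated with all alleles is determined"
  if (length(unique(lo)) == 1L) {
    return(done("B1_SINGLE", unique(lo)))
  }

  # "non-causative alleles are identified and computationally excluded":
  # transgenic transactivators, transgenic reporters (without inserted
  # expressed sequence), recombinases in conditional genotypes, wild types;
  # tool alleles with expressed cargo beyond the tool product are retained.
  is_tool <- vapply(ids, function(aid) {
    a <- get(aid, env$alleles)
    if (a$is_wild_type) return(TRUE)
    no_cargo <- length(a$expressed_genes) == 0L
    if (a$generation_method == "transgenic" &&
        "transactivator" %in% a$attributes && no_cargo) return(TRUE)
    if (a$generation_method == "transgenic" && "reporter" %in% a$attributes &&
        !"inserted_expressed_sequence" %in% a$attributes) return(TRUE)
    if ("recombinase" %in% a$attributes && gt$is_conditional && no_cargo) {
      return(TRUE)
    }
    FALSE
  }, NA)
  kept <- ids[!is_tool]
  if (length(kept) == 0L) {
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "all_alleles_excluded"))
  }
  in_kept <- al %in% kept
  lo2 <- lo[in_kept]; kd2 <- kd[in_kept]; nm2 <- nm[in_kept]
  A <- sort(unique(lo2))

  kind_of <- function(l) kd2[lo2 == l]
  class_of <- function(l) {
    m <- if (exists(l, env$markers, inherits = FALSE)) get(l, env$markers)
    if (is.null(m)) NA_character_ else m$marker_class
  }

  if (length(A) == 1L) {
    box <- if (all(c("mutated", "expressed") %in% kind_of(A)))
      "B11_SELF_EXPRESSED" else "B3_SINGLE_AFTER_FILTER"
    return(done(box, A))
  }

  cls <- vapply(A, class_of, "")
  mgr <- A[cls %in% "multi_genic_region"]
  if (length(mgr) > 1L) {
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "multiple_multigenic"))
  }
  if (length(mgr) == 1L) {
    inside <- c(mgr, get(mgr, env$markers)$region_genes)
    if (length(setdiff(A, inside)) == 0L) {
      return(done("B4_MULTIGENIC_MARKER", mgr))
    }
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "multigenic_plus_outside"))
  }

  expressed <- sort(unique(lo2[kd2 == "expressed"]))
  tg <- A[cls %in% "transgene"]
  endo <- A[vapply(A, function(l) "mutated" %in% kind_of(l), NA)]
  endo <- setdiff(endo, tg)

  if (length(expressed) == 0L) {
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "multi_marker_no_expressed"))
  }
  if (length(expressed) > 1L) {
    if (length(tg) == 1L && length(endo) == 0L) {
      return(done("B6_TRANSGENE_ONLY", tg))
    }
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "multi_expressed_not_single_transgene"))
  }
  if (any(nm2[lo2 == expressed & kd2 == "expressed"])) {
    return(list(terminal_box = "EXCLUDED", annotate = character(),
                reason = "non_mouse_expressed"))
  }
  if (length(tg) == 1L && length(setdiff(A, c(tg, expressed))) == 0L &&
      length(A) == 2L) {
    box <- if ("mutated" %in% kind_of(expressed))
      "B9_TRANSGENE_ENDOGENOUS_MATCH" else "B8_TRANSGENE_PLUS_GENE"
    return(done(box, c(tg, expressed)))
  }
  if (length(A) == 2L && expressed %in% A &&
      setdiff(A, expressed) %in% config$docking_site_ids) {
    return(done("B10_DOCKING_SITE", expressed))
  }
  list(terminal_box = "EXCLUDED", annotate = character(),
       reason = "unresolved_multi")
}
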